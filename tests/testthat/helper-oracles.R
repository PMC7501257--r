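# Independent brute-force oracles and tiny fixture builders.
# These deliberately avoid the code paths they are used to check.

# Pearson r^2 from the raw sum formula (no stats::cor).
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- (n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2)
  if (den == 0) return(NA_real_)
  num^2 / den
}

# Position-by-position insertion scanner: per base, count qualifying samples
# by an explicit loop, then walk the contig collecting maximal runs.
oracle_insertions <- function(depth, min_len = 500L, depth_min = 5L,
                              min_samples = 10L, strict = TRUE) {
  n <- nrow(depth$depth)
  qual <- logical(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(ncol(depth$depth))) {
      d <- depth$depth[i, j]
      if (if (strict) d > depth_min else d >= depth_min) cnt <- cnt + 1L
    }
    qual[i] <- cnt >= min_samples
  }
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        out <- rbind(out, data.frame(contig = depth$contig,
                                     start = depth$start + i - 1L,
                                     end = depth$start + j))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out %||% data.frame(contig = character(), start = integer(), end = integer())
}

# Pairwise-merge fixpoint for SV collapsing: repeatedly merge any two calls
# of the same (sample, type, contig) stratum that share >= 1 bp, until stable.
oracle_sv_fixpoint <- function(calls) {
  x <- calls
  x$n_source_calls <- 1L
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(nrow(x))) {
        if (j <= i) next
        same <- x$sample[i] == x$sample[j] && x$sv_type[i] == x$sv_type[j] &&
          x$contig[i] == x$contig[j]
        if (same && x$start[i] < x$end[j] && x$start[j] < x$end[i]) {
          x$start[i] <- min(x$start[i], x$start[j])
          x$end[i] <- max(x$end[i], x$end[j])
          x$n_source_calls[i] <- x$n_source_calls[i] + x$n_source_calls[j]
          x <- x[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  x <- x[order(x$sample, x$sv_type, x$contig, x$start), , drop = FALSE]
  rownames(x) <- NULL
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny genotype table straight from a dosage matrix (sites x samples).
make_gt <- function(dosage, contig = "chr1", pos = NULL) {
  n <- nrow(dosage)
  sites <- data.frame(contig = contig, pos = pos %||% (seq_len(n) * 1000L),
                      ref = rep("A", n), alt = rep("G", n))
  geno_table(sites, dosage)
}

# Synthetic proxy_set (labelled synthetic: built directly, not via a scan)
# for tests of the set-comparison arithmetic.
make_proxy_set <- function(keys, tag_key = "chr1:500:A:G", population = "x") {
  px <- if (length(keys)) {
    data.frame(contig = "chr1", pos = seq_along(keys), ref = "A", alt = "G",
               key = keys, r2 = 0.9, stringsAsFactors = FALSE)
  } else data.frame()
  structure(list(tag = list(contig = "chr1", pos = 500L, key = tag_key),
                 population = population, assessable = TRUE,
                 reason = NA_character_, n_proxies = length(keys),
                 proxies = px),
            class = "proxy_set")
}

# Random dosage matrix with optional missingness.
rand_dosage <- function(n_sites, n_samples, missing = 0) {
  d <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              nrow = n_sites)
  if (missing > 0) d[runif(length(d)) < missing] <- NA_integer_
  d
}
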