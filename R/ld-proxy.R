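#' Squared genotype correlation (composite LD r-squared)
#'
#' r-squared between two genotype dosage vectors (0/1/2), computed as the
#' squared Pearson correlation over pairwise-complete entries. This is the
#' composite (genotype-based) LD estimate: phase is not required, which makes
#' it applicable to any pair of cohorts. A monomorphic vector (zero variance
#' after pairwise deletion) leaves r-squared undefined; this is an error, not
#' a zero.
#'
#' @param dosages_a,dosages_b equal-length numeric vectors of allele dosages;
#'   `NA` = missing genotype.
#' @param min_complete minimum pairwise-complete observations (default 2; the
#'   proxy scan uses a stricter 10).
#' @return r-squared in \[0, 1\].
#' @export
r_squared <- function(dosages_a, dosages_b, min_complete = 2L) {
  if (length(dosages_a) != length(dosages_b))
    stop_popref("dosage vectors differ in length")
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < min_complete)
    stop_popref("fewer than %d pairwise-complete observations", min_complete)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop_popref("monomorphic vector: r-squared undefined")
  stats::cor(a, b)^2
}

#' Select replicated GWAS tag SNPs per trait
#'
#' Greedy locus clustering: within each trait, take the strongest remaining
#' association (smallest `strength`, e.g. a p-value), assign every
#' association within `window_bp` on the same contig to its locus, and
#' repeat. A locus is retained iff its associations come from at least
#' `min_studies` distinct studies ("replicated"); the retained locus is
#' represented by its strongest association — the tag SNP. Strength ties
#' break by lower (contig, position), making the output invariant to input
#' order.
#'
#' @param associations data.frame: `trait_term`, `contig`, `pos`, `strength`
#'   (> 0, smaller is stronger), `study_id`, optionally `ref`, `alt`, `rsid`.
#' @param window_bp locus half-width in bp (default 1 Mb).
#' @param min_studies distinct studies required per locus (default 2).
#' @param contig_lengths optional named vector used to clip locus intervals.
#' @return data.frame of tag SNPs: trait_term, contig, pos, strength,
#'   n_supporting_associations, n_studies, locus_start, locus_end (plus
#'   ref/alt/rsid when supplied). Empty input gives an empty frame.
#' @export
select_tag_snps <- function(associations, window_bp = 1e6, min_studies = 2L,
                            contig_lengths = NULL) {
  if (!nrow(associations)) return(empty_tags(associations))
  if (any(associations$strength <= 0))
    stop_popref("association strength must be > 0")
  out <- list()
  for (trait in unique(associations$trait_term)) {
    a <- associations[associations$trait_term == trait, , drop = FALSE]
    a <- a[order(a$strength, a$contig, a$pos), , drop = FALSE]
    while (nrow(a)) {
      tag <- a[1L, , drop = FALSE]
      in_locus <- a$contig == tag$contig & abs(a$pos - tag$pos) <= window_bp
      locus <- a[in_locus, , drop = FALSE]
      if (length(unique(locus$study_id)) >= min_studies) {
        lo <- max(1, tag$pos - window_bp)
        hi <- tag$pos + window_bp
        if (!is.null(contig_lengths) && tag$contig %in% names(contig_lengths))
          hi <- min(hi, contig_lengths[[tag$contig]])
        tag$n_supporting_associations <- nrow(locus)
        tag$n_studies <- length(unique(locus$study_id))
        tag$locus_start <- lo
        tag$locus_end <- hi
        out[[length(out) + 1L]] <- tag
      }
      a <- a[!in_locus, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out) %||% empty_tags(associations)
  res <- res[order(res$trait_term, res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_tags <- function(associations) {
  res <- associations[0, , drop = FALSE]
  res$n_supporting_associations <- integer()
  res$n_studies <- integer()
  res$locus_start <- numeric()
  res$locus_end <- numeric()
  res
}

#' Find LD proxies of a tag SNP in one population
#'
#' Candidate sites are those within `window_bp` of the tag on the same
#' contig, excluding the tag site itself (by site key — a distinct site
#' duplicating the tag's dosages *is* a proxy with r-squared 1). A candidate
#' is a proxy iff its r-squared with the tag is *strictly* above `r2_min`.
#' Candidates that are monomorphic or share fewer than `min_complete`
#' complete genotype pairs with the tag are skipped. A tag that is absent
#' from the table, ungenotyped, or monomorphic is not assessable in this
#' population; the returned set is flagged accordingly.
#'
#' @param gt a [geno_table()] for the population.
#' @param tag_contig,tag_pos tag site coordinates. If several alleles are
#'   recorded at the position, `tag_ref`/`tag_alt` disambiguate.
#' @param tag_ref,tag_alt optional tag alleles.
#' @param r2_min r-squared threshold (strict >). Default 0.8.
#' @param window_bp search half-width (default 1 Mb, the locus window).
#' @param min_complete minimum pairwise-complete genotypes per pair.
#' @param population label stored in the result.
#' @return object of class `proxy_set`: list with `tag` (key and coords),
#'   `population`, `assessable`, `proxies` (data.frame contig, pos, ref, alt,
#'   key, r2) and `n_proxies`.
#' @export
find_proxies <- function(gt, tag_contig, tag_pos, tag_ref = NULL,
                         tag_alt = NULL, r2_min = 0.8, window_bp = 1e6,
                         min_complete = 10L, population = "pop") {
  stopifnot(inherits(gt, "geno_table"))
  s <- gt$sites
  hit <- which(s$contig == tag_contig & s$pos == tag_pos &
               (is.null(tag_ref) | s$ref == (tag_ref %||% "")) &
               (is.null(tag_alt) | s$alt == (tag_alt %||% "")))
  tag_key <- site_key(tag_contig, tag_pos, tag_ref %||% "?", tag_alt %||% "?")
  not_assessable <- function(reason) {
    structure(list(tag = list(contig = tag_contig, pos = tag_pos, key = tag_key),
                   population = population, assessable = FALSE,
                   reason = reason, n_proxies = NA_integer_,
                   proxies = data.frame()), class = "proxy_set")
  }
  if (length(hit) == 0L) return(not_assessable("tag not present"))
  hit <- hit[1L]
  tag_d <- gt$dosage[hit, ]
  if (sum(!is.na(tag_d)) < min_complete)
    return(not_assessable("tag insufficiently genotyped"))
  if (stats::var(tag_d, na.rm = TRUE) == 0)
    return(not_assessable("tag monomorphic"))
  tag_key <- site_key(s$contig[hit], s$pos[hit], s$ref[hit], s$alt[hit])
  cand <- which(s$contig == tag_contig & abs(s$pos - tag_pos) <= window_bp)
  cand <- setdiff(cand, hit)
  r2 <- rep(NA_real_, length(cand))
  if (length(cand)) {
    D <- gt$dosage[cand, , drop = FALSE]
    tok <- !is.na(tag_d)
    n_complete <- rowSums(!is.na(D[, tok, drop = FALSE]))
    ## Pearson against every candidate at once; zero-variance pairs come
    ## back NA (skipped), matching the per-pair semantics. Complete data
    ## takes the fast path.
    use <- if (anyNA(D) || anyNA(tag_d)) "pairwise.complete.obs" else "everything"
    r <- suppressWarnings(stats::cor(tag_d, t(D), use = use))[1L, ]
    r2 <- r^2
    r2[n_complete < min_complete] <- NA_real_
  }
  keep <- !is.na(r2) & r2 > r2_min
  px <- s[cand[keep], c("contig", "pos", "ref", "alt"), drop = FALSE]
  px$key <- site_key(px$contig, px$pos, px$ref, px$alt)
  px$r2 <- r2[keep]
  px <- px[order(px$pos), , drop = FALSE]
  rownames(px) <- NULL
  structure(list(tag = list(contig = tag_contig, pos = tag_pos, key = tag_key),
                 population = population, assessable = TRUE, reason = NA_character_,
                 n_proxies = nrow(px), proxies = px),
            class = "proxy_set")
}

#' @export
print.proxy_set <- function(x, ...) {
  if (!x$assessable) {
    cat(sprintf("proxy_set [%s] tag %s: not assessable (%s)\n",
                x$population, x$tag$key, x$reason))
  } else {
    cat(sprintf("proxy_set [%s] tag %s: %d proxies\n",
                x$population, x$tag$key, x$n_proxies))
  }
  invisible(x)
}

#' Compare a tag SNP's proxy sets between two populations
#'
#' Shared proxies are counted by site key. Percentages are reported both
#' exactly and rounded half-away-from-zero to the nearest integer; when a
#' population has no proxies its percentages are undefined (`NA`), never 0 or
#' 100.
#'
#' @param set_a,set_b `proxy_set`s for the *same* tag (checked by key).
#' @return object of class `proxy_comparison`: n_a, n_b, n_shared, exact
#'   fractions `frac_*`, rounded `pct_a_shared`, `pct_a_only`,
#'   `pct_b_shared`, `pct_b_only`.
#' @export
compare_proxy_sets <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "proxy_set"), inherits(set_b, "proxy_set"))
  if (!identical(set_a$tag$key, set_b$tag$key))
    stop_popref("proxy sets are for different tags (%s vs %s)",
                set_a$tag$key, set_b$tag$key)
  keys_a <- set_a$proxies$key %||% character()
  keys_b <- set_b$proxies$key %||% character()
  n_a <- length(keys_a); n_b <- length(keys_b)
  n_shared <- length(intersect(keys_a, keys_b))
  pcts <- function(n) {
    if (n == 0L) c(shared = NA_real_, only = NA_real_)
    else c(shared = 100 * n_shared / n, only = 100 * (n - n_shared) / n)
  }
  pa <- pcts(n_a); pb <- pcts(n_b)
  structure(list(
    tag = set_a$tag, n_a = n_a, n_b = n_b, n_shared = n_shared,
    frac_a_shared = pa[["shared"]] / 100, frac_b_shared = pb[["shared"]] / 100,
    pct_a_shared_exact = pa[["shared"]], pct_a_only_exact = pa[["only"]],
    pct_b_shared_exact = pb[["shared"]], pct_b_only_exact = pb[["only"]],
    pct_a_shared = round_half_up(pa[["shared"]]),
    pct_a_only = round_half_up(pa[["only"]]),
    pct_b_shared = round_half_up(pb[["shared"]]),
    pct_b_only = round_half_up(pb[["only"]])
  ), class = "proxy_comparison")
}

#' @export
print.proxy_comparison <- function(x, ...) {
  cat(sprintf(paste0("proxy comparison, tag %s: n_a=%d n_b=%d shared=%d | ",
                     "A: ~%s%% shared / ~%s%% only; B: ~%s%% shared / ~%s%% only\n"),
              x$tag$key, x$n_a, x$n_b, x$n_shared,
              x$pct_a_shared, x$pct_a_only, x$pct_b_shared, x$pct_b_only))
  invisible(x)
}

#' Allele-frequency contrast of tag SNPs between two populations
#'
#' For each tag site, the AF difference (population a minus b) and a class
#' label at the `common_cut` threshold (AF strictly above the cut = common):
#' `common-both`, `common-a-rare-b`, `common-b-rare-a`, `rare-both`, or
#' `absent-in-a` / `absent-in-b` / `absent-in-both` when a site is missing
#' from (or ungenotyped in) a population — the "tag not assessable" tally.
#'
#' @param tag_sites data.frame with a `key` column (e.g. tags from
#'   [select_tag_snps()] with keys added) or a character vector of keys.
#' @param stats_a,stats_b allele-stat tables from [compute_allele_stats()].
#' @param common_cut AF threshold (strict >). Default 0.05.
#' @return data.frame: key, af_a, af_b, delta, label.
#' @export
af_contrast <- function(tag_sites, stats_a, stats_b, common_cut = 0.05) {
  keys <- if (is.character(tag_sites)) tag_sites else tag_sites$key
  af_of <- function(stats) {
    m <- match(keys, stats$key)
    af <- stats$alt_af[m]
    af[!is.na(m) & stats$no_genotypes[m]] <- NA_real_
    af
  }
  af_a <- af_of(stats_a); af_b <- af_of(stats_b)
  label <- character(length(keys))
  miss_a <- is.na(af_a); miss_b <- is.na(af_b)
  label[miss_a & miss_b] <- "absent-in-both"
  label[miss_a & !miss_b] <- "absent-in-a"
  label[!miss_a & miss_b] <- "absent-in-b"
  both <- !miss_a & !miss_b
  ca <- af_a > common_cut; cb <- af_b > common_cut
  label[both & ca & cb] <- "common-both"
  label[both & ca & !cb] <- "common-a-rare-b"
  label[both & !ca & cb] <- "common-b-rare-a"
  label[both & !ca & !cb] <- "rare-both"
  data.frame(key = keys, af_a = af_a, af_b = af_b, delta = af_a - af_b,
             label = label, stringsAsFactors = FALSE)
}
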