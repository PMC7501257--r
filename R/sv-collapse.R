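#' Collapse overlapping structural-variant calls per individual
#'
#' Within each (sample, sv_type, contig) stratum, intervals sharing at least
#' 1 bp are merged by single linkage (chains merge transitively); abutting
#' intervals (end == next start) do *not* merge — "overlapping" is read
#' literally. Calls are never merged across samples or across SV types.
#' Translocation (TRA) records, which carry a mate breakpoint instead of an
#' interval, merge only when both breakpoints agree within `tra_window` bp
#' (default 0, i.e. exact equality).
#'
#' @param calls data.frame: `sample`, `sv_type` (DEL/DUP/INV/INS/TRA),
#'   `contig`, `start`, `end` (0-based half-open; INS has end = start + 1);
#'   TRA rows additionally use `mate_contig`, `mate_pos`.
#' @param tra_window breakpoint tolerance for TRA merging, in bp.
#' @return data.frame of collapsed calls with `n_source_calls`, sorted by
#'   (sample, sv_type, contig, start); merged intervals are pairwise disjoint
#'   within each stratum.
#' @export
collapse_overlapping <- function(calls, tra_window = 0L) {
  need <- c("sample", "sv_type", "contig", "start", "end")
  if (!all(need %in% names(calls)))
    stop_popref("calls must have columns %s", paste(need, collapse = ", "))
  interval <- calls$sv_type != "TRA"
  bad <- interval & !(calls$start < calls$end)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_popref("malformed interval (start >= end) for %s %s %s:%s-%s",
                calls$sample[i], calls$sv_type[i], calls$contig[i],
                calls$start[i], calls$end[i])
  }
  if (!nrow(calls)) {
    out <- calls[0, need, drop = FALSE]
    out$n_source_calls <- integer()
    return(out)
  }
  strata <- split(seq_len(nrow(calls)),
                  paste(calls$sample, calls$sv_type, calls$contig, sep = "\r"))
  pieces <- lapply(strata, function(idx) {
    x <- calls[idx, , drop = FALSE]
    if (x$sv_type[1L] == "TRA") return(collapse_tra(x, tra_window))
    o <- order(x$start, x$end)
    s <- x$start[o]; e <- x$end[o]
    ## sweep: strict overlap (next start < current end) extends the cluster
    cur_s <- s[1L]; cur_e <- e[1L]; n <- 1L
    res <- list()
    for (i in seq_along(s)[-1L]) {
      if (s[i] < cur_e) {
        cur_e <- max(cur_e, e[i]); n <- n + 1L
      } else {
        res[[length(res) + 1L]] <- c(cur_s, cur_e, n)
        cur_s <- s[i]; cur_e <- e[i]; n <- 1L
      }
    }
    res[[length(res) + 1L]] <- c(cur_s, cur_e, n)
    m <- do.call(rbind, res)
    data.frame(sample = x$sample[1L], sv_type = x$sv_type[1L],
               contig = x$contig[1L], start = m[, 1L], end = m[, 2L],
               n_source_calls = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample, out$sv_type, out$contig, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

collapse_tra <- function(x, tra_window) {
  if (is.null(x$mate_contig)) x$mate_contig <- NA_character_
  if (is.null(x$mate_pos)) x$mate_pos <- NA_real_
  ## group by quantized breakpoint pair; window 0 = exact equality
  q <- function(p) if (tra_window > 0) floor(p / (tra_window + 1)) else p
  grp <- paste(x$contig, q(x$start), x$mate_contig, q(x$mate_pos))
  agg <- lapply(split(seq_len(nrow(x)), grp), function(i) {
    data.frame(sample = x$sample[1L], sv_type = "TRA", contig = x$contig[i[1L]],
               start = x$start[i[1L]], end = x$end[i[1L]],
               n_source_calls = length(i), stringsAsFactors = FALSE)
  })
  do.call(rbind, agg)
}

#' Per-individual and cohort summary of collapsed SVs
#'
#' @param collapsed output of [collapse_overlapping()].
#' @return list: `per_sample` (sample, counts by type, total), `mean_per_sample`
#'   (exact) and `mean_per_sample_rounded` (to the unit, half away from zero).
#' @export
sv_summary <- function(collapsed) {
  if (!nrow(collapsed)) {
    return(list(per_sample = data.frame(sample = character(), total = integer()),
                mean_per_sample = NaN, mean_per_sample_rounded = NaN))
  }
  tab <- table(collapsed$sample, collapsed$sv_type)
  per_sample <- data.frame(sample = rownames(tab),
                           as.data.frame.matrix(tab),
                           total = as.integer(rowSums(tab)),
                           stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  m <- mean(per_sample$total)
  list(per_sample = per_sample, mean_per_sample = m,
       mean_per_sample_rounded = round_half_up(m))
}
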