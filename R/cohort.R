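#' Per-site cohort allele statistics
#'
#' For every site: the number of individuals with a non-missing genotype, the
#' alternative-allele frequency alt_af = alt allele count / (2 * n_genotyped),
#' and the minor-allele frequency maf = min(alt_af, 1 - alt_af). Sites with
#' no genotyped individual are flagged (`no_genotypes`), not dropped; their
#' frequencies are `NA`.
#'
#' @param gt a [geno_table()] (the constructor rejects non-diploid calls).
#' @return data.frame: site columns (`contig`, `pos`, `ref`, `alt`, `rsid`,
#'   `key`) plus `n_genotyped`, `alt_af`, `maf`, `no_genotypes`.
#' @export
compute_allele_stats <- function(gt) {
  stopifnot(inherits(gt, "geno_table"))
  d <- gt$dosage
  n_genotyped <- as.integer(rowSums(!is.na(d)))
  alt_ac <- rowSums(d, na.rm = TRUE)
  alt_af <- ifelse(n_genotyped > 0, alt_ac / (2 * n_genotyped), NA_real_)
  out <- gt$sites
  out$key <- site_key(out$contig, out$pos, out$ref, out$alt)
  out$n_genotyped <- n_genotyped
  out$alt_af <- alt_af
  out$maf <- pmin(alt_af, 1 - alt_af)
  out$no_genotypes <- n_genotyped == 0L
  out
}

#' Select common variants
#'
#' Keeps sites with minor-allele frequency *strictly* above `maf_min` and at
#' least `min_genotyped` genotyped individuals (inclusive). `measure =
#' "alt_af"` filters on the alternative-allele frequency instead of the MAF
#' (the two readings of "frequency of more than 5%" for a cohort definition
#' of common variants).
#'
#' @param stats output of [compute_allele_stats()].
#' @param maf_min frequency threshold (strict >). Default 0.05.
#' @param min_genotyped minimum genotyped individuals (inclusive). Default 100.
#' @param measure `"maf"` (default) or `"alt_af"`.
#' @return the filtered stats data.frame.
#' @export
select_common <- function(stats, maf_min = 0.05, min_genotyped = 100L,
                          measure = c("maf", "alt_af")) {
  measure <- match.arg(measure)
  f <- stats[[measure]]
  keep <- !is.na(f) & f > maf_min & stats$n_genotyped >= min_genotyped
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select population-specific variants
#'
#' A common variant is population-specific iff, for *every* external panel,
#' the site is either absent from the panel (not detected) or its panel
#' frequency is strictly below `rare_max`. Panel lookup is by exact
#' (contig, pos, ref, alt) key; an allele mismatch therefore counts as "not
#' detected".
#'
#' @param common_set output of [select_common()].
#' @param panels panel table from [read_panel_af()] (or any data.frame with
#'   `key`, `panel`, `af`).
#' @param rare_max panel-frequency ceiling (strict <). Default 0.01.
#' @return subset of `common_set`, with an added `n_panels_detected` column.
#' @export
select_population_specific <- function(common_set, panels, rare_max = 0.01) {
  if (is.null(panels$key))
    panels$key <- site_key(panels$contig, panels$pos, panels$ref, panels$alt)
  pt <- data.table::as.data.table(panels)
  agg <- pt[, list(max_af = max(af), n_panels = .N), by = "key"]
  m <- match(common_set$key, agg$key)
  max_af <- agg$max_af[m]           # NA = absent from every panel
  keep <- is.na(max_af) | max_af < rare_max
  out <- common_set[keep, , drop = FALSE]
  out$n_panels_detected <- ifelse(is.na(agg$n_panels[m][keep]), 0L,
                                  agg$n_panels[m][keep])
  rownames(out) <- NULL
  out
}

#' Flag variants without any known identifier
#'
#' Returns the variants whose `rsid` is unset and whose site key is absent
#' from a supplied identifier index (e.g. a dbSNP extract).
#'
#' @param variants data.frame with `key` and `rsid` columns (e.g. from
#'   [select_population_specific()]).
#' @param rsid_index character vector of site keys known to carry an rsID
#'   (may be empty).
#' @return subset of `variants`.
#' @export
flag_novel <- function(variants, rsid_index = character()) {
  keep <- is.na(variants$rsid) & !(variants$key %in% rsid_index)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Major allele per site
#'
#' The cohort's major allele: alt if alt_af > 0.5, ref if alt_af < 0.5, and
#' ref on an exact tie (declared tie-break, keeping the reference where the
#' cohort gives no direction). Sites with no genotyped individuals get `NA`
#' and are signalled with a warning.
#'
#' @param stats output of [compute_allele_stats()].
#' @return `stats` with an added `major_allele` column.
#' @export
major_allele_at <- function(stats) {
  maj <- ifelse(stats$alt_af > 0.5, stats$alt, stats$ref)
  und <- stats$n_genotyped == 0L
  if (any(und)) {
    maj[und] <- NA_character_
    warning(sprintf("%d site(s) with no genotyped individuals: major allele undefined",
                    sum(und)), call. = FALSE)
  }
  stats$major_allele <- maj
  stats
}
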