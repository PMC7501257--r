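#' Fraction of variants phased into a phase block
#'
#' A variant counts as phased when it carries a phase-block identifier.
#' Reported over two denominators: all variants (the headline convention for
#' linked-read phasing reports) and heterozygous variants only — homozygous
#' sites cannot carry phase information, so both readings are given.
#'
#' @param variants data.frame: `contig`, `pos`, `zygosity` ("het"/"hom"),
#'   `phase_block_id` (`NA`/"" = unphased).
#' @param autosomes_only restrict to contigs in `autosomes` first.
#' @param autosomes contig names considered autosomal.
#' @return list: `n_phased`, `n_total`, `pct` (one decimal, half away from
#'   zero), `fraction` (exact), and `het_only` (same fields over the
#'   heterozygous denominator).
#' @export
phased_fraction <- function(variants, autosomes_only = TRUE,
                            autosomes = paste0("chr", 1:22)) {
  if (autosomes_only) {
    variants <- variants[variants$contig %in% autosomes, , drop = FALSE]
  }
  if (!nrow(variants))
    stop_popref("no variants to summarize (empty set after filtering)")
  phased <- !is.na(variants$phase_block_id) & variants$phase_block_id != ""
  all_d <- phased_fraction_from_counts(sum(phased), nrow(variants))
  het <- variants$zygosity == "het"
  het_d <- if (any(het))
    phased_fraction_from_counts(sum(phased & het), sum(het)) else NULL
  c(all_d, list(het_only = het_d))
}

#' Phased percentage from raw counts
#'
#' The arithmetic core of [phased_fraction()], usable directly on published
#' counts: percentage = 100 * n_phased / n_total, reported rounded to one
#' decimal (half away from zero) with the exact fraction retained.
#'
#' @param n_phased,n_total non-negative counts, `n_total` > 0.
#' @return list: `n_phased`, `n_total`, `fraction`, `pct`.
#' @export
phased_fraction_from_counts <- function(n_phased, n_total) {
  if (n_total <= 0) stop_popref("n_total must be > 0")
  if (n_phased > n_total) stop_popref("n_phased exceeds n_total")
  frac <- n_phased / n_total
  list(n_phased = n_phased, n_total = n_total, fraction = frac,
       pct = round_half_up(100 * frac, 1))
}

#' Fraction of short genes phased into a single block
#'
#' Eligible genes have span length (1-based inclusive: end - start + 1)
#' strictly below `max_len` and at least `min_het` heterozygous variants
#' within the span. A gene counts as single-block iff *all* its heterozygous
#' variants are phased and share one phase-block identifier.
#'
#' @param genes data.frame: `gene_id`, `contig`, `start`, `end` (1-based
#'   inclusive).
#' @param variants as in [phased_fraction()].
#' @param max_len gene length ceiling in bp (strict <). Default 100 kb.
#' @param min_het minimum heterozygous variants (inclusive). Default 2.
#' @return list: `n_eligible`, `n_single_block`, `fraction`, `pct` (two
#'   decimals), `per_gene` data.frame (gene_id, n_het, n_blocks,
#'   single_block, eligible).
#' @export
genes_single_block <- function(genes, variants, max_len = 1e5, min_het = 2L) {
  het <- variants[variants$zygosity == "het", , drop = FALSE]
  per <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start + 1
    in_span <- het$contig == g$contig & het$pos >= g$start & het$pos <= g$end
    v <- het[in_span, , drop = FALSE]
    eligible <- len < max_len && nrow(v) >= min_het
    blocks <- unique(v$phase_block_id[!is.na(v$phase_block_id) &
                                      v$phase_block_id != ""])
    all_phased <- nrow(v) > 0 &&
      all(!is.na(v$phase_block_id) & v$phase_block_id != "")
    data.frame(gene_id = g$gene_id, n_het = nrow(v),
               n_blocks = length(blocks),
               single_block = all_phased && length(blocks) == 1L,
               eligible = eligible, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_eligible <- sum(per$eligible)
  n_single <- sum(per$eligible & per$single_block)
  frac <- if (n_eligible > 0) n_single / n_eligible else NA_real_
  list(n_eligible = n_eligible, n_single_block = n_single, fraction = frac,
       pct = round_half_up(100 * frac, 2), per_gene = per)
}

#' Total length of long runs of homozygosity per individual
#'
#' Per sample, the sum of lengths of ROH segments *strictly longer* than
#' `min_len` ("larger than 5 Mb"). Samples whose segments all fall below the
#' threshold report 0.
#'
#' @param segments data.frame: `sample`, `contig`, `start`, `end` (0-based
#'   half-open; length = end - start).
#' @param min_len length threshold in bp (strict >). Default 5 Mb.
#' @return data.frame: sample, n_long, total_long_bp.
#' @export
total_long_roh <- function(segments, min_len = 5e6) {
  if (!nrow(segments)) {
    return(data.frame(sample = character(), n_long = integer(),
                      total_long_bp = numeric()))
  }
  len <- segments$end - segments$start
  if (any(len <= 0)) stop_popref("ROH segments must have positive length")
  long <- len > min_len
  n <- tapply(long, segments$sample, sum)
  tot <- tapply(len * long, segments$sample, sum)
  out <- data.frame(sample = names(n), n_long = as.integer(n),
                    total_long_bp = as.numeric(tot), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$sample), , drop = FALSE]
}

#' Read phase annotations from a VCF with PS (phase set) FORMAT field
#'
#' Extracts one sample's variants with zygosity derived from GT and the phase
#' block from PS (heterozygous calls without PS, or with unphased separators,
#' count as unphased).
#'
#' @param path VCF file.
#' @param sample sample name (default: first sample).
#' @return data.frame usable by [phased_fraction()] / [genes_single_block()].
#' @export
read_phase_annotations <- function(path, sample = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  ps <- VariantAnnotation::geno(vcf)$PS
  if (is.null(gt)) stop_popref("VCF %s has no GT field", path)
  j <- if (is.null(sample)) 1L else match(sample, colnames(gt))
  if (is.na(j)) stop_popref("sample %s not in VCF", sample)
  rr <- SummarizedExperiment::rowRanges(vcf)
  g <- gt[, j]
  zyg <- ifelse(g %in% c("0/1", "1/0", "0|1", "1|0"), "het",
         ifelse(g %in% c("1/1", "1|1", "0/0", "0|0"), "hom", NA_character_))
  block <- if (is.null(ps)) rep(NA_character_, length(g)) else as.character(ps[, j])
  block[!grepl("\\|", g)] <- NA_character_   # unphased separator: no block
  data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr), zygosity = zyg,
             phase_block_id = block, stringsAsFactors = FALSE)
}
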