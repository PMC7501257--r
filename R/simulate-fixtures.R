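## Fixture generators for the interval-based stages. All of them are
## truth-first: the ground truth is planted, then the observable input is
## constructed around it, so recovery tests never depend on the code they
## check.

#' Simulate per-individual structural-variant calls with known collapse truth
#'
#' For each sample and SV type a set of *disjoint* true merged intervals is
#' planted; each is then emitted as 1-3 overlapping source calls whose
#' single-linkage union equals the planted interval. The truth sidecar is the
#' planted set, by construction, not a re-computation.
#'
#' @param config a [sim_config()] (seed, contigs, n_samples are used).
#' @param n_true_per_sample planted merged SVs per sample.
#' @param sv_types types to draw from (interval types only).
#' @param len_range true-interval length range in bp.
#' @param dir optional output directory (`sv_calls.tsv`, `sv_truth.tsv`).
#' @return list with `calls` (sample, sv_type, contig, start, end) and
#'   `truth` (same columns plus `n_source_calls`).
#' @export
simulate_sv_calls <- function(config, n_true_per_sample = 5L,
                              sv_types = c("DEL", "DUP", "INV"),
                              len_range = c(300L, 3000L), dir = NULL) {
  stopifnot(inherits(config, "sim_config"), n_true_per_sample >= 0)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  ctg <- names(config$contig_lengths)[1L]
  ctg_len <- as.integer(config$contig_lengths[[1L]])
  out <- with_substream(config$seed, "sv", {
    calls <- list(); truth <- list()
    for (s in samples) {
      k <- n_true_per_sample
      if (k == 0L) next
      ## disjoint slots, one true interval per slot
      slot <- floor(ctg_len / k)
      if (slot < max(len_range) + 10L)
        stop_popref("contig too short for %d SVs of up to %d bp", k, max(len_range))
      for (i in seq_len(k)) {
        len <- sample(len_range[1L]:len_range[2L], 1L)
        lo <- (i - 1L) * slot
        start <- lo + sample.int(slot - len - 1L, 1L)
        end <- start + len
        type <- sample(sv_types, 1L)
        pieces <- split_into_overlapping(start, end)
        truth[[length(truth) + 1L]] <- data.frame(
          sample = s, sv_type = type, contig = ctg, start = start, end = end,
          n_source_calls = nrow(pieces), stringsAsFactors = FALSE)
        calls[[length(calls) + 1L]] <- data.frame(
          sample = s, sv_type = type, contig = ctg,
          start = pieces$start, end = pieces$end, stringsAsFactors = FALSE)
      }
    }
    list(calls = do.call(rbind, calls) %||% empty_sv(),
         truth = do.call(rbind, truth) %||% empty_sv(truth = TRUE))
  })
  ## shuffle call order so downstream must not rely on it
  out$calls <- with_substream(config$seed, "sv-shuffle",
                              out$calls[sample.int(nrow(out$calls)), , drop = FALSE])
  rownames(out$calls) <- rownames(out$truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out$calls, file.path(dir, "sv_calls.tsv"), sep = "\t")
    data.table::fwrite(out$truth, file.path(dir, "sv_truth.tsv"), sep = "\t")
  }
  out
}

empty_sv <- function(truth = FALSE) {
  df <- data.frame(sample = character(), sv_type = character(),
                   contig = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  if (truth) df$n_source_calls <- integer()
  df
}

## Split [start, end) into 1-3 source intervals, pairwise chained by >=1 bp
## overlaps, whose union is exactly [start, end).
split_into_overlapping <- function(start, end) {
  len <- end - start
  k <- if (len < 20L) 1L else sample.int(3L, 1L)
  if (k == 1L) return(data.frame(start = start, end = end))
  cuts <- sort(sample((start + 5L):(end - 5L), k - 1L))
  ov <- pmin(3L, pmax(1L, floor(len / 10L)))  # overlap depth at each cut
  s <- c(start, cuts - ov)
  e <- c(cuts + ov, end)
  data.frame(start = as.integer(s), end = as.integer(e))
}

#' Simulate assembly-vs-reference coverage with planted gaps
#'
#' Gaps (uncovered reference regions) are planted first — a mix of large
#' (> `min_len`) and sub-threshold ones, some overlapping a planted
#' centromere — and coverage is emitted as their complement. The truth
#' sidecar lists the gaps that qualify as patch regions (> `min_len` bp,
#' zero centromere overlap), straight from the plan.
#'
#' @param config a [sim_config()] (seed used).
#' @param contig_lengths reference contigs; defaults to two 10 Mb contigs
#'   (gap logic needs room for > 800 kb intervals).
#' @param min_len patch length threshold used to label the truth (the caller
#'   under test applies its own threshold).
#' @param dir optional output directory (`coverage.bed`, `centromeres.bed`,
#'   `gaps_truth.tsv`).
#' @return list: `coverage`, `centromeres`, `gaps` (all planted gaps),
#'   `truth` (qualifying patch regions), `contig_lengths`.
#' @export
simulate_alignment_coverage <- function(config,
                                        contig_lengths = c(ref1 = 1e7, ref2 = 1e7),
                                        min_len = 8e5, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_substream(config$seed, "coverage", {
    gaps <- list(); cents <- list()
    for (ctg in names(contig_lengths)) {
      len <- contig_lengths[[ctg]]
      ## one centromere in the middle third
      c_start <- round(len * stats::runif(1, 0.38, 0.45))
      c_end <- c_start + round(len * 0.05)
      cents[[ctg]] <- data.frame(contig = ctg, start = c_start, end = c_end)
      ## three gaps: one large clean, one sub-threshold, one large in centromere
      g1 <- round(stats::runif(1, 0.05, 0.15) * len)
      l1 <- round(stats::runif(1, min_len * 1.1, min_len * 1.8))
      g2 <- round(stats::runif(1, 0.65, 0.75) * len)
      l2 <- round(stats::runif(1, min_len * 0.3, min_len * 0.8))
      g3 <- c_start + 1000
      l3 <- round(min_len * 1.2)
      gaps[[ctg]] <- data.frame(
        contig = ctg,
        start = c(g1, g2, g3), end = c(g1 + l1, g2 + l2, g3 + l3),
        in_centromere = c(FALSE, FALSE, TRUE))
    }
    gaps <- do.call(rbind, gaps); cents <- do.call(rbind, cents)
    list(gaps = gaps, cents = cents)
  })
  gaps <- out$gaps[order(out$gaps$contig, out$gaps$start), ]
  ## coverage = complement of the planted gaps
  gr_gaps <- intervals_to_granges(gaps)
  full <- GenomicRanges::GRanges(names(contig_lengths),
                                 IRanges::IRanges(1L, as.integer(contig_lengths)))
  coverage <- granges_to_intervals(GenomicRanges::setdiff(full, gr_gaps))
  cent_gr <- intervals_to_granges(out$cents)
  ov <- IRanges::overlapsAny(intervals_to_granges(gaps), cent_gr)
  truth <- gaps[(gaps$end - gaps$start) > min_len & !ov,
                c("contig", "start", "end")]
  rownames(gaps) <- rownames(truth) <- rownames(coverage) <- NULL
  res <- list(coverage = coverage, centromeres = out$cents,
              gaps = gaps[c("contig", "start", "end")], truth = truth,
              contig_lengths = contig_lengths)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bed3(res$coverage, file.path(dir, "coverage.bed"))
    write_bed3(res$centromeres, file.path(dir, "centromeres.bed"))
    data.table::fwrite(res$truth, file.path(dir, "gaps_truth.tsv"), sep = "\t")
  }
  res
}

#' Simulate phase-block annotations and gene spans with known summaries
#'
#' The summary numbers (phased counts, single-block gene fraction) are fixed
#' first and a variant/gene layout realizing them exactly is constructed:
#' each eligible gene (< 100 kb, >= 2 heterozygous sites) is either phased
#' into one block or deliberately split/unphased; extra ineligible genes
#' (too long, or a single het) and intergenic variants are added around them.
#'
#' @param config a [sim_config()] (seed used).
#' @param n_variants total variants; heterozygous fraction is ~2/3.
#' @param target_phased_frac fraction of variants carrying a phase set.
#' @param n_genes_single,n_genes_split eligible genes phased into one block /
#'   into two blocks.
#' @param dir optional output directory (`phased.tsv`, `genes.tsv`,
#'   `phase_truth.tsv`).
#' @return list: `variants` (contig, pos, zygosity, phase_block_id),
#'   `genes` (gene_id, contig, start, end), `truth` (n_phased, n_total,
#'   n_eligible_genes, n_single_block).
#' @export
simulate_phase_annotations <- function(config, n_variants = 2000L,
                                       target_phased_frac = 0.957,
                                       n_genes_single = 18L,
                                       n_genes_split = 2L, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ctg <- "chr1"
  n_phased <- round(n_variants * target_phased_frac)
  with_substream(config$seed, "phase", {
    gene_slot <- 120000L
    n_genes <- n_genes_single + n_genes_split + 2L  # + long + single-het gene
    genes <- data.frame(
      gene_id = sprintf("G%03d", seq_len(n_genes)),
      contig = ctg,
      start = (seq_len(n_genes) - 1L) * gene_slot + 1000L,
      stringsAsFactors = FALSE)
    kind <- c(rep("single", n_genes_single), rep("split", n_genes_split),
              "toolong", "onehet")
    genes$end <- genes$start + as.integer(stats::runif(n_genes, 20000, 80000))
    ## 1-based inclusive length = end - start + 1 = 100000 exactly: ineligible
    genes$end[kind == "toolong"] <- genes$start[kind == "toolong"] + 99999L
    variants <- list(); block <- 0L
    unphased_budget <- n_variants - n_phased
    for (i in seq_len(n_genes)) {
      n_het <- if (kind[i] == "onehet") 1L else sample(3:6, 1L)
      pos <- sort(sample(genes$start[i]:genes$end[i], n_het))
      block <- block + 1L
      pb <- rep(sprintf("PB%04d", block), n_het)
      if (kind[i] == "split") {            # second half in a different block
        block <- block + 1L
        pb[(n_het %/% 2 + 1L):n_het] <- sprintf("PB%04d", block)
      }
      variants[[i]] <- data.frame(contig = ctg, pos = pos, zygosity = "het",
                                  phase_block_id = pb, stringsAsFactors = FALSE)
    }
    v <- do.call(rbind, variants)
    ## filler variants outside genes to reach the exact planned counts
    n_fill <- n_variants - nrow(v)
    if (n_fill < unphased_budget)
      stop_popref("not enough filler variants to realize target_phased_frac")
    fill_pos <- n_genes * gene_slot + seq_len(n_fill) * 50L
    fill_phased <- c(rep(TRUE, n_fill - unphased_budget),
                     rep(FALSE, unphased_budget))
    fill <- data.frame(
      contig = ctg, pos = fill_pos,
      zygosity = "het",   # unphased hets are the realistic dropout mode
      phase_block_id = ifelse(fill_phased, "PB9999", NA_character_),
      stringsAsFactors = FALSE)
    v <- rbind(v, fill)
    truth <- data.frame(n_phased = n_phased, n_total = n_variants,
                        n_eligible_genes = n_genes_single + n_genes_split,
                        n_single_block = n_genes_single)
    res <- list(variants = v, genes = genes[c("gene_id", "contig", "start", "end")],
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(res$variants, file.path(dir, "phased.tsv"), sep = "\t")
      data.table::fwrite(res$genes, file.path(dir, "genes.tsv"), sep = "\t")
      data.table::fwrite(truth, file.path(dir, "phase_truth.tsv"), sep = "\t")
    }
    res
  })
}

#' Simulate per-individual runs of homozygosity
#'
#' Segment lengths are drawn on both sides of the 5 Mb threshold on a virtual
#' long chromosome (test-scale cohort contigs cannot hold multi-Mb runs). The
#' truth is arithmetic on the plan: per sample, the sum of planted lengths
#' strictly greater than `min_len`.
#'
#' @param config a [sim_config()] (seed, n_samples used).
#' @param n_segments segments per sample.
#' @param contig_length virtual chromosome length.
#' @param min_len threshold used for the truth column.
#' @param dir optional output directory (`roh.tsv`, `roh_truth.tsv`).
#' @return list: `segments` (sample, contig, start, end), `truth`
#'   (sample, total_long_bp).
#' @export
simulate_roh <- function(config, n_segments = 6L, contig_length = 2.49e8,
                         min_len = 5e6, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  with_substream(config$seed, "roh", {
    segs <- lapply(samples, function(s) {
      if (n_segments == 0L) return(NULL)
      lens <- round(stats::runif(n_segments, 5e5, 1.2e7))
      slot <- floor(contig_length / n_segments)
      starts <- (seq_len(n_segments) - 1L) * slot +
        vapply(pmax(slot - lens, 1), function(m) sample.int(m, 1L), 1L)
      data.frame(sample = s, contig = "chr1",
                 start = starts, end = starts + lens, stringsAsFactors = FALSE)
    })
    segs <- do.call(rbind, segs) %||%
      data.frame(sample = character(), contig = character(),
                 start = numeric(), end = numeric())
    truth <- if (nrow(segs)) {
      lens <- segs$end - segs$start
      agg <- tapply(lens * (lens > min_len), segs$sample, sum)
      data.frame(sample = names(agg), total_long_bp = as.numeric(agg))
    } else data.frame(sample = character(), total_long_bp = numeric())
    res <- list(segments = segs, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(segs, file.path(dir, "roh.tsv"), sep = "\t")
      data.table::fwrite(truth, file.path(dir, "roh_truth.tsv"), sep = "\t")
    }
    res
  })
}

#' Simulate an alternative assembly FASTA plus alignment blocks for patching
#'
#' For each planted qualifying gap a dedicated alternative-assembly contig is
#' generated, with the gap's sequence embedded at a known offset, and a
#' colinear alignment block (ref interval -> alt interval, random strand) is
#' emitted. The truth is the embedded sequence itself.
#'
#' @param coverage_sim output of [simulate_alignment_coverage()].
#' @param config a [sim_config()] (seed used).
#' @param dir optional output directory (`alt_assembly.fasta`,
#'   `alt_blocks.tsv`).
#' @return list: `alt_fasta` (DNAStringSet), `blocks` (data.frame), `truth`
#'   (data.frame contig, start, end, sequence — the expected patches).
#' @export
simulate_alt_assembly <- function(coverage_sim, config, dir = NULL) {
  gaps <- coverage_sim$truth
  with_substream(config$seed, "altasm", {
    seqs <- character(nrow(gaps)); blocks <- list(); truths <- character(nrow(gaps))
    for (i in seq_len(nrow(gaps))) {
      len <- gaps$end[i] - gaps$start[i]
      pad <- 500L
      full <- paste(sample(c("A", "C", "G", "T"), len + 2L * pad, replace = TRUE),
                    collapse = "")
      patch_fwd <- substr(full, pad + 1L, pad + len)
      strand <- sample(c("+", "-"), 1L)
      truths[i] <- if (strand == "+") patch_fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(patch_fwd)))
      seqs[i] <- full
      blocks[[i]] <- data.frame(
        ref_contig = gaps$contig[i], ref_start = gaps$start[i],
        ref_end = gaps$end[i], alt_contig = sprintf("alt%02d", i),
        alt_start = pad, alt_end = pad + len, strand = strand,
        stringsAsFactors = FALSE)
    }
    alt <- Biostrings::DNAStringSet(seqs)
    names(alt) <- sprintf("alt%02d", seq_len(nrow(gaps)))
    blocks <- do.call(rbind, blocks) %||% data.frame()
    truth <- cbind(gaps, sequence = truths, stringsAsFactors = FALSE)
    res <- list(alt_fasta = alt, blocks = blocks, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(alt, file.path(dir, "alt_assembly.fasta"))
      data.table::fwrite(blocks, file.path(dir, "alt_blocks.tsv"), sep = "\t")
    }
    res
  })
}

write_bed3 <- function(df, path) {
  data.table::fwrite(df[c("contig", "start", "end")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

read_bed3 <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(df)[1:3] <- c("contig", "start", "end")
  df[1:3]
}
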