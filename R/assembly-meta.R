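#' Reference regions not covered by the base assembly
#'
#' Complement of the alignment coverage within each reference contig, as
#' maximal 0-based half-open intervals. Coverage intervals may be unsorted or
#' overlapping (they are unioned first), but must lie within contig bounds.
#'
#' @param coverage data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. read from a BED file.
#' @param contig_lengths named vector of reference contig lengths.
#' @return data.frame of gaps: contig, start, end, length.
#' @export
uncovered_gaps <- function(coverage, contig_lengths) {
  if (nrow(coverage)) {
    if (!all(coverage$contig %in% names(contig_lengths)))
      stop_popref("coverage references a contig without a length")
    if (any(coverage$start < 0) ||
        any(coverage$end > contig_lengths[coverage$contig]))
      stop_popref("coverage interval exceeds contig bounds")
  }
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    cov <- coverage[coverage$contig == ctg, , drop = FALSE]
    if (!nrow(cov)) {
      return(data.frame(contig = ctg, start = 0L, end = len))
    }
    full <- GenomicRanges::GRanges(ctg, IRanges::IRanges(1L, len))
    gaps <- GenomicRanges::setdiff(full, intervals_to_granges(cov))
    if (!length(gaps)) return(NULL)
    granges_to_intervals(gaps)
  })
  res <- do.call(rbind, out) %||%
    data.frame(contig = character(), start = integer(), end = integer())
  res$length <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Select patchable gap regions
#'
#' Keeps gaps strictly longer than `min_len` whose overlap with any
#' centromere interval does not exceed `max_centromere_overlap` bp (default
#' 0: any overlap excludes the gap).
#'
#' @param gaps output of [uncovered_gaps()].
#' @param centromeres data.frame `contig`, `start`, `end` (0-based half-open).
#' @param min_len length threshold in bp (strict >). Default 800 kb.
#' @param max_centromere_overlap tolerated centromere overlap in bp.
#' @return filtered gaps data.frame.
#' @export
select_patch_regions <- function(gaps, centromeres, min_len = 8e5,
                                 max_centromere_overlap = 0L) {
  if (!nrow(gaps)) return(gaps)
  keep_len <- gaps$length > min_len
  ov_bp <- rep(0L, nrow(gaps))
  if (nrow(centromeres)) {
    g <- intervals_to_granges(gaps)
    cg <- GenomicRanges::reduce(intervals_to_granges(centromeres))
    hits <- GenomicRanges::findOverlaps(g, cg)
    if (length(hits)) {
      w <- GenomicRanges::width(IRanges::pintersect(
        g[S4Vectors::queryHits(hits)], cg[S4Vectors::subjectHits(hits)]))
      ov <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov_bp[as.integer(names(ov))] <- as.integer(ov)
    }
  }
  out <- gaps[keep_len & ov_bp <= max_centromere_overlap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_alt_blocks <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("ref_contig", "ref_start", "ref_end", "alt_contig",
            "alt_start", "alt_end", "strand")
  if (!all(need %in% names(df)))
    stop_popref("alignment blocks need columns %s", paste(need, collapse = ", "))
  df
}

#' Extract patch sequences from an alternative assembly
#'
#' Each gap region must be contained in exactly one colinear alignment block
#' (reference interval -> alternative-assembly interval of equal length); the
#' aligned alternative subsequence is extracted and, for minus-strand blocks,
#' reverse-complemented. Regions covered by no block, or spanning several,
#' are reported as unpatchable rather than guessed.
#'
#' @param regions gaps from [select_patch_regions()].
#' @param alt_blocks data.frame: `ref_contig`, `ref_start`, `ref_end`,
#'   `alt_contig`, `alt_start`, `alt_end` (0-based half-open, equal lengths),
#'   `strand` ("+"/"-"). A path to a PAF-like TSV is also accepted.
#' @param alt_fasta alternative assembly as a `DNAStringSet` or FASTA path.
#' @return list: `patches` (data.frame contig, start, end, alt_contig,
#'   alt_start, alt_end, strand, sequence) and `unpatchable` (data.frame with
#'   a `reason` column).
#' @export
extract_patches <- function(regions, alt_blocks, alt_fasta) {
  if (is.character(alt_blocks)) alt_blocks <- read_alt_blocks(alt_blocks)
  if (is.character(alt_fasta)) alt_fasta <- Biostrings::readDNAStringSet(alt_fasta)
  names(alt_fasta) <- sub("\\s.*$", "", names(alt_fasta))
  if (nrow(alt_blocks) &&
      any(alt_blocks$ref_end - alt_blocks$ref_start !=
          alt_blocks$alt_end - alt_blocks$alt_start))
    stop_popref("alignment blocks must map equal-length intervals (colinear 1:1)")
  patches <- list(); unpatch <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    contains <- alt_blocks$ref_contig == r$contig &
      alt_blocks$ref_start <= r$start & r$end <= alt_blocks$ref_end
    touches <- alt_blocks$ref_contig == r$contig &
      alt_blocks$ref_start < r$end & r$start < alt_blocks$ref_end
    if (sum(contains) == 1L) {
      b <- alt_blocks[which(contains), ]
      off <- r$start - b$ref_start
      len <- r$end - r$start
      if (b$strand == "+") {
        a_start <- b$alt_start + off
      } else {
        a_start <- b$alt_end - off - len
      }
      seqv <- Biostrings::subseq(alt_fasta[[b$alt_contig]],
                                 start = a_start + 1L, width = len)
      if (b$strand == "-") seqv <- Biostrings::reverseComplement(seqv)
      patches[[length(patches) + 1L]] <- data.frame(
        contig = r$contig, start = r$start, end = r$end,
        alt_contig = b$alt_contig, alt_start = a_start,
        alt_end = a_start + len, strand = b$strand,
        sequence = as.character(seqv), stringsAsFactors = FALSE)
    } else {
      reason <- if (sum(touches) == 0L) "no alignment block"
                else if (sum(contains) > 1L) "multiple containing blocks"
                else "spans multiple blocks"
      unpatch[[length(unpatch) + 1L]] <- cbind(
        r[c("contig", "start", "end")], reason = reason)
    }
  }
  empty_p <- data.frame(contig = character(), start = integer(),
                        end = integer(), alt_contig = character(),
                        alt_start = integer(), alt_end = integer(),
                        strand = character(), sequence = character())
  empty_u <- data.frame(contig = character(), start = integer(),
                        end = integer(), reason = character())
  list(patches = do.call(rbind, patches) %||% empty_p,
       unpatchable = do.call(rbind, unpatch) %||% empty_u)
}

#' Weighted count of homozygous assembly-vs-read differences
#'
#' Sums, over homozygous differences with quality at least `qual_min`: 1 for
#' a single-nucleotide difference, |len(ref) - len(alt)| for an indel, and
#' the number of differing positions for an equal-length multi-base
#' substitution. Heterozygous differences reflect the diploid donor, not
#' assembly error, and are excluded.
#'
#' @param diffs data.frame: `ref_allele`, `alt_allele`, `quality` (>= 0),
#'   `zygosity` ("hom"/"het").
#' @param qual_min quality floor (inclusive). Default 10.
#' @return weighted difference count in bp.
#' @export
count_homozygous_differences <- function(diffs, qual_min = 10) {
  if (any(diffs$quality < 0)) stop_popref("qualities must be >= 0")
  keep <- diffs$zygosity == "hom" & diffs$quality >= qual_min
  d <- diffs[keep, , drop = FALSE]
  if (!nrow(d)) return(0)
  lr <- nchar(d$ref_allele); la <- nchar(d$alt_allele)
  w <- abs(lr - la)
  eq <- lr == la
  w[eq] <- vapply(which(eq), function(i) {
    sum(utf8ToInt(d$ref_allele[i]) != utf8ToInt(d$alt_allele[i]))
  }, numeric(1L))
  sum(w)
}

#' Base-level assembly quality (QV)
#'
#' QV = -10 * log10(weighted_diff_count / effective_genome_size). With zero
#' differences the error rate is below the resolution of the read set; the
#' report then carries the detection ceiling -10*log10(1/effective_size) and
#' is flagged as a lower bound.
#'
#' @param weighted_count weighted homozygous-difference count from
#'   [count_homozygous_differences()].
#' @param effective_size effective genome size in bp (> 0): the number of
#'   assembly bases with short-read coverage.
#' @return object of class `qv_report`: `weighted_diff_count`,
#'   `effective_genome_size`, `qv`, `lower_bound`.
#' @export
assembly_qv <- function(weighted_count, effective_size) {
  if (!is.numeric(effective_size) || effective_size <= 0)
    stop_popref("effective_size must be > 0")
  if (weighted_count < 0) stop_popref("weighted_count must be >= 0")
  lb <- weighted_count == 0
  qv <- if (lb) -10 * log10(1 / effective_size)
        else -10 * log10(weighted_count / effective_size)
  structure(list(weighted_diff_count = weighted_count,
                 effective_genome_size = effective_size,
                 qv = qv, lower_bound = lb), class = "qv_report")
}

#' @export
print.qv_report <- function(x, ...) {
  cat(sprintf("QV %s%.2f (%s diff bp / %s bp effective size)\n",
              if (x$lower_bound) ">= " else "", x$qv,
              format(x$weighted_diff_count, big.mark = ",", scientific = FALSE),
              format(x$effective_genome_size, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Effective genome size from a depth track
#'
#' Helper implementing "sum of bases with short-read coverage": the number of
#' bases with depth at or above `depth_min` (default 1).
#'
#' @param depth a [depth_matrix()] (single-sample track expected; with several
#'   columns a base counts when any sample covers it) or an integer vector.
#' @param depth_min minimum depth for a base to count.
#' @return number of covered bases.
#' @export
effective_genome_size <- function(depth, depth_min = 1L) {
  v <- if (inherits(depth, "depth_matrix")) {
    apply(depth$depth, 1L, max)
  } else as.integer(depth)
  sum(v >= depth_min)
}
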