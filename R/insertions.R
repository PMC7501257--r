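#' Per-base per-sample depth matrix
#'
#' Dense container for read depth of previously unmapped reads over one
#' assembly contig: one row per base (0-based offset `start`), one column per
#' sample. Absent data is depth 0; all samples cover the same span.
#'
#' @param contig contig name.
#' @param depth integer matrix, bases x samples, values >= 0.
#' @param start 0-based offset of the first row on the contig.
#' @param samples sample names (defaults to matrix colnames).
#' @return object of class `depth_matrix`.
#' @export
depth_matrix <- function(contig, depth, start = 0L, samples = colnames(depth)) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (any(depth < 0, na.rm = TRUE) || anyNA(depth))
    stop_popref("depths must be non-negative integers (use 0 for absent data)")
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(depth)))
  colnames(depth) <- samples
  structure(list(contig = contig, start = as.integer(start), depth = depth,
                 samples = samples), class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("depth_matrix %s:[%d,%d) x %d samples\n", x$contig, x$start,
              x$start + nrow(x$depth), length(x$samples)))
  invisible(x)
}

#' Per-base count of samples passing the depth threshold
#'
#' @param depth a [depth_matrix()].
#' @param depth_min depth threshold.
#' @param strict `TRUE` counts samples with depth *strictly greater than*
#'   `depth_min` ("more than 5 reads"); `FALSE` uses >=.
#' @return integer vector, one count per base.
#' @export
samples_passing <- function(depth, depth_min = 5L, strict = TRUE) {
  stopifnot(inherits(depth, "depth_matrix"))
  cmp <- if (strict) depth$depth > depth_min else depth$depth >= depth_min
  as.integer(rowSums(cmp))
}

#' Call non-reference insertion regions from depth tracks
#'
#' An insertion region is a maximal run of consecutive bases at which at
#' least `min_samples` samples exceed the depth threshold, kept iff the run
#' is at least `min_len` bp long. The qualifying sample *set* may vary along
#' the run — the criterion is per base; `n_supporting_samples` reports the
#' minimum per-base count over the region (conservative support).
#'
#' @param depth a [depth_matrix()] or a list of them (one per contig).
#' @param min_len minimum region length in bp (inclusive, "at least 500 bp").
#' @param depth_min per-base depth threshold.
#' @param min_samples samples required per base (inclusive, "10 or more").
#' @param strict see [samples_passing()]; default strict ">".
#' @return data.frame: contig, start, end (0-based half-open), length,
#'   n_supporting_samples, sorted by (contig, start).
#' @export
call_insertion_regions <- function(depth, min_len = 500L, depth_min = 5L,
                                   min_samples = 10L, strict = TRUE) {
  stopifnot(min_len > 0, depth_min > 0, min_samples > 0)
  if (inherits(depth, "depth_matrix")) depth <- list(depth)
  out <- lapply(depth, function(dm) {
    counts <- samples_passing(dm, depth_min = depth_min, strict = strict)
    qual <- counts >= min_samples
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    data.frame(
      contig = dm$contig,
      start = dm$start + starts[keep] - 1L,
      end = dm$start + ends[keep],
      length = r$lengths[keep],
      n_supporting_samples = vapply(which(keep), function(i) {
        min(counts[starts[i]:ends[i]])
      }, integer(1L)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out) %||%
    data.frame(contig = character(), start = integer(), end = integer(),
               length = integer(), n_supporting_samples = integer())
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize called insertion regions
#'
#' @param regions output of [call_insertion_regions()].
#' @return list: `n_regions`, `total_bp`, and the per-region table (with
#'   sample support) in deterministic (contig, start) order.
#' @export
summarize_insertions <- function(regions) {
  regions <- regions[order(regions$contig, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  list(n_regions = nrow(regions),
       total_bp = sum(regions$length),
       regions = regions)
}

#' Write one BedGraph per sample from depth tracks
#'
#' Runs of equal depth are collapsed; zero-depth runs are written too, so a
#' round trip restores the full span.
#'
#' @param tracks list of [depth_matrix()] objects.
#' @param dir output directory; files are named `depth_<sample>.bedgraph`.
#' @return character vector of file paths, invisibly.
#' @export
write_depth_bedgraphs <- function(tracks, dir) {
  if (inherits(tracks, "depth_matrix")) tracks <- list(tracks)
  samples <- tracks[[1L]]$samples
  paths <- file.path(dir, sprintf("depth_%s.bedgraph", samples))
  for (j in seq_along(samples)) {
    lines <- unlist(lapply(tracks, function(dm) {
      r <- rle(as.integer(dm$depth[, j]))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      sprintf("%s\t%d\t%d\t%d", dm$contig, dm$start + starts,
              dm$start + ends, r$values)
    }))
    writeLines(lines, paths[j])
  }
  invisible(paths)
}

#' Read per-sample BedGraph files into depth matrices
#'
#' @param paths BedGraph files, one per sample.
#' @param contig_lengths named vector: contigs and their lengths; bases not
#'   covered by any record get depth 0.
#' @param samples sample names (default: file names stripped of
#'   `depth_`/`.bedgraph`).
#' @return named list of [depth_matrix()], one per contig.
#' @export
read_bedgraph_depth <- function(paths, contig_lengths, samples = NULL) {
  if (is.null(samples))
    samples <- sub("^depth_", "", sub("\\.bedgraph$", "", basename(paths)))
  tracks <- lapply(names(contig_lengths), function(ctg) {
    n <- as.integer(contig_lengths[[ctg]])
    m <- matrix(0L, nrow = n, ncol = length(paths))
    for (j in seq_along(paths)) {
      gr <- rtracklayer::import(paths[j], format = "bedGraph")
      gr <- gr[as.character(GenomicRanges::seqnames(gr)) == ctg]
      if (!length(gr)) next
      s <- GenomicRanges::start(gr); w <- GenomicRanges::width(gr)
      m[sequence(w, from = s), j] <- rep.int(as.integer(gr$score), w)
    }
    depth_matrix(ctg, m, start = 0L, samples = samples)
  })
  names(tracks) <- names(contig_lengths)
  tracks
}
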