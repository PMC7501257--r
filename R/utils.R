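## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages in reports are rounded half away from zero (so 28.5 -> 29),
#' matching the "~29% / ~71%" style of proxy-sharing summaries, rather than
#' base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Deterministic per-stream sub-seed from one global seed, so independent
## generator stages do not share a random stream. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483629)
}

## Run expr under a temporary RNG state seeded per stream.
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  expr
}

## Site key used everywhere a variant must be matched across tables:
## contig:pos:ref:alt after multi-allelic splitting.
site_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

stop_popref <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

## data.frame of 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(df, contig = "contig",
                                 start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = df[[contig]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]])
  )
}

granges_to_intervals <- function(gr) {
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
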