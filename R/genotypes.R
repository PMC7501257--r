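#' Multi-sample genotype table
#'
#' Lightweight container for diploid genotypes at biallelic sites: a site
#' table plus an integer dosage matrix (number of alternative alleles, 0/1/2,
#' `NA` = missing genotype). Multi-allelic records are represented as one row
#' per alternative allele (see [read_vcf_genotypes()]).
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` and optionally `rsid` (`NA` = no identifier).
#' @param dosage integer matrix, `nrow(sites)` x n_samples, values in
#'   \{0,1,2,NA\}.
#' @param samples character vector of sample names (defaults to matrix
#'   colnames).
#' @return object of class `geno_table` with elements `sites`, `dosage`,
#'   `samples`.
#' @export
geno_table <- function(sites, dosage, samples = colnames(dosage)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop_popref("sites must have columns %s", paste(need, collapse = ", "))
  if (is.null(sites$rsid)) sites$rsid <- NA_character_
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites))
    stop_popref("dosage has %d rows but sites has %d", nrow(dosage), nrow(sites))
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop_popref("non-diploid dosage %d at %s:%d", dosage[bad][1L],
                sites$contig[i[1L]], sites$pos[i[1L]])
  }
  ok_allele <- grepl("^[ACGT]+$", sites$ref) & grepl("^[ACGT]+$", sites$alt)
  if (!all(ok_allele))
    stop_popref("alleles must be non-empty over {A,C,G,T} (first bad row %d)",
                which(!ok_allele)[1L])
  if (any(sites$pos < 1)) stop_popref("positions must be >= 1")
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(dosage)))
  colnames(dosage) <- samples
  rownames(sites) <- NULL
  structure(list(sites = sites, dosage = dosage, samples = samples),
            class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  cat(sprintf("geno_table: %d sites x %d samples, %.1f%% missing\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$dosage)

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Write a genotype table as a multi-sample VCF
#'
#' Plain-text VCFv4.2 with GT-only FORMAT; missing genotypes are "./.".
#'
#' @param gt a [geno_table()].
#' @param path output file path (uncompressed `.vcf`).
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path, contig_lengths = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popref",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gt$samples), collapse = "\t"))
  gtmat <- matrix(dosage_to_gt(gt$dosage), nrow = nrow(gt$dosage))
  body <- paste(
    gt$sites$contig, gt$sites$pos,
    ifelse(is.na(gt$sites$rsid), ".", gt$sites$rsid),
    gt$sites$ref, gt$sites$alt, ".", "PASS", ".", "GT",
    apply(gtmat, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype table
#'
#' Uses \pkg{VariantAnnotation} to parse the file, then converts GT calls to
#' alternative-allele dosages. Multi-allelic records are split into one
#' biallelic row per alternative allele; at a split row the dosage counts
#' only that allele. Half-missing calls (e.g. "./1") and any call with a "."
#' allele are treated as missing. Both "/" and "|" separators are accepted.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [geno_table()].
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gtc <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtc)) stop_popref("VCF %s has no GT field", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)   # DNAStringSetList
  ids <- names(rr)
  rsid <- ifelse(grepl("^rs", ids %||% character()), ids, NA_character_)

  n_alt <- lengths(alts)
  row_of <- rep.int(seq_along(n_alt), n_alt)   # expanded row -> source record
  allele_ix <- sequence(n_alt)                 # which ALT within the record

  ## parse GT strings once per record into two allele-index columns
  gsplit <- strsplit(as.vector(gtc), "[/|]", perl = FALSE)
  a1 <- vapply(gsplit, function(g) g[1L] %||% ".", "")
  a2 <- vapply(gsplit, function(g) if (length(g) >= 2L) g[2L] else ".", "")
  dim(a1) <- dim(gtc); dim(a2) <- dim(gtc)
  miss <- a1 == "." | a2 == "."

  dos <- function(rows, k) {
    ## dosage of ALT allele index k for the given source rows
    d <- (a1[rows, , drop = FALSE] == as.character(k)) +
         (a2[rows, , drop = FALSE] == as.character(k))
    d[miss[rows, , drop = FALSE]] <- NA_integer_
    storage.mode(d) <- "integer"
    d
  }
  dosage <- matrix(NA_integer_, nrow = length(row_of), ncol = ncol(gtc))
  for (k in sort(unique(allele_ix))) {
    sel <- allele_ix == k
    dosage[sel, ] <- dos(row_of[sel], k)
  }
  sites <- data.frame(
    contig = contig[row_of],
    pos = pos[row_of],
    ref = ref[row_of],
    alt = as.character(unlist(alts)),
    rsid = rsid[row_of],
    stringsAsFactors = FALSE
  )
  geno_table(sites, dosage, samples = colnames(gtc))
}

#' Read an external-panel allele-frequency table
#'
#' TSV with columns `contig`, `pos`, `ref`, `alt`, `panel`, `af`. A site/panel
#' combination absent from the table means "not detected in that panel".
#'
#' @param path TSV file.
#' @return data.frame with the five key columns plus a `key` column.
#' @export
read_panel_af <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("contig", "pos", "ref", "alt", "panel", "af")
  if (!all(need %in% names(df)))
    stop_popref("panel AF table must have columns %s", paste(need, collapse = ", "))
  if (any(df$af < 0 | df$af > 1)) stop_popref("panel AFs must be in [0,1]")
  df$key <- site_key(df$contig, df$pos, df$ref, df$alt)
  df
}
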