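#' Simulation configuration
#'
#' One configuration object drives every generator. Defaults describe the
#' emulated study cohort: 110 individuals of mixed genotyping coverage
#' (expressed as per-genotype dropout), allele frequencies uniform on
#' \[0.05, 0.95\], haplotype blocks of 100 kb that recombine freely at block
#' boundaries, and a low background depth for the unmapped-read tracks.
#'
#' @param seed integer master seed; every generator derives an independent
#'   sub-stream from it, so a fixed config yields byte-identical outputs.
#' @param n_samples number of diploid individuals.
#' @param n_sites number of variant sites, placed on a regular grid across
#'   contigs proportionally to contig length.
#' @param contig_lengths named integer vector, contig name -> length in bp.
#' @param af_law allele-frequency sampling law: `list(type = "uniform", lo, hi)`
#'   or `list(type = "fixed", af = <vector or scalar>)` for founder-allele
#'   Bernoulli probabilities.
#' @param n_founders size of the founder-haplotype pool per block. Small pools
#'   give strong within-block LD.
#' @param ld_block_length haplotype-block length in bp; `Inf` is the
#'   single-block limit (whole contig is one block).
#' @param recomb_between_blocks probability that a haplotype redraws its
#'   founder at a block boundary (1 = blocks independent).
#' @param missing_rate per-genotype dropout probability.
#' @param depth_mean background Poisson mean for depth tracks (reads).
#' @param insertion_plan data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), `n_carrier_samples`, `carrier_depth`: regions where
#'   exactly `n_carrier_samples` samples get depth exactly `carrier_depth`.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 110L,
                       n_sites = 2000L,
                       contig_lengths = c(chr1 = 2e6),
                       af_law = list(type = "uniform", lo = 0.05, hi = 0.95),
                       n_founders = 6L,
                       ld_block_length = 1e5,
                       recomb_between_blocks = 1,
                       missing_rate = 0.05,
                       depth_mean = 3,
                       insertion_plan = NULL) {
  stopifnot(is_count(seed), is_count(n_samples), is_count(n_sites),
            is_count(n_founders), n_founders >= 2)
  if (is.null(names(contig_lengths)) || any(contig_lengths <= 0))
    stop_popref("contig_lengths must be a named vector of positive lengths")
  for (p in c(recomb_between_blocks, missing_rate)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_popref("probabilities must lie in [0,1]")
  }
  if (!is.infinite(ld_block_length) && ld_block_length < 1)
    stop_popref("ld_block_length must be >= 1 bp or Inf")
  if (depth_mean < 0) stop_popref("depth_mean must be >= 0")
  if (is.null(insertion_plan)) {
    insertion_plan <- data.frame(contig = character(), start = integer(),
                                 end = integer(), n_carrier_samples = integer(),
                                 carrier_depth = integer())
  }
  ip <- insertion_plan
  if (nrow(ip)) {
    if (!all(ip$contig %in% names(contig_lengths)))
      stop_popref("insertion_plan references unknown contig")
    lens <- contig_lengths[ip$contig]
    if (any(ip$start < 0) || any(ip$end > lens) || any(ip$start >= ip$end))
      stop_popref("insertion_plan intervals must lie within contig bounds")
    if (any(ip$n_carrier_samples > n_samples))
      stop_popref("n_carrier_samples exceeds n_samples")
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_sites = as.integer(n_sites),
                 contig_lengths = contig_lengths, af_law = af_law,
                 n_founders = as.integer(n_founders),
                 ld_block_length = ld_block_length,
                 recomb_between_blocks = recomb_between_blocks,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 insertion_plan = ip),
            class = "sim_config")
}

## Regular grid of site positions across contigs, proportional to length.
build_sites <- function(config) {
  lens <- config$contig_lengths
  share <- lens / sum(lens)
  n_i <- floor(config$n_sites * share)
  rem <- config$n_sites - sum(n_i)
  if (rem > 0) {  # largest remainders get the leftover sites
    frac <- config$n_sites * share - n_i
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_i[add] <- n_i[add] + 1L
  }
  if (any(n_i > lens)) stop_popref("more sites than bases on a contig")
  pos <- unlist(lapply(seq_along(lens), function(i) {
    if (n_i[i] == 0L) return(integer())
    as.integer(pmax(1, round(lens[i] * (seq_len(n_i[i]) - 0.5) / n_i[i])))
  }), use.names = FALSE)
  data.frame(contig = rep(names(lens), n_i), pos = pos,
             stringsAsFactors = FALSE)
}

draw_site_af <- function(config, n) {
  law <- config$af_law
  switch(law$type,
         uniform = stats::runif(n, law$lo, law$hi),
         fixed = rep_len(law$af, n),
         stop_popref("unknown af_law type '%s'", law$type))
}

## Founder haplotype pool over all sites: n_founders x n_sites 0/1 matrix.
draw_founders <- function(config, sites) {
  n <- nrow(sites)
  af <- draw_site_af(config, n)
  founders <- matrix(stats::rbinom(config$n_founders * n, 1L,
                                   rep(af, each = config$n_founders)),
                     nrow = config$n_founders)
  founders
}

## Block index per site (global, contiguous across contigs).
site_blocks <- function(config, sites) {
  if (is.infinite(config$ld_block_length)) {
    return(match(sites$contig, names(config$contig_lengths)))
  }
  if (config$ld_block_length > min(config$contig_lengths))
    stop_popref("ld_block_length exceeds shortest contig (%d bp); use Inf for the single-block limit",
                min(config$contig_lengths))
  within <- floor((sites$pos - 1) / config$ld_block_length)
  ## offset so block ids never collide across contigs
  key <- paste(sites$contig, within)
  match(key, unique(key))
}

## Copy haplotypes from the founder pool, one founder choice per block,
## Markov across consecutive blocks of a contig.
copy_haplotypes <- function(config, sites, founders) {
  blocks <- site_blocks(config, sites)
  n_hap <- 2L * config$n_samples
  ublocks <- unique(blocks)
  block_contig <- sites$contig[match(ublocks, blocks)]
  choice <- matrix(0L, nrow = length(ublocks), ncol = n_hap)
  for (b in seq_along(ublocks)) {
    fresh <- sample.int(config$n_founders, n_hap, replace = TRUE)
    if (b == 1L || block_contig[b] != block_contig[b - 1L]) {
      choice[b, ] <- fresh
    } else {
      recomb <- stats::runif(n_hap) < config$recomb_between_blocks
      choice[b, ] <- ifelse(recomb, fresh, choice[b - 1L, ])
    }
  }
  H <- matrix(0L, nrow = nrow(sites), ncol = n_hap)
  for (b in seq_along(ublocks)) {
    idx <- which(blocks == ublocks[b])
    H[idx, ] <- t(founders[choice[b, ], idx, drop = FALSE])
  }
  H
}

ref_alt_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Simulate a genotyped cohort with block-wise LD
#'
#' Haplotypes are piecewise copies of a small founder pool: within an LD
#' block every haplotype equals one founder, and founder choices recombine at
#' block boundaries with probability `recomb_between_blocks`. This yields
#' high r-squared within blocks and near-zero r-squared across blocks without
#' any coalescent machinery. Genotype dosage is the sum of two haplotypes;
#' genotypes then drop out independently at `missing_rate`. The true allele
#' frequency of a site is its founder-pool mean (founders are chosen
#' uniformly, so the observed allele count is Binomial(2n, true AF)).
#'
#' @param config a [sim_config()]; requires `n_samples >= 2`, `n_sites >= 1`.
#' @param dir optional output directory: writes `cohort.vcf` and the truth
#'   table `cohort_truth.tsv` (contig, pos, ref, alt, true_af).
#' @return list with `gt` (a [geno_table()]), `truth` (data.frame with
#'   `true_af`), and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 2 || config$n_sites < 1)
    stop_popref("need n_samples >= 2 and n_sites >= 1")
  sites <- build_sites(config)
  founders <- with_substream(config$seed, "founders", draw_founders(config, sites))
  res <- cohort_from_founders(config, sites, founders)
  if (!is.null(dir)) write_cohort_fixture(res, dir, "cohort")
  res
}

cohort_from_founders <- function(config, sites, founders, alleles = NULL) {
  H <- with_substream(config$seed, "haplotypes",
                      copy_haplotypes(config, sites, founders))
  dosage <- H[, seq(1L, ncol(H), 2L), drop = FALSE] +
            H[, seq(2L, ncol(H), 2L), drop = FALSE]
  if (config$missing_rate > 0) {
    dosage <- with_substream(config$seed, "missing", {
      drop <- matrix(stats::runif(length(dosage)) < config$missing_rate,
                     nrow = nrow(dosage))
      dosage[drop] <- NA_integer_
      dosage
    })
  }
  al <- alleles %||%
    with_substream(config$seed, "alleles", ref_alt_alleles(nrow(sites)))
  sites$ref <- al$ref
  sites$alt <- al$alt
  colnames(dosage) <- sprintf("S%03d", seq_len(config$n_samples))
  gt <- geno_table(sites, dosage)
  truth <- cbind(gt$sites[c("contig", "pos", "ref", "alt")],
                 true_af = colMeans(founders))
  list(gt = gt, truth = truth, config = config)
}

write_cohort_fixture <- function(res, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(res$gt, file.path(dir, paste0(stem, ".vcf")),
            contig_lengths = res$config$contig_lengths)
  data.table::fwrite(res$truth, file.path(dir, paste0(stem, "_truth.tsv")),
                     sep = "\t")
  invisible(dir)
}

#' Simulate two populations on shared sites
#'
#' Both populations use the same site grid and (with `shared_founders = TRUE`)
#' the same founder allele pool, but copy haplotypes under their own
#' `ld_block_length`. The population with shorter blocks has, in expectation,
#' fewer high-r-squared proxies per tag site — the LD-structure contrast that
#' limits GWAS transferability between ancestries.
#'
#' @param config_a,config_b [sim_config()]s; must agree on `n_sites` and
#'   `contig_lengths` (the site map).
#' @param shared_founders draw one founder pool (from `config_a`'s seed) used
#'   by both populations, so true allele frequencies coincide.
#' @param dir optional output directory (`pop_a.vcf`, `pop_b.vcf` + truths).
#' @return list with `a` and `b`, each as from [simulate_cohort()].
#' @export
simulate_two_populations <- function(config_a, config_b,
                                     shared_founders = TRUE, dir = NULL) {
  stopifnot(inherits(config_a, "sim_config"), inherits(config_b, "sim_config"))
  if (config_a$n_sites != config_b$n_sites ||
      !identical(config_a$contig_lengths, config_b$contig_lengths))
    stop_popref("configs must share n_sites and contig_lengths (same site map)")
  sites <- build_sites(config_a)
  f_a <- with_substream(config_a$seed, "founders", draw_founders(config_a, sites))
  f_b <- if (shared_founders) f_a else
    with_substream(config_b$seed, "founders", draw_founders(config_b, sites))
  ## one allele labelling for the shared site map: the two tables must
  ## describe the same variants
  al <- with_substream(config_a$seed, "alleles", ref_alt_alleles(nrow(sites)))
  a <- cohort_from_founders(config_a, sites, f_a, alleles = al)
  b <- cohort_from_founders(config_b, sites, f_b, alleles = al)
  if (!is.null(dir)) {
    write_cohort_fixture(a, dir, "pop_a")
    write_cohort_fixture(b, dir, "pop_b")
  }
  list(a = a, b = b)
}

#' Plant per-sample depth tracks with non-reference insertion regions
#'
#' Background depth is Poisson(`depth_mean`) per base per sample. Inside each
#' planted interval, exactly `n_carrier_samples` samples (chosen at random)
#' have depth exactly `carrier_depth` — sharp values so threshold semantics
#' can be tested at the boundary. Intended for assembly-contig scale (tens of
#' kb); the dense base-by-sample matrix is capped at 5e7 cells.
#'
#' @param config a [sim_config()] whose `insertion_plan` and `contig_lengths`
#'   describe the tracks.
#' @param dir optional output directory: one BedGraph per sample
#'   (`depth_<sample>.bedgraph`) plus `insertions_truth.tsv` (the plan).
#' @return list of [depth_matrix()] (one per contig) with the plan attached
#'   as attribute `truth`.
#' @export
plant_depth_tracks <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$contig_lengths
  if (sum(as.double(lens)) * config$n_samples > 5e7)
    stop_popref("depth tracks would exceed 5e7 cells; use smaller contigs")
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  tracks <- with_substream(config$seed, "depth", {
    lapply(names(lens), function(ctg) {
      n <- as.integer(lens[[ctg]])
      d <- matrix(stats::rpois(n * config$n_samples, config$depth_mean),
                  nrow = n)
      plan <- config$insertion_plan
      plan <- plan[plan$contig == ctg, , drop = FALSE]
      for (i in seq_len(nrow(plan))) {
        carriers <- sample.int(config$n_samples, plan$n_carrier_samples[i])
        rows <- (plan$start[i] + 1L):plan$end[i]
        d[rows, carriers] <- plan$carrier_depth[i]
        ## non-carriers stay at background inside the interval
      }
      depth_matrix(ctg, d, start = 0L, samples = samples)
    })
  })
  names(tracks) <- names(lens)
  attr(tracks, "truth") <- config$insertion_plan
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_depth_bedgraphs(tracks, dir)
    data.table::fwrite(config$insertion_plan,
                       file.path(dir, "insertions_truth.tsv"), sep = "\t")
  }
  tracks
}
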