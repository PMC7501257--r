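#' Resolved run configuration
#'
#' All stage thresholds in one place. Defaults are the study's stated values:
#' common = MAF > 5% in >= 100 genotyped individuals; specific = < 1% in every
#' panel or absent; proxies at r-squared > 0.8 within +/- 1 Mb from loci
#' replicated in >= 2 studies; insertions >= 500 bp at depth > 5 in >= 10
#' samples; patches > 800 kb outside centromeres; QV from homozygous
#' differences of quality >= 10; ROH summed above 5 Mb.
#'
#' @param seed master seed for the simulated inputs.
#' @param maf_min,min_genotyped,rare_max common/specific variant thresholds.
#' @param r2_min,window_bp,min_studies LD-proxy thresholds.
#' @param ins_min_len,ins_depth_min,ins_min_samples,ins_strict insertion-caller
#'   thresholds.
#' @param tra_window SV translocation merge window (bp).
#' @param patch_min_len meta-assembly gap threshold (bp).
#' @param qv_qual_min difference-quality floor for QV.
#' @param roh_min_len ROH length threshold (bp).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, maf_min = 0.05, min_genotyped = 100L,
                       rare_max = 0.01, r2_min = 0.8, window_bp = 1e6,
                       min_studies = 2L, ins_min_len = 500L,
                       ins_depth_min = 5L, ins_min_samples = 10L,
                       ins_strict = TRUE, tra_window = 0L,
                       patch_min_len = 8e5, qv_qual_min = 10,
                       roh_min_len = 5e6) {
  structure(as.list(environment()), class = "run_config")
}

#' Simulate external-panel allele frequencies for a cohort's sites
#'
#' Panels see each site with probability `detect_prob`; detected sites carry
#' the site's true allele frequency plus sampling noise. A chosen fraction of
#' the *common* sites is forced to be population-specific by design: rare
#' (< `rare_max`) or absent in every panel. The truth sidecar lists those keys.
#'
#' @param truth cohort truth table (contig, pos, ref, alt, true_af) from
#'   [simulate_cohort()].
#' @param config a [sim_config()] (seed used).
#' @param panels panel names.
#' @param detect_prob per-panel detection probability for ordinary sites.
#' @param specific_frac fraction of common (true MAF > 0.05) sites made
#'   population-specific.
#' @param rare_max the rarity ceiling the design respects.
#' @param dir optional output directory (`panel_af.tsv`, `specific_truth.tsv`).
#' @return list: `panel_af` data.frame (contig, pos, ref, alt, panel, af) and
#'   `truth` (keys of designed population-specific sites).
#' @export
simulate_panel_af <- function(truth, config,
                              panels = c("1000g", "gnomad", "topmed"),
                              detect_prob = 0.95, specific_frac = 0.02,
                              rare_max = 0.01, dir = NULL) {
  with_substream(config$seed, "panels", {
    key <- site_key(truth$contig, truth$pos, truth$ref, truth$alt)
    maf <- pmin(truth$true_af, 1 - truth$true_af)
    common <- which(maf > 0.05)
    n_spec <- max(1L, round(length(common) * specific_frac))
    spec <- sort(sample(common, n_spec))
    rows <- list()
    for (p in panels) {
      det <- stats::runif(nrow(truth)) < detect_prob
      af <- pmin(1, pmax(0, truth$true_af + stats::rnorm(nrow(truth), 0, 0.02)))
      ## designed specific sites: absent from this panel or rare in it
      absent_here <- stats::runif(nrow(truth)) < 0.5
      af[spec] <- stats::runif(length(spec), 0, rare_max * 0.9)
      det[spec] <- !absent_here[spec]
      rows[[p]] <- data.frame(contig = truth$contig[det], pos = truth$pos[det],
                              ref = truth$ref[det], alt = truth$alt[det],
                              panel = p, af = af[det], stringsAsFactors = FALSE)
    }
    panel_af <- do.call(rbind, rows)
    rownames(panel_af) <- NULL
    res <- list(panel_af = panel_af,
                truth = data.frame(key = key[spec], stringsAsFactors = FALSE))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(panel_af, file.path(dir, "panel_af.tsv"), sep = "\t")
      data.table::fwrite(res$truth, file.path(dir, "specific_truth.tsv"),
                         sep = "\t")
    }
    res
  })
}

## Synthetic GWAS-catalog-style association table over a population's sites:
## replicated loci (>= 2 studies) around chosen tag sites, one trait term per
## locus (the catalog is analysed split by trait).
simulate_associations <- function(stats, config, n_tags = 25L) {
  with_substream(config$seed, "assoc", {
    poly <- which(!is.na(stats$maf) & stats$maf > 0.1)
    n_tags <- min(n_tags, length(poly))
    tags <- sort(sample(poly, n_tags))
    rows <- lapply(seq_along(tags), function(i) {
      s <- stats[tags[i], ]
      n_st <- sample(2:4, 1L)
      ## strongest report sits exactly at the genotyped tag site (offset 0)
      data.frame(trait_term = sprintf("trait%03d", i), contig = s$contig,
                 pos = s$pos + (seq_len(n_st) - 1L),
                 ref = s$ref, alt = s$alt,
                 strength = sort(10^-stats::runif(n_st, 6, 12)),
                 study_id = sprintf("GCST%05d", sample.int(99999L, n_st)),
                 stringsAsFactors = FALSE)
    })
    a <- do.call(rbind, rows)
    ## strongest association exactly at the tag site
    a[order(a$strength), ]
  })
}

#' Run every stage end-to-end on simulated inputs
#'
#' One-command synthetic demo: generates all inputs under `out_dir/inputs`
#' with the configured seed, runs every stage, compares each stage's result
#' to the generator's truth sidecar, and writes `summary.json`, the resolved
#' configuration (`config.json`), and per-stage output files. Stage failures
#' are caught and named; the summary's `ok` field reflects them.
#'
#' @param out_dir output directory (created).
#' @param config a [run_config()].
#' @param stages subset of stage names to run (default: all).
#' @return the summary list, invisibly. Element `ok` is `TRUE` iff every
#'   requested stage succeeded.
#' @export
run_all <- function(out_dir, config = run_config(),
                    stages = c("afstats", "popspec", "proxy", "insertions",
                               "svcollapse", "metaasm", "qv", "phasing",
                               "roh")) {
  stopifnot(inherits(config, "run_config"))
  if (!length(stages)) {
    warning("empty stage list: nothing to do", call. = FALSE)
    return(invisible(list(ok = TRUE, stages = list())))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- file.path(out_dir, "inputs")
  seed <- config$seed
  summary <- list(seed = seed, stages = list())
  run_stage <- function(name, fn) {
    if (!name %in% stages) return()
    res <- tryCatch(fn(), error = function(e) list(error = conditionMessage(e)))
    summary$stages[[name]] <<- res
  }

  cohort_cfg <- sim_config(seed = seed, n_samples = 110L, n_sites = 2000L,
                           contig_lengths = c(chr1 = 2e6))
  cohort <- NULL; stats <- NULL
  if (any(c("afstats", "popspec") %in% stages)) {
    cohort <- simulate_cohort(cohort_cfg, dir = inputs)
    stats <- compute_allele_stats(cohort$gt)
  }

  run_stage("afstats", function() {
    data.table::fwrite(stats, file.path(out_dir, "allele_stats.tsv"), sep = "\t")
    maj <- suppressWarnings(major_allele_at(stats))
    list(n_sites = nrow(stats),
         mean_abs_af_error = mean(abs(stats$alt_af - cohort$truth$true_af),
                                  na.rm = TRUE),
         n_major_alt = sum(maj$major_allele == maj$alt, na.rm = TRUE))
  })

  run_stage("popspec", function() {
    common <- select_common(stats, config$maf_min, config$min_genotyped)
    pan <- simulate_panel_af(cohort$truth, cohort_cfg,
                             rare_max = config$rare_max, dir = inputs)
    spec <- select_population_specific(common, pan$panel_af, config$rare_max)
    novel <- flag_novel(spec)
    data.table::fwrite(spec, file.path(out_dir, "population_specific.tsv"),
                       sep = "\t")
    list(n_common = nrow(common), n_specific = nrow(spec),
         n_novel = nrow(novel),
         truth_recovered = all(pan$truth$key %in% spec$key |
                                 !(pan$truth$key %in% common$key)))
  })

  run_stage("proxy", function() {
    cfg_a <- sim_config(seed = seed, n_samples = 110L, n_sites = 2000L,
                        contig_lengths = c(chr1 = 2e6), ld_block_length = 1e5,
                        missing_rate = 0.02)
    cfg_b <- sim_config(seed = seed + 1L, n_samples = 110L, n_sites = 2000L,
                        contig_lengths = c(chr1 = 2e6), ld_block_length = 1e4,
                        missing_rate = 0.02)
    pops <- simulate_two_populations(cfg_a, cfg_b, dir = inputs)
    st_a <- compute_allele_stats(pops$a$gt)
    assoc <- simulate_associations(st_a, cfg_a)
    data.table::fwrite(assoc, file.path(inputs, "associations.tsv"), sep = "\t")
    tags <- select_tag_snps(assoc, config$window_bp, config$min_studies)
    comp <- lapply(seq_len(nrow(tags)), function(i) {
      pa <- find_proxies(pops$a$gt, tags$contig[i], tags$pos[i],
                         r2_min = config$r2_min, window_bp = config$window_bp,
                         population = "a")
      pb <- find_proxies(pops$b$gt, tags$contig[i], tags$pos[i],
                         r2_min = config$r2_min, window_bp = config$window_bp,
                         population = "b")
      if (!pa$assessable || !pb$assessable) return(NULL)
      cp <- compare_proxy_sets(pa, pb)
      data.frame(tag = cp$tag$key, n_a = cp$n_a, n_b = cp$n_b,
                 n_shared = cp$n_shared, pct_a_shared = cp$pct_a_shared,
                 pct_b_shared = cp$pct_b_shared, stringsAsFactors = FALSE)
    })
    comp <- do.call(rbind, comp)
    if (is.null(comp)) stop_popref("no tag was assessable in both populations")
    data.table::fwrite(comp, file.path(out_dir, "proxy_comparison.tsv"),
                       sep = "\t")
    list(n_tags = nrow(tags), n_assessable = nrow(comp),
         mean_proxies_a = mean(comp$n_a), mean_proxies_b = mean(comp$n_b),
         short_blocks_fewer = mean(comp$n_b) < mean(comp$n_a))
  })

  run_stage("insertions", function() {
    plan <- data.frame(contig = c("ctg1", "ctg1", "ctg2"),
                       start = c(2000L, 9000L, 5000L),
                       end = c(2800L, 9600L, 6500L),
                       n_carrier_samples = c(12L, 15L, 11L),
                       carrier_depth = c(8L, 9L, 7L))
    dcfg <- sim_config(seed = seed, n_samples = 30L, n_sites = 1L,
                       contig_lengths = c(ctg1 = 20000, ctg2 = 20000),
                       depth_mean = 1, insertion_plan = plan)
    tracks <- plant_depth_tracks(dcfg, dir = inputs)
    regions <- call_insertion_regions(tracks, config$ins_min_len,
                                      config$ins_depth_min,
                                      config$ins_min_samples,
                                      config$ins_strict)
    sm <- summarize_insertions(regions)
    data.table::fwrite(sm$regions, file.path(out_dir, "insertions.bed"),
                       sep = "\t", col.names = FALSE)
    truth <- attr(tracks, "truth")
    list(n_regions = sm$n_regions, total_bp = sm$total_bp,
         truth_recovered = nrow(sm$regions) == nrow(truth) &&
           all(sm$regions$contig == truth$contig) &&
           all(sm$regions$start == truth$start) &&
           all(sm$regions$end == truth$end))
  })

  run_stage("svcollapse", function() {
    svcfg <- sim_config(seed = seed, n_samples = 20L, n_sites = 1L,
                        contig_lengths = c(chr1 = 2e6))
    sv <- simulate_sv_calls(svcfg, dir = inputs)
    collapsed <- collapse_overlapping(sv$calls, config$tra_window)
    sm <- sv_summary(collapsed)
    data.table::fwrite(collapsed, file.path(out_dir, "sv_collapsed.tsv"),
                       sep = "\t")
    truth <- sv$truth[order(sv$truth$sample, sv$truth$sv_type,
                            sv$truth$contig, sv$truth$start), ]
    rownames(truth) <- NULL
    list(n_input = nrow(sv$calls), n_collapsed = nrow(collapsed),
         mean_per_sample = sm$mean_per_sample,
         truth_recovered = isTRUE(all.equal(collapsed, truth,
                                            check.attributes = FALSE)))
  })

  meta <- NULL
  if (any(c("metaasm", "qv") %in% stages)) {
    metacfg <- sim_config(seed = seed, n_samples = 2L, n_sites = 1L)
    meta <- simulate_alignment_coverage(metacfg, dir = inputs)
  }

  run_stage("metaasm", function() {
    metacfg <- sim_config(seed = seed, n_samples = 2L, n_sites = 1L)
    alt <- simulate_alt_assembly(meta, metacfg, dir = inputs)
    gaps <- uncovered_gaps(meta$coverage, meta$contig_lengths)
    patches_r <- select_patch_regions(gaps, meta$centromeres,
                                      config$patch_min_len)
    px <- extract_patches(patches_r, alt$blocks, alt$alt_fasta)
    data.table::fwrite(px$patches[setdiff(names(px$patches), "sequence")],
                       file.path(out_dir, "patches.tsv"), sep = "\t")
    list(n_gaps = nrow(gaps), n_patch_regions = nrow(patches_r),
         n_patched = nrow(px$patches), n_unpatchable = nrow(px$unpatchable),
         truth_recovered = identical(px$patches$sequence, alt$truth$sequence))
  })

  run_stage("qv", function() {
    diffs <- with_substream(seed, "qvdiffs", {
      n <- 400L
      data.frame(
        ref_allele = sample(c("A", "C", "G", "T", "AT", "ACGT"), n, TRUE),
        alt_allele = sample(c("A", "C", "G", "T"), n, TRUE),
        quality = round(stats::runif(n, 0, 60), 1),
        zygosity = sample(c("hom", "het"), n, TRUE, prob = c(0.7, 0.3)),
        stringsAsFactors = FALSE)
    })
    diffs <- diffs[diffs$ref_allele != diffs$alt_allele, ]
    data.table::fwrite(diffs, file.path(inputs, "assembly_diffs.tsv"),
                       sep = "\t")
    wc <- count_homozygous_differences(diffs, config$qv_qual_min)
    qv <- assembly_qv(wc, effective_size = 5e6)  # demo-scale genome
    list(weighted_diff_count = wc, effective_genome_size = qv$effective_genome_size,
         qv = qv$qv, lower_bound = qv$lower_bound)
  })

  run_stage("phasing", function() {
    pcfg <- sim_config(seed = seed, n_samples = 2L, n_sites = 1L)
    ph <- simulate_phase_annotations(pcfg, dir = inputs)
    pf <- phased_fraction(ph$variants)
    gb <- genes_single_block(ph$genes, ph$variants)
    list(n_phased = pf$n_phased, n_total = pf$n_total, pct = pf$pct,
         genes_single_block_pct = gb$pct,
         truth_recovered = pf$n_phased == ph$truth$n_phased &&
           gb$n_single_block == ph$truth$n_single_block &&
           gb$n_eligible == ph$truth$n_eligible_genes)
  })

  run_stage("roh", function() {
    rcfg <- sim_config(seed = seed, n_samples = 20L, n_sites = 1L)
    roh <- simulate_roh(rcfg, dir = inputs)
    tot <- total_long_roh(roh$segments, config$roh_min_len)
    data.table::fwrite(tot, file.path(out_dir, "roh_totals.tsv"), sep = "\t")
    m <- merge(tot, roh$truth, by = "sample",
               suffixes = c("_called", "_truth"))
    list(n_samples = nrow(tot),
         mean_total_long_mb = mean(tot$total_long_bp) / 1e6,
         truth_recovered = nrow(m) == nrow(tot) &&
           all(m$total_long_bp_called == m$total_long_bp_truth))
  })

  failed <- vapply(summary$stages, function(s) !is.null(s$error), logical(1L))
  summary$ok <- !any(failed)
  summary$failed_stages <- names(summary$stages)[failed]
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
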