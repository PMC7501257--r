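test_that("identical configs give byte-identical fixture files", {
  cfg <- sim_config(seed = 101, n_samples = 20, n_sites = 100,
                    contig_lengths = c(chr1 = 1e5),
                    insertion_plan = data.frame(
                      contig = "chr1", start = 1000L, end = 1700L,
                      n_carrier_samples = 12L, carrier_depth = 8L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  plant_depth_tracks(cfg, dir = d1)
  plant_depth_tracks(cfg, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("missing_rate = 0 genotypes every site in every sample", {
  cfg <- sim_config(seed = 1, n_samples = 15, n_sites = 60,
                    contig_lengths = c(chr1 = 1e5), missing_rate = 0)
  res <- simulate_cohort(cfg)
  expect_false(anyNA(res$gt$dosage))
  expect_equal(dim(res$gt$dosage), c(60L, 15L))
})

test_that("single-block limit with one founder pair gives perfect LD", {
  cfg <- sim_config(seed = 3, n_samples = 40, n_sites = 30,
                    contig_lengths = c(chr1 = 1e5), ld_block_length = Inf,
                    n_founders = 2, missing_rate = 0)
  res <- simulate_cohort(cfg)
  d <- res$gt$dosage
  poly <- which(apply(d, 1, var) > 0)
  for (i in poly[-1]) {
    expect_equal(r_squared(d[poly[1], ], d[i, ]), 1.0)
  }
})

test_that("finite block longer than the contig is rejected, Inf is not", {
  expect_error(simulate_cohort(
    sim_config(seed = 1, n_samples = 5, n_sites = 10,
               contig_lengths = c(chr1 = 1e4), ld_block_length = 2e4)),
    "shortest contig")
  expect_silent(simulate_cohort(
    sim_config(seed = 1, n_samples = 5, n_sites = 10,
               contig_lengths = c(chr1 = 1e4), ld_block_length = Inf)))
})

test_that("observed AF tracks the recorded truth at binomial precision", {
  # founder-choice sampling makes the alt count Binomial(2n, true_af)
  cfg <- sim_config(seed = 42, n_samples = 500, n_sites = 300,
                    contig_lengths = c(chr1 = 1e6), missing_rate = 0,
                    af_law = list(type = "fixed", af = 0.3))
  res <- simulate_cohort(cfg)
  st <- compute_allele_stats(res$gt)
  se <- sqrt(res$truth$true_af * (1 - res$truth$true_af) / (2 * 500))
  within3 <- abs(st$alt_af - res$truth$true_af) <= 3 * se + 1e-12
  expect_gte(mean(within3), 0.98)
})

test_that("AF error shrinks from n = 100 to n = 1000", {
  err <- sapply(c(100, 1000), function(n) {
    cfg <- sim_config(seed = 7, n_samples = n, n_sites = 200,
                      contig_lengths = c(chr1 = 1e6), missing_rate = 0)
    res <- simulate_cohort(cfg)
    st <- compute_allele_stats(res$gt)
    mean(abs(st$alt_af - res$truth$true_af))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)   # ~ mean binomial SE at 2n = 2000
})

test_that("median r-squared within blocks exceeds across blocks", {
  cfg <- sim_config(seed = 9, n_samples = 120, n_sites = 200,
                    contig_lengths = c(chr1 = 2e5), ld_block_length = 2e4,
                    missing_rate = 0)
  res <- simulate_cohort(cfg)
  d <- res$gt$dosage
  blk <- floor((res$gt$sites$pos - 1) / 2e4)
  poly <- which(apply(d, 1, var) > 0)
  within <- c(); across <- c()
  set.seed(1)
  for (k in 1:400) {
    ij <- sample(poly, 2)
    r2 <- oracle_r2(d[ij[1], ], d[ij[2], ])
    if (is.na(r2)) next
    if (blk[ij[1]] == blk[ij[2]]) within <- c(within, r2)
    else across <- c(across, r2)
  }
  expect_gt(median(within), median(across))
})

test_that("two-population generator is symmetric and rejects mismatched maps", {
  cfg <- sim_config(seed = 5, n_samples = 30, n_sites = 100,
                    contig_lengths = c(chr1 = 1e5))
  pp <- simulate_two_populations(cfg, cfg)
  expect_identical(pp$a$gt$dosage, pp$b$gt$dosage)
  expect_identical(pp$a$gt$sites, pp$b$gt$sites)
  cfg2 <- sim_config(seed = 5, n_samples = 30, n_sites = 101,
                     contig_lengths = c(chr1 = 1e5))
  expect_error(simulate_two_populations(cfg, cfg2), "share n_sites")
})

test_that("a monomorphic population yields no assessable tags", {
  cfg_a <- sim_config(seed = 6, n_samples = 30, n_sites = 50,
                      contig_lengths = c(chr1 = 1e5), missing_rate = 0)
  cfg_b <- sim_config(seed = 6, n_samples = 30, n_sites = 50,
                      contig_lengths = c(chr1 = 1e5), missing_rate = 0,
                      af_law = list(type = "fixed", af = 0))
  pp <- simulate_two_populations(cfg_a, cfg_b, shared_founders = FALSE)
  expect_true(all(pp$b$gt$dosage == 0L))
  s <- pp$b$gt$sites
  for (i in c(1L, 25L)) {
    ps <- find_proxies(pp$b$gt, s$contig[i], s$pos[i])
    expect_false(ps$assessable)
  }
})

test_that("planted depth intervals carry exact carrier counts", {
  plan <- data.frame(contig = "c1", start = 1000L, end = 1600L,
                     n_carrier_samples = 12L, carrier_depth = 6L)
  cfg <- sim_config(seed = 11, n_samples = 20, n_sites = 1,
                    contig_lengths = c(c1 = 5000), depth_mean = 0,
                    insertion_plan = plan)
  tr <- plant_depth_tracks(cfg)
  counts <- samples_passing(tr$c1, depth_min = 5, strict = TRUE)
  expect_true(all(counts[1001:1600] == 12L))
  expect_true(all(counts[-(1001:1600)] == 0L))
  # carrier_depth equal to the threshold is invisible under strict ">"
  plan$carrier_depth <- 5L
  cfg2 <- sim_config(seed = 11, n_samples = 20, n_sites = 1,
                     contig_lengths = c(c1 = 5000), depth_mean = 0,
                     insertion_plan = plan)
  tr2 <- plant_depth_tracks(cfg2)
  expect_equal(nrow(call_insertion_regions(tr2, min_len = 500, depth_min = 5,
                                           min_samples = 10, strict = TRUE)),
               0L)
})

test_that("all-zero background with empty plan gives all-zero tracks", {
  cfg <- sim_config(seed = 2, n_samples = 5, n_sites = 1,
                    contig_lengths = c(c1 = 2000), depth_mean = 0)
  tr <- plant_depth_tracks(cfg)
  expect_true(all(tr$c1$depth == 0L))
})

test_that("config validation rejects out-of-range plans and probabilities", {
  expect_error(sim_config(missing_rate = 1.2), "probabilities")
  expect_error(sim_config(
    contig_lengths = c(c1 = 1000),
    insertion_plan = data.frame(contig = "c1", start = 500L, end = 1500L,
                                n_carrier_samples = 2L, carrier_depth = 5L)),
    "contig bounds")
  expect_error(sim_config(
    n_samples = 5,
    contig_lengths = c(c1 = 1e4),
    insertion_plan = data.frame(contig = "c1", start = 10L, end = 20L,
                                n_carrier_samples = 6L, carrier_depth = 5L)),
    "exceeds n_samples")
})

test_that("interval generators write truth sidecars that match their plan", {
  cfg <- sim_config(seed = 13, n_samples = 8, n_sites = 1,
                    contig_lengths = c(chr1 = 2e6))
  d <- withr::local_tempdir()
  sv <- simulate_sv_calls(cfg, dir = d)
  expect_true(file.exists(file.path(d, "sv_truth.tsv")))
  expect_equal(nrow(sv$truth), 8 * 5)
  # zero SVs requested -> empty call set and truth
  sv0 <- simulate_sv_calls(cfg, n_true_per_sample = 0)
  expect_equal(nrow(sv0$calls), 0L)
  expect_equal(nrow(sv0$truth), 0L)
  roh <- simulate_roh(cfg, dir = d)
  lens <- roh$segments$end - roh$segments$start
  manual <- tapply(lens * (lens > 5e6), roh$segments$sample, sum)
  expect_equal(as.numeric(manual[roh$truth$sample]), roh$truth$total_long_bp)
})

test_that("full coverage means no gap truth", {
  cfg <- sim_config(seed = 4, n_samples = 2, n_sites = 1)
  cov <- simulate_alignment_coverage(cfg)
  # complement of coverage reproduces exactly the planted gaps
  gaps <- uncovered_gaps(cov$coverage, cov$contig_lengths)
  expect_equal(gaps[c("contig", "start", "end")], cov$gaps)
  full <- data.frame(contig = names(cov$contig_lengths), start = 0,
                     end = as.integer(cov$contig_lengths))
  expect_equal(nrow(uncovered_gaps(full, cov$contig_lengths)), 0L)
})
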