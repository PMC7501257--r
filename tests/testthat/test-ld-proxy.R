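test_that("r_squared matches hand computations and signals degenerate input", {
  expect_equal(r_squared(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1.0)
  expect_equal(r_squared(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)
  # hand Pearson: r^2 = 27/34
  expect_equal(r_squared(c(0, 1, 2, 0, 1, 2), c(0, 1, 1, 0, 1, 2)), 27 / 34)
  expect_error(r_squared(c(0, 0, 0), c(0, 1, 2)), "monomorphic")
  expect_error(r_squared(c(0, 1), c(0, 1, 2)), "length")
  expect_error(r_squared(c(0, NA), c(NA, 1)), "pairwise-complete")
})

test_that("r_squared is symmetric and invariant under allele relabeling", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    a <- sample(0:2, n, replace = TRUE)
    b <- sample(0:2, n, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    r <- r_squared(a, b)
    expect_equal(r_squared(b, a), r)
    expect_equal(r_squared(2 - a, b), r)
    expect_equal(r_squared(a, 2 - b), r)
    expect_equal(r, oracle_r2(a, b))
  }
})

test_that("tag selection keeps only replicated loci and picks the strongest", {
  # one locus, one study -> dropped
  a1 <- data.frame(trait_term = "t", contig = "chr1", pos = 5e6,
                   strength = 1e-9, study_id = "s1")
  expect_equal(nrow(select_tag_snps(a1)), 0L)
  # two variants 500 kb apart, two studies -> one tag at the stronger
  a2 <- data.frame(trait_term = "t", contig = "chr1",
                   pos = c(5e6, 5.5e6), strength = c(1e-9, 1e-8),
                   study_id = c("s1", "s2"))
  tags <- select_tag_snps(a2)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$pos, 5e6)
  expect_equal(tags$n_supporting_associations, 2L)
  # 3 Mb apart, each replicated -> two tags
  a3 <- data.frame(trait_term = "t", contig = "chr1",
                   pos = c(5e6, 5e6, 8e6, 8e6), strength = c(1e-9, 1e-7, 1e-8, 1e-6),
                   study_id = c("s1", "s2", "s3", "s4"))
  expect_equal(nrow(select_tag_snps(a3)), 2L)
  expect_error(select_tag_snps(transform(a1, strength = 0)), "> 0")
})

test_that("tag selection satisfies its declared invariants on random inputs", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 40
    a <- data.frame(trait_term = sample(c("t1", "t2"), n, TRUE),
                    contig = sample(c("chr1", "chr2"), n, TRUE),
                    pos = sample.int(2e7, n),
                    strength = 10^-runif(n, 3, 12),
                    study_id = sample(paste0("s", 1:6), n, TRUE))
    tags <- select_tag_snps(a, min_studies = 2)
    # pairwise > 1 Mb apart per trait and contig
    if (nrow(tags) > 1) {
      for (tr in unique(tags$trait_term)) {
        tt <- tags[tags$trait_term == tr, ]
        for (ctg in unique(tt$contig)) {
          p <- sort(tt$pos[tt$contig == ctg])
          if (length(p) > 1) expect_true(all(diff(p) > 1e6))
        }
      }
    }
    # every tag is replicated and is the strongest in its own window among
    # the trait's associations
    for (i in seq_len(nrow(tags))) {
      t <- tags[i, ]
      w <- a$trait_term == t$trait_term & a$contig == t$contig &
        abs(a$pos - t$pos) <= 1e6
      expect_gte(length(unique(a$study_id[w])), 2L)
      expect_equal(min(a$strength[w]), t$strength)
    }
    # permutation invariance
    perm <- a[sample.int(n), ]
    expect_equal(select_tag_snps(perm, min_studies = 2), tags)
  }
})

test_that("proxy scan excludes the tag, applies the strict threshold, and windows", {
  # 6 samples; site2 duplicates the tag's dosages; site3 has known r2 = 27/34;
  # site4 is outside the window; site5 monomorphic
  d <- rbind(c(0, 1, 2, 0, 1, 2),
             c(0, 1, 2, 0, 1, 2),
             c(0, 1, 1, 0, 1, 2),
             c(0, 1, 2, 0, 1, 2),
             c(1, 1, 1, 1, 1, 1))
  gt <- make_gt(d, pos = c(1000L, 2000L, 3000L, 900000L, 4000L))
  ps <- find_proxies(gt, "chr1", 1000, r2_min = 0.5, window_bp = 10000,
                     min_complete = 2)
  expect_true(ps$assessable)
  expect_equal(ps$proxies$pos, c(2000L, 3000L))
  expect_equal(ps$proxies$r2, c(1, 27 / 34))
  # strictness: r2 exactly at the threshold is excluded (r2 = 1 is exact in
  # floating point, unlike fractions such as 27/34)
  ps2 <- find_proxies(gt, "chr1", 1000, r2_min = 1, window_bp = 10000,
                      min_complete = 2)
  expect_equal(nrow(ps2$proxies), 0L)
  # widening the window pulls in the far duplicate
  ps3 <- find_proxies(gt, "chr1", 1000, r2_min = 0.5, window_bp = 1e6,
                      min_complete = 2)
  expect_equal(nrow(ps3$proxies), 3L)
  # absent and monomorphic tags are flagged, not errored
  expect_false(find_proxies(gt, "chr1", 99L)$assessable)
  expect_false(find_proxies(gt, "chr1", 4000L, min_complete = 2)$assessable)
})

test_that("proxy sets shrink as r2_min rises or the window falls", {
  cfg <- sim_config(seed = 23, n_samples = 80, n_sites = 150,
                    contig_lengths = c(chr1 = 1.5e5), ld_block_length = 3e4)
  res <- simulate_cohort(cfg)
  st <- compute_allele_stats(res$gt)
  tag <- which(st$maf > 0.2)[5]
  prev <- NULL
  for (r2min in c(0.2, 0.5, 0.8, 0.95)) {
    ps <- find_proxies(res$gt, st$contig[tag], st$pos[tag],
                       r2_min = r2min, window_bp = 5e4)
    if (!is.null(prev)) expect_true(all(ps$proxies$key %in% prev))
    prev <- ps$proxies$key
  }
  prev <- NULL
  for (w in c(1e5, 5e4, 1e4, 2e3)) {
    ps <- find_proxies(res$gt, st$contig[tag], st$pos[tag],
                       r2_min = 0.5, window_bp = w)
    if (!is.null(prev)) expect_true(all(ps$proxies$key %in% prev))
    prev <- ps$proxies$key
  }
})

test_that("proxy-set comparison arithmetic and rounding", {
  a <- make_proxy_set(paste0("k", 1:7))
  b <- make_proxy_set(paste0("k", c(1, 2, 10)))
  cp <- compare_proxy_sets(a, b)
  expect_equal(cp$n_shared, 2L)
  expect_equal(cp$pct_a_shared, 29)
  expect_equal(cp$pct_a_only, 71)
  expect_equal(cp$pct_b_shared, 67)
  expect_equal(cp$pct_b_only, 33)
  expect_equal(cp$pct_a_shared_exact + cp$pct_a_only_exact, 100)
  # identical non-empty sets
  cp2 <- compare_proxy_sets(make_proxy_set(c("x", "y")),
                            make_proxy_set(c("x", "y")))
  expect_equal(cp2$pct_a_shared, 100)
  expect_equal(cp2$pct_b_only, 0)
  # empty side undefined
  cp3 <- compare_proxy_sets(make_proxy_set(character()), b)
  expect_true(is.na(cp3$pct_a_shared))
  expect_equal(cp3$n_shared, 0L)
  # mismatched tags rejected
  expect_error(compare_proxy_sets(a, make_proxy_set("k", tag_key = "other")),
               "different tags")
})

test_that("AF contrast labels straddle the common threshold", {
  sa <- data.frame(key = c("k1", "k2", "k3", "k4"),
                   alt_af = c(0.30, 0.06, 0.01, 0.2),
                   no_genotypes = FALSE)
  sb <- data.frame(key = c("k1", "k2", "k3"),
                   alt_af = c(0.30, 0.04, 0.30),
                   no_genotypes = FALSE)
  ac <- af_contrast(c("k1", "k2", "k3", "k4"), sa, sb)
  expect_equal(ac$label, c("common-both", "common-a-rare-b",
                           "common-b-rare-a", "absent-in-b"))
  expect_equal(ac$delta[1], 0)
})
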