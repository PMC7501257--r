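test_that("gap complement matches hand results and tiles the contig", {
  lens <- c(ref1 = 1e6)
  cov <- data.frame(contig = "ref1", start = c(0, 5e5), end = c(3e5, 1e6))
  gaps <- uncovered_gaps(cov, lens)
  expect_equal(gaps$start, 3e5)
  expect_equal(gaps$end, 5e5)
  expect_equal(gaps$length, 2e5)
  # full coverage -> none; empty -> the whole contig
  expect_equal(nrow(uncovered_gaps(
    data.frame(contig = "ref1", start = 0, end = 1e6), lens)), 0L)
  whole <- uncovered_gaps(cov[0, ], lens)
  expect_equal(whole$length, 1e6)
  # coverage + gaps tile the contig exactly
  expect_equal(sum(cov$end - cov$start) + sum(gaps$length), 1e6)
  expect_error(uncovered_gaps(
    data.frame(contig = "ref1", start = 0, end = 2e6), lens), "bounds")
})

test_that("patch selection applies the strict length and zero-overlap rules", {
  cents <- data.frame(contig = "r", start = 5e6, end = 6e6)
  gaps <- data.frame(contig = "r",
                     start = c(0, 2e6, 4.1e6, 8e6),
                     end = c(9e5, 2.7e6, 5.000001e6, 8.8e5 + 8e6))
  gaps$length <- gaps$end - gaps$start
  kept <- select_patch_regions(gaps, cents, min_len = 8e5)
  # 900 kb clean kept; 700 kb dropped; 900 kb with 1 bp centromere overlap
  # dropped; the last one kept (880 kb clean)
  expect_equal(kept$start, c(0, 8e6))
  # exactly 800 kb is dropped (strict >)
  g800 <- data.frame(contig = "r", start = 0, end = 8e5, length = 8e5)
  expect_equal(nrow(select_patch_regions(g800, cents)), 0L)
  # the overlap tolerance option readmits the centromere-grazing gap
  relaxed <- select_patch_regions(gaps, cents, min_len = 8e5,
                                  max_centromere_overlap = 10)
  expect_equal(nrow(relaxed), 3L)
})

test_that("patches map through plus and minus strand blocks", {
  set.seed(8)
  alt_seq <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  alt <- Biostrings::DNAStringSet(alt_seq)
  names(alt) <- "altA"
  blocks <- data.frame(ref_contig = "r", ref_start = 100000, ref_end = 110000,
                       alt_contig = "altA", alt_start = 2000, alt_end = 12000,
                       strand = "+", stringsAsFactors = FALSE)
  region <- data.frame(contig = "r", start = 100000, end = 110000,
                       length = 10000)
  px <- extract_patches(region, blocks, alt)
  expect_equal(nrow(px$patches), 1L)
  expect_equal(px$patches$sequence, substr(alt_seq, 2001, 12000))
  # minus strand: reverse complement of the mapped interval
  blocks$strand <- "-"
  pxm <- extract_patches(region, blocks, alt)
  expect_equal(pxm$patches$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(alt_seq, 2001, 12000)))))
  # offset region inside a larger block, minus strand: mapped from the far end
  region2 <- data.frame(contig = "r", start = 101000, end = 102000,
                        length = 1000)
  pxo <- extract_patches(region2, blocks, alt)
  expect_equal(pxo$patches$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(alt_seq, 10001, 11000)))))
  # unaligned or block-spanning regions are unpatchable, with a reason
  far <- data.frame(contig = "r", start = 5e6, end = 5.9e6, length = 9e5)
  expect_equal(extract_patches(far, blocks, alt)$unpatchable$reason,
               "no alignment block")
  two <- rbind(blocks, transform(blocks, ref_start = 110000, ref_end = 120000,
                                 alt_start = 0, alt_end = 10000))
  spanning <- data.frame(contig = "r", start = 105000, end = 115000,
                         length = 10000)
  expect_equal(extract_patches(spanning, two, alt)$unpatchable$reason,
               "spans multiple blocks")
})

test_that("homozygous difference weighting follows SNV/indel rules", {
  d <- data.frame(ref_allele = "A", alt_allele = "G", quality = 30,
                  zygosity = "hom")
  expect_equal(count_homozygous_differences(d), 1)
  d <- data.frame(ref_allele = "A", alt_allele = "ATTT", quality = 30,
                  zygosity = "hom")
  expect_equal(count_homozygous_differences(d), 3)
  d <- data.frame(ref_allele = c("A", "C"), alt_allele = c("G", "T"),
                  quality = c(9, 50), zygosity = c("hom", "het"))
  expect_equal(count_homozygous_differences(d), 0)
  # quality floor is inclusive
  d <- data.frame(ref_allele = "A", alt_allele = "G", quality = 10,
                  zygosity = "hom")
  expect_equal(count_homozygous_differences(d), 1)
  # equal-length multi-base substitution counts differing positions
  d <- data.frame(ref_allele = "ACGT", alt_allele = "AGGA", quality = 30,
                  zygosity = "hom")
  expect_equal(count_homozygous_differences(d), 2)
})

test_that("QV follows the closed form with a sentinel at zero differences", {
  expect_equal(assembly_qv(1, 1e4)$qv, 40)
  expect_equal(assembly_qv(4, 1e5)$qv, -10 * log10(4e-5))
  expect_equal(round(assembly_qv(4, 1e5)$qv, 2), 43.98)
  z <- assembly_qv(0, 1e6)
  expect_true(z$lower_bound)
  expect_equal(z$qv, 60)
  expect_error(assembly_qv(5, 0), "> 0")
  # strictly decreasing in the difference count
  qvs <- sapply(c(1, 10, 100, 1000), function(k) assembly_qv(k, 1e7)$qv)
  expect_true(all(diff(qvs) < 0))
})

test_that("planted >800 kb non-centromeric gaps are recovered end to end", {
  cfg <- sim_config(seed = 81, n_samples = 2, n_sites = 1)
  cov <- simulate_alignment_coverage(cfg)
  gaps <- uncovered_gaps(cov$coverage, cov$contig_lengths)
  regions <- select_patch_regions(gaps, cov$centromeres)
  expect_equal(regions[c("contig", "start", "end")], cov$truth,
               ignore_attr = TRUE)
  alt <- simulate_alt_assembly(cov, cfg)
  px <- extract_patches(regions, alt$blocks, alt$alt_fasta)
  expect_equal(px$patches$sequence, alt$truth$sequence)
  expect_equal(nrow(px$unpatchable), 0L)
  # round trip: patch lengths equal gap lengths
  expect_equal(nchar(px$patches$sequence), px$patches$end - px$patches$start)
})

test_that("effective genome size counts covered bases", {
  expect_equal(effective_genome_size(c(0L, 1L, 3L, 0L, 2L)), 3L)
  # rows are bases: base 1 = (0,0) uncovered, base 2 = (2,1) covered
  dm <- depth_matrix("c", matrix(c(0L, 2L, 0L, 1L), 2))
  expect_equal(effective_genome_size(dm), 1L)
})
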