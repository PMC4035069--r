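test_that("config validation rejects bad inputs", {
  expect_error(sim_config(n_mirnas = 0), "n_mirnas")
  expect_error(sim_config(contamination_fractions = c(rRNA = 0.7, tRNA = 0.4)),
               "sum to < 1")
  expect_error(sim_config(contamination_fractions = c(bogus = 0.1)),
               "unknown contamination")
  expect_error(sim_config(length_profile = c("17" = 1)), "18..30")
  cfg <- sim_config(length_profile = c("21" = 2, "22" = 6))
  expect_equal(sum(cfg$length_profile), 1)
})

test_that("reference building is deterministic and plants what it claims", {
  cfg <- sim_config(seed = 1, n_mirnas = 20, n_novel_hairpins = 3)
  r1 <- build_reference_set(cfg)
  r2 <- build_reference_set(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$mature, r2$mature)
  expect_identical(r1$novel_loci, r2$novel_loci)
  r3 <- build_reference_set(sim_config(seed = 2, n_mirnas = 20))
  expect_false(identical(r1$genome, r3$genome))

  # exactly 3 planted novel loci, absent from the miRNA reference
  expect_equal(nrow(r1$novel_loci), 3L)
  expect_false(any(r1$novel_loci$mature_seq %in% r1$mature))
  expect_false(any(r1$novel_loci$precursor_seq %in% r1$precursor))

  # every mature occurs in exactly one precursor
  n_prec <- vapply(r1$mature, function(m)
    sum(vapply(r1$precursor, function(p) grepl(m, p, fixed = TRUE),
               logical(1))), integer(1))
  expect_true(all(n_prec == 1L))

  # planted loci sequences really are at the recorded genome coordinates
  for (i in seq_len(nrow(r1$novel_loci))) {
    nl <- r1$novel_loci[i]
    expect_identical(substr(r1$genome[[nl$chrom]], nl$start + 1L, nl$end),
                     nl$precursor_seq)
  }
})

test_that("genome sizing errors when too small, pads when large", {
  expect_error(build_reference_set(sim_config(seed = 1, n_mirnas = 5,
                                              genome_size = 1000L)),
               "too small")
  refs <- build_reference_set(sim_config(seed = 1, n_mirnas = 5,
                                         genome_size = 60000L))
  expect_equal(sum(nchar(refs$genome)), 60000L)
})

test_that("planted precursors fold into hairpins", {
  refs <- build_reference_set(sim_config(seed = 7, n_mirnas = 6))
  for (p in refs$precursor[1:3]) {
    mlen <- nchar(refs$mature[[match(p, refs$precursor)]])
    f <- fold_sequence(p)
    expect_gte(f$n_pairs, mlen - 2L)
  }
})

test_that("per-read provenance partitions each library", {
  s <- shared_sim()
  cc <- s$truth$category_counts
  expect_equal(cc[library_ == 1, sum(n)], s$cfg$library_depths[1])
  expect_equal(cc[library_ == 2, sum(n)], s$cfg$library_depths[2])
  expect_equal(nrow(s$truth$reads), sum(s$cfg$library_depths))
})

test_that("planted category rates match configuration (binomial tolerance)", {
  cfg <- sim_config(seed = 9, n_mirnas = 10, library_depths = c(10000, 10000),
                    contamination_fractions = c(polyA = 0.01, rRNA = 0.05))
  refs <- build_reference_set(cfg)
  truth <- simulate_libraries(cfg, refs, tempfile())
  n_polyA <- truth$reads[library_ == 1 & category == "polyA", .N]
  expect_gt(n_polyA, 100 - 4 * sqrt(100))
  expect_lt(n_polyA, 100 + 4 * sqrt(100))
  n_rrna <- truth$reads[library_ == 1 & category == "rRNA", .N]
  expect_gt(n_rrna, 500 - 4 * sqrt(500))
  expect_lt(n_rrna, 500 + 4 * sqrt(500))
})

test_that("planted DE miRNA count and expected-count ratios are exact", {
  cfg <- sim_config(seed = 4, n_mirnas = 37, de_fraction = 0.1,
                    planted_log2fc = 2)
  refs <- build_reference_set(cfg)
  truth <- simulate_libraries(cfg, refs, tempfile())
  expect_equal(sum(truth$mirna$de_status != 0), floor(0.1 * 37))
  up <- truth$mirna[de_status == 1]
  # per-miRNA weight ratio is exactly 2^planted_log2fc; expected counts
  # also carry the (slightly) different per-library weight normalization
  expect_equal(up$w2 / up$w1, rep(4, nrow(up)))
  null <- truth$mirna[de_status == 0]
  expect_equal(null$w2, null$w1)
})

test_that("fixed seed reproduces byte-identical FASTQ, depth 0 is graceful", {
  cfg <- sim_config(seed = 6, n_mirnas = 8, library_depths = c(500, 500))
  refs <- build_reference_set(cfg)
  t1 <- simulate_libraries(cfg, refs, tempfile())
  t2 <- simulate_libraries(cfg, refs, tempfile())
  expect_identical(readLines(t1$fastq[1]), readLines(t2$fastq[1]))
  expect_identical(t1$mirna, t2$mirna)

  cfg0 <- sim_config(seed = 6, n_mirnas = 8, library_depths = c(0, 0))
  t0 <- simulate_libraries(cfg0, refs, tempfile())
  expect_true(file.exists(t0$fastq[1]))
  expect_equal(file.size(t0$fastq[1]), 0)
  expect_equal(nrow(t0$reads), 0L)
})

test_that("CT table follows the log2 abundance model exactly at zero noise", {
  cfg <- sim_config(seed = 8, n_mirnas = 4, ct_noise_sd = 0, n_qpcr = 2)
  truth <- structure(list(mirna = data.table::data.table(
    mirna_id = c("a", "b"),
    expected_count_1 = c(400, 100), expected_count_2 = c(100, 100))),
    class = "sim_truth")
  ct <- simulate_ct_table(cfg, truth, mirna_ids = c("a", "b"))
  a <- ct[mirna_id == "a"]
  dct <- a[, .(d = mean(ct - ct_ref)), by = group]
  # 4:1 abundance ratio -> exactly 2 cycles of delta-CT difference
  expect_equal(dct[group == "Uni", d] - dct[group == "Mul", d], 2)
  b <- ct[mirna_id == "b"]
  expect_equal(unique(round(b$ct, 12)), unique(round(b$ct, 12))[1])
  # reproducible under the same seed
  ct2 <- simulate_ct_table(cfg, truth, mirna_ids = c("a", "b"))
  expect_identical(ct, ct2)
})
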