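test_that("normalize_tpm matches its definition and guards inputs", {
  expect_equal(normalize_tpm(5214, 5948837), 5214 / 5948837 * 1e6)
  expect_equal(round_half_away(normalize_tpm(5214, 5948837)), 876)
  expect_equal(normalize_tpm(7, 7), 1e6)
  expect_equal(normalize_tpm(0, 123456), 0)
  expect_error(normalize_tpm(10, 0), "clean_total")
  expect_error(normalize_tpm(-1, 10), "count")
})

test_that("exact test matches the recurrence-summation oracle", {
  expect_equal(exact_count_pvalue(0, 0, 1e6, 1e6), 1)
  # closed form at N1 = N2: p(k|x) = C(x+k, x) / 2^(x+k+1)
  lower_closed <- function(x, y) sum(choose(x + 0:y, x) / 2^(x + 0:y + 1))
  expect_equal(exact_count_pvalue(1, 0, 5e5, 5e5),
               min(1, 2 * min(lower_closed(1, 0), 1)), tolerance = 1e-12)
  for (x in c(0, 2, 7)) for (y in c(0, 1, 5, 12)) {
    expect_equal(exact_count_pvalue(x, y, 1e6, 1e6),
                 oracle_ac_pvalue(x, y, 1e6, 1e6), tolerance = 1e-12)
  }
  expect_equal(exact_count_pvalue(50, 5, 1e6, 1e6),
               oracle_ac_pvalue(50, 5, 1e6, 1e6), tolerance = 1e-10)
  # unequal library sizes
  expect_equal(exact_count_pvalue(20, 35, 5948837, 5945145),
               oracle_ac_pvalue(20, 35, 5948837, 5945145),
               tolerance = 1e-10)
  expect_error(exact_count_pvalue(-1, 0, 10, 10), "non-negative")
  expect_error(exact_count_pvalue(1.5, 0, 10, 10), "integers")
  expect_error(exact_count_pvalue(1, 0, 0, 10), "positive")
})

test_that("exact test is pointwise-symmetric at equal totals, tail-monotone", {
  # the underlying distribution is symmetric at N1 = N2:
  # p(y|x) = C(x+y, x) / 2^(x+y+1) = p(x|y); the doubled-tail two-sided
  # p-value conditions on x and is deliberately not swap-invariant
  set.seed(31)
  for (i in 1:25) {
    x <- rpois(1, 40); y <- rpois(1, 10)
    expect_equal(dnbinom(y, size = x + 1, prob = 0.5),
                 dnbinom(x, size = y + 1, prob = 0.5), tolerance = 1e-12)
    # with unequal totals the pointwise ratio is exactly N1/N2
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    r <- dnbinom(y, x + 1, N1 / (N1 + N2)) /
      dnbinom(x, y + 1, N2 / (N1 + N2))
    expect_equal(r, N1 / N2, tolerance = 1e-9)
  }
  x <- 40
  p_up <- exact_count_pvalue(x, x + 0:30, 1e5, 1e5)
  expect_true(all(diff(p_up) <= 1e-12))
  p_dn <- exact_count_pvalue(x, x - 0:30, 1e5, 1e5)
  expect_true(all(diff(p_dn) <= 1e-12))
})

test_that("all-null counts give near-calibrated label rates", {
  set.seed(55)
  n <- 400
  mu <- exp(runif(n, log(20), log(2000)))
  x <- rpois(n, mu); y <- rpois(n, mu)
  p <- exact_count_pvalue(x, y, 1e5, 1e5)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("fold change, ratio classes and labels follow the stated rules", {
  fc <- fold_change(c(10, 40, 7), c(40, 10, 7))
  expect_equal(fc$log2fc, c(2, -2, 0))
  expect_equal(fc$ratio_class, c(">2", "<=1/2", "(1/2,2]"))
  expect_equal(fold_change(10, 20)$ratio_class, "(1/2,2]")  # boundary 2
  expect_equal(fold_change(20, 10)$ratio_class, "<=1/2")    # boundary 1/2
  expect_error(fold_change(0, 10), "positive")

  expect_equal(sig_label(c(1.5, 0.5, -2, 1.2, -1.01),
                         c(0.005, 0.001, 0.03, 0.5, 0.0099)),
               c("**", "None", "*", "None", "**"))
  expect_equal(sig_label(2, 0.01), "*")   # p = 0.01 boundary is "*"
})

test_that("de_table applies zero revision and low-expression filtering", {
  rec <- data.table::data.table(
    mirna_id = c("zero_t", "low_both", "boundary", "plain", "undetected"),
    count_lib1 = c(0L, 0L, 1L, 100L, 0L),
    count_lib2 = c(50L, 0L, 0L, 210L, 0L))
  # totals chosen so count 1 -> std 1 exactly in lib1
  de <- de_table(rec, clean_totals = c(1e6, 1e6), control = 1L)
  expect_false("undetected" %in% de$mirna_id)   # zero in both: not detected
  z <- de[mirna_id == "zero_t"]
  expect_equal(z$std1, 0.01)                    # revised from 0
  expect_equal(z$std2, 50)
  expect_false("low_both" %in% de$mirna_id)
  b <- de[mirna_id == "boundary"]               # (1, 0.01): only one < 1
  expect_equal(nrow(b), 1L)
  expect_equal(b$std1, 1)
  p <- de[mirna_id == "plain"]
  expect_equal(p$log2fc, log2(210 / 100))
  expect_equal(p$pvalue, exact_count_pvalue(100, 210, 1e6, 1e6))
})

test_that("de_table drops sub-1 pairs like (0.4, 0.9) but keeps (1.0, 0.2)", {
  rec <- data.table::data.table(
    mirna_id = c("a", "b"),
    count_lib1 = c(4L, 10L), count_lib2 = c(9L, 2L))
  de <- de_table(rec, clean_totals = c(1e7, 1e7))
  expect_equal(de$mirna_id, "b")
})

test_that("clustering merges identical profiles and is order-invariant", {
  de <- data.table::data.table(
    mirna_id = c("u1", "u2", "d1", "d2"),
    std1 = c(10, 10, 800, 805), std2 = c(160, 160, 50, 49))
  cl <- cluster_de(de)
  expect_equal(min(cl$hclust$height), 0)  # u1/u2 identical
  k2 <- stats::cutree(cl$hclust, 2)
  expect_equal(k2[["u1"]], k2[["u2"]])
  expect_equal(k2[["d1"]], k2[["d2"]])
  expect_false(k2[["u1"]] == k2[["d1"]])

  set.seed(2)
  cl2 <- cluster_de(de[sample(4)])
  expect_equal(sort(cl2$hclust$height), sort(cl$hclust$height))
  expect_error(cluster_de(de[1]), "at least 2")

  nwk <- export_newick(cl, tempfile(fileext = ".nwk"))
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, de$mirna_id)
})

test_that("planted two-block structure is recovered by cutting at 2", {
  s <- shared_sim()
  de <- data.table::data.table(
    mirna_id = sprintf("m%02d", 1:20),
    std1 = c(rep(20, 10), rep(500, 10)) * exp(rnorm(20, 0, 0.05)),
    std2 = c(rep(300, 10), rep(30, 10)) * exp(rnorm(20, 0, 0.05)))
  cl <- cluster_de(de)
  k2 <- stats::cutree(cl$hclust, 2)
  expect_equal(length(unique(k2[1:10])), 1L)
  expect_equal(length(unique(k2[11:20])), 1L)
  expect_false(k2[[1]] == k2[[20]])
})

test_that("de_summaries emits both breakdowns", {
  rec <- data.table::data.table(
    mirna_id = sprintf("m%d", 1:6),
    count_lib1 = c(100L, 10L, 400L, 55L, 5L, 900L),
    count_lib2 = c(95L, 80L, 90L, 60L, 4L, 910L))
  de <- de_table(rec, clean_totals = c(1e5, 1e5))
  sm <- de_summaries(de)
  expect_equal(sum(sm$by_ratio_class$n), nrow(de))
  expect_equal(sum(sm$by_significance$fraction), 1)
})
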