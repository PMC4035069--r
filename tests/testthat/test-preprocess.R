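adapter3 <- "TGGAATTCTCGGGTGCCAAGG"
adapter5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

pad36 <- function(x) substr(paste0(x, strrep("G", 36)), 1, 36)

test_that("filter cascade assigns each read to its first failing category", {
  insert <- "ACGTACGTACGTACGTACGTAC"             # 22 nt clean insert
  reads <- c(
    clean   = pad36(paste0(insert, adapter3)),
    lowq    = pad36(paste0(insert, adapter3)),
    noad    = strrep("ACGT", 9),                 # 36 nt, no adapter
    dimer   = pad36(adapter3),                   # empty insert
    a5      = pad36(paste0(substr(adapter5, 1, 9),
                           "ACGTACGTACGTAC", adapter3)),
    short16 = pad36(paste0("ACGTACGTACGTACGT", adapter3)),
    polyA   = pad36(paste0(strrep("A", 20), adapter3)))
  quals <- c(strrep("I", 36), strrep("#", 36), rep(strrep("I", 36), 5))
  fq <- write_test_fastq(unname(reads), tempfile(fileext = ".fastq"),
                         quals = quals)
  out <- clean_reads(fq, adapter3, adapter5)
  r <- out$report
  get <- function(ty) r$count[r$type == ty]
  expect_equal(get("total_reads"), 7)
  expect_equal(get("high_quality"), 6)
  expect_equal(get("adapter3_null"), 1)
  expect_equal(get("insert_null"), 1)
  expect_equal(get("adapter5_contaminants"), 1)
  expect_equal(get("shorter_than_18nt"), 1)
  expect_equal(get("polyA"), 1)
  expect_equal(get("clean_reads"), 1)
  expect_identical(out$tags$tag, insert)
})

test_that("a pure-A insert is polyA, not clean", {
  fq <- write_test_fastq(pad36(paste0(strrep("A", 20), adapter3)),
                         tempfile(fileext = ".fastq"))
  out <- clean_reads(fq, adapter3, adapter5)
  expect_equal(out$report$count[out$report$type == "polyA"], 1)
  expect_equal(nrow(out$tags), 0L)
})

test_that("reads with N or low mean quality are removed before accounting", {
  seqs <- c(pad36(paste0("ACGTACGTACGTACGTACGTAC", adapter3)),
            pad36(paste0("ACGTACGTNCGTACGTACGTAC", adapter3)))
  fq <- write_test_fastq(seqs, tempfile(fileext = ".fastq"))
  out <- clean_reads(fq, adapter3, adapter5)
  expect_equal(out$report$count[out$report$type == "high_quality"], 1)
  expect_equal(out$report$count[out$report$type == "clean_reads"], 1)
})

test_that("empty and malformed FASTQ are handled per contract", {
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  out <- clean_reads(empty, adapter3, adapter5)
  expect_true(all(out$report$count == 0, na.rm = TRUE))
  expect_equal(nrow(out$tags), 0L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(clean_reads(bad, adapter3, adapter5), "record at index 2")
  expect_error(clean_reads(tempfile(), adapter3, adapter5), "not found")
})

test_that("accounting identity holds on random FASTQ fuzz", {
  set.seed(101)
  for (rep_i in 1:5) {
    n <- sample(50:150, 1)
    seqs <- vapply(seq_len(n), function(i) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(5:30, 1), TRUE),
                   collapse = "")
      if (runif(1) < 0.7) pad36(paste0(ins, adapter3)) else
        pad36(paste0(ins, strrep("T", 36)))
    }, character(1))
    quals <- ifelse(runif(n) < 0.1, strrep("#", 36), strrep("I", 36))
    fq <- write_test_fastq(seqs, tempfile(fileext = ".fastq"), quals = quals)
    r <- clean_reads(fq, adapter3, adapter5)$report
    get <- function(ty) r$count[r$type == ty]
    expect_equal(get("high_quality"),
                 get("clean_reads") + get("adapter3_null") +
                   get("insert_null") + get("adapter5_contaminants") +
                   get("shorter_than_18nt") + get("polyA"))
    expect_equal(get("total_reads"), n)
  }
})

test_that("cleaning is idempotent on already-clean inserts", {
  s <- shared_sim()
  tags <- s$cl[[1]]$tags
  fq <- write_test_fastq(rep(tags$tag, tags$count),
                         tempfile(fileext = ".fastq"))
  again <- clean_reads(fq, adapter3, adapter5)
  r <- again$report
  expect_equal(r$count[r$type == "clean_reads"],
               r$count[r$type == "high_quality"])
  rejoined <- merge(tags, again$tags, by = "tag", all = TRUE)
  expect_false(any(is.na(rejoined$count.x) | is.na(rejoined$count.y)))
  expect_equal(rejoined$count.x, rejoined$count.y)
})

test_that("filter_report recomputes printed-style percentages", {
  r <- filter_report(1000, 10, 5, 25, 40, 20, total_reads = 1010)
  expect_equal(r$count[r$type == "clean_reads"], 900)
  expect_equal(r$percent[r$type == "clean_reads"], 90)
  expect_equal(r$percent[r$type == "adapter3_null"], 1)
  expect_error(filter_report(100, 90, 20, 0, 0, 0), "exceed")
  expect_error(filter_report(100, -1, 0, 0, 0, 0), ">= 0")
  tab <- filter_report_table(list(a = r, b = r))
  expect_equal(tab$total_count[tab$type == "clean_reads"], 1800)
})

test_that("length distribution is weighted, normalized, and empty-safe", {
  tags <- data.table::data.table(
    tag = c(strrep("A", 22), strrep("C", 22), strrep("G", 24)),
    count = c(3L, 2L, 5L))
  ld <- length_distribution(tags)
  expect_equal(ld[length_nt == 22, count], 5L)
  expect_equal(ld[length_nt == 24, fraction], 0.5)
  expect_equal(sum(ld$fraction), 1)
  expect_equal(nrow(length_distribution(tags[0])), 0L)

  one <- length_distribution(data.table::data.table(
    tag = strrep("A", 22), count = 7L))
  expect_equal(one$fraction, 1)

  s <- shared_sim()
  ld2 <- length_distribution(rbind(s$cl[[1]]$tags, s$cl[[2]]$tags))
  expect_equal(ld2$fraction, ld2$count / sum(ld2$count))
  # empirical mode equals the mode expected from the planted truth: the
  # miRNA part is abundance-weighted over the planted mature lengths, the
  # contaminant/background part follows the configured length profile
  mir <- s$truth$mirna
  wlen <- tapply(mir$w1 + mir$w2, nchar(mir$mature_seq), sum)
  mir_frac <- 1 - sum(s$cfg$contamination_fractions)
  expected <- s$cfg$length_profile * (1 - mir_frac)
  expected[names(wlen)] <- expected[names(wlen)] +
    mir_frac * wlen / sum(mir$w1 + mir$w2)
  expect_equal(ld2[which.max(count), length_nt],
               as.integer(names(which.max(expected))))
})

test_that("collapse_tags conserves counts and orders deterministically", {
  t1 <- data.table::data.table(tag = c(strrep("AC", 11), strrep("TG", 11)),
                               count = c(3L, 1L))
  t2 <- data.table::data.table(tag = c(strrep("TG", 11), strrep("GA", 11)),
                               count = c(2L, 9L))
  u <- collapse_tags(t1, t2)
  expect_equal(u[tag == strrep("AC", 11), c(count_lib1, count_lib2)],
               c(3L, 0L))
  expect_equal(u$tag[1], strrep("GA", 11))   # highest total first
  expect_true(all(nchar(u$tag) >= 18 & nchar(u$tag) <= 30))

  s <- shared_sim()
  u2 <- s$tags
  expect_equal(sum(u2$count_lib1),
               s$cl[[1]]$report$count[s$cl[[1]]$report$type == "clean_reads"])
  expect_equal(sum(u2$count_lib2),
               s$cl[[2]]$report$count[s$cl[[2]]$report$type == "clean_reads"])
  expect_equal(anyDuplicated(u2$tag), 0L)
})

test_that("noise-free simulated library cleans losslessly", {
  cfg <- sim_config(seed = 5, n_mirnas = 10, library_depths = c(3000, 3000),
                    contamination_fractions = c(low_quality = 0),
                    error_rate = 0, n_novel_hairpins = 0)
  refs <- build_reference_set(cfg)
  truth <- simulate_libraries(cfg, refs, tempfile())
  out <- clean_reads(truth$fastq[1], cfg$adapter3, cfg$adapter5)
  r <- out$report
  expect_equal(r$count[r$type == "clean_reads"], 3000)
  expect_equal(sum(out$tags$count), 3000)
  expect_true(all(out$tags$tag %in% refs$mature))
})
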