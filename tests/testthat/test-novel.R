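test_that("folding reproduces canonical hairpins and degenerate cases", {
  f <- fold_sequence("GGGGAAACCCC")
  expect_equal(f$structure, "((((...))))")
  expect_equal(f$n_pairs, 4L)
  expect_equal(f$energy, 4 * -3 + 3 * -1)   # 4 GC pairs, 3 stacks

  fa <- fold_sequence(strrep("A", 30))
  expect_equal(fa$energy, 0)
  expect_equal(fa$structure, strrep(".", 30))
  expect_equal(fa$n_pairs, 0L)

  expect_error(fold_sequence("ACGTX"), "invalid")
  expect_equal(fold_sequence("ACGU")$structure, "....")  # too short to pair

  # dot-bracket is balanced and same length, structure matches energy
  pm <- fold_sequence("GGGGAAACCCC", model = "pairmax")
  expect_equal(pm$n_pairs, 4L)
  expect_equal(pm$energy, -4)
})

test_that("folding DP attains the enumeration optimum on random 12-mers", {
  set.seed(19)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    for (model in c("stack", "pairmax")) {
      got <- fold_sequence(s, model = model)
      expect_equal(got$energy, oracle_fold(s, model = model),
                   info = paste(model, s))
      # reported structure is consistent with the reported energy
      pr <- ovamir:::dotbracket_partners(strsplit(got$structure, "")[[1]])
      expect_equal(sum(pr > 0) %/% 2, got$n_pairs)
    }
  }
})

test_that("planted hairpin construction folds as designed", {
  set.seed(8)
  mature <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  hp <- paste0(mature, strrep("A", 8), ovamir:::revcomp_chr(mature))
  f <- fold_sequence(hp)
  expect_gte(f$n_pairs, nchar(mature) - 2L)
})

test_that("window extraction does the stated arithmetic and merging", {
  genome <- c(chrA = strrep("ACGT", 500))   # 2000 nt
  tag22 <- substr(genome[["chrA"]], 501, 522)
  h <- data.table::data.table(tag = tag22, chrom = "chrA", start = 500L,
                              strand = "+", count_lib1 = 5L,
                              count_lib2 = 0L)
  ec <- extract_candidates(h, genome, flank = 70L)
  expect_equal(ec$windows$start, 430L)
  expect_equal(ec$windows$end, 592L)

  h2 <- rbind(h, data.table::data.table(
    tag = substr(genome[["chrA"]], 533, 554), chrom = "chrA",
    start = 532L, strand = "+", count_lib1 = 2L, count_lib2 = 0L))
  ec2 <- extract_candidates(h2, genome, flank = 70L)
  expect_equal(nrow(ec2$windows), 1L)

  # window clipping at chromosome bounds
  h3 <- data.table::data.table(tag = substr(genome[["chrA"]], 11, 32),
                               chrom = "chrA", start = 10L, strand = "+",
                               count_lib1 = 1L, count_lib2 = 0L)
  ec3 <- extract_candidates(h3, genome, flank = 70L)
  expect_equal(ec3$windows$start, 0L)

  # repeat-like tags (> max_loci hits) are discarded
  many <- data.table::data.table(
    tag = "ACGTACGTACGTACGTACGTAC", chrom = "chrA",
    start = seq(0L, 1900L, by = 100L), strand = "+",
    count_lib1 = 1L, count_lib2 = 0L)
  ec4 <- extract_candidates(many, genome, flank = 10L, max_loci = 15L)
  expect_equal(nrow(ec4$windows), 0L)
})

test_that("criteria flags fail for poor energy and scattered reads", {
  set.seed(33)
  mature <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  hairpin <- paste0(strrep("A", 10), mature, strrep("A", 8),
                    ovamir:::revcomp_chr(mature), strrep("A", 10))
  genome <- c(chrH = paste0(strrep("A", 300), hairpin, strrep("A", 300)))
  feats <- GenomicRanges::GRanges("chrH", IRanges::IRanges(1, 10),
                                  strand = "+", type = "exon", id = "x")

  support <- data.table::data.table(
    tag = mature, chrom = "chrH", start = 310L, strand = "+",
    count_lib1 = 30L, count_lib2 = 30L)
  cands <- extract_candidates(support, genome)
  nv <- call_novel(cands, genome, feats)
  expect_equal(nrow(nv), 1L)
  expect_true(nv$pass)
  expect_true(nv$ok_energy && nv$ok_dicer && nv$ok_pairing)

  # same support, but folding an unstructured all-A region: energy fails
  supA <- data.table::data.table(
    tag = substr(genome[["chrH"]], 51, 72),
    chrom = "chrH", start = 50L, strand = "+",
    count_lib1 = 30L, count_lib2 = 0L)
  nvA <- call_novel(extract_candidates(supA, genome), genome, feats)
  expect_false(nvA$ok_energy)
  expect_false(nvA$pass)

  # scattered 5' ends fail the Dicer criterion (and skip folding)
  scat <- data.table::data.table(
    tag = vapply(0:9, function(k) substr(genome[["chrH"]], 301 + 7 * k,
                                         322 + 7 * k), character(1)),
    chrom = "chrH", start = seq(300L, by = 7L, length.out = 10L),
    strand = "+", count_lib1 = 3L, count_lib2 = 3L)
  nvS <- call_novel(extract_candidates(scat, genome), genome, feats)
  expect_false(any(nvS$ok_dicer))
  expect_true(all(is.na(nvS$energy)))
  expect_false(any(nvS$pass))

  # a candidate overlapping known annotation is rejected
  feats2 <- GenomicRanges::GRanges("chrH", IRanges::IRanges(250, 400),
                                   strand = "+", type = "exon", id = "x")
  nv2 <- call_novel(cands, genome, feats2)
  expect_false(nv2$ok_unannotated)
  expect_false(nv2$pass)
})

test_that("planted novel loci are recovered; none inside annotation", {
  s <- shared_sim()
  hits <- attr(s$ann, "hits")
  unann_hits <- merge(hits,
                      s$ann[category == "unann",
                            .(tag, count_lib1, count_lib2)], by = "tag")
  cands <- extract_candidates(unann_hits, s$refs$genome)
  nv <- call_novel(cands, s$refs$genome, s$refs$features)
  passed <- nv[pass == TRUE]
  # every planted locus is hit by exactly one passing candidate
  truth <- s$refs$novel_loci
  for (i in seq_len(nrow(truth))) {
    hit <- passed[chrom == truth$chrom[i] & start <= truth$start[i] + 10 &
                    end >= truth$end[i] - 10]
    expect_equal(nrow(hit), 1L, info = truth$id[i])
  }
  # no passing candidate overlaps known annotation (criterion built in)
  gr <- GenomicRanges::GRanges(passed$chrom,
                               IRanges::IRanges(passed$start + 1L,
                                                passed$end))
  expect_equal(length(GenomicRanges::findOverlaps(gr, s$refs$features)), 0L)
})

test_that("candidate BED export round-trips coordinates bit-exactly", {
  nv <- data.table::data.table(
    window_id = 1:2, chrom = c("chr1", "chr2"), start = c(100L, 50L),
    end = c(180L, 140L), strand = c("+", "-"),
    precursor_seq = "ACGT", structure = "....", energy = -20,
    mature_seq = "ACGT", mature_start = 110L)
  bed <- tempfile(fileext = ".bed")
  txt <- tempfile(fileext = ".txt")
  export_novel(nv, bed_path = bed, structure_path = txt)
  gr <- rtracklayer::import.bed(bed)
  expect_equal(GenomicRanges::start(gr) - 1L, nv$start)
  expect_equal(GenomicRanges::end(gr), nv$end)
  expect_equal(as.character(GenomicRanges::strand(gr)), nv$strand)
  expect_equal(length(readLines(txt)), 6L)
})
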