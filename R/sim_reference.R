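#' Build the synthetic reference bundle
#'
#' Constructs a self-contained toy study reference: a small genome hosting
#' known miRNA precursor loci, ncRNA genes, repeats, exon/intron gene models
#' and planted novel hairpin loci; FASTA-style mature/precursor and ncRNA
#' reference sets; a 3' UTR set; and gene-to-GO-term / gene-to-pathway maps.
#' Precursors fold into hairpins by construction: the mature arm is followed
#' by an 8 nt loop and the reverse complement of the mature sequence carrying
#' at most 2 mutations (the star arm). Novel loci use the same construction
#' but are planted only in the genome, never in the miRNA reference.
#'
#' @param config a [sim_config()] object.
#' @return object of class `ref_bundle`: list with elements `genome`
#'   (named character vector of chromosome sequences), `features`
#'   ([GenomicRanges::GRanges] with a `type` metadata column), `mature` and
#'   `precursor` (named character vectors), `mature_meta` (data.table),
#'   `ncrna` (list of named character vectors per ncRNA class), `utr`
#'   (named character vector), `go_map` and `kegg_map` (data.tables with
#'   columns gene_id, term_id, ontology), and `novel_loci` (data.table of
#'   planted loci with precursor coordinates and mature arm).
#' @export
#' @examples
#' refs <- build_reference_set(sim_config(seed = 1, n_mirnas = 10))
#' names(refs$genome)
build_reference_set <- function(config) {
  validate_sim_config(config)
  set.seed(sim_child_seed(config, 1L))

  mat_lens <- mirna_lengths(config, config$n_mirnas + config$n_novel_hairpins)
  mats <- unique_random_dna(config$n_mirnas + config$n_novel_hairpins, mat_lens)
  known_idx <- seq_len(config$n_mirnas)
  mature <- mats[known_idx]
  names(mature) <- sprintf("toy-miR-%04d", known_idx)
  novel_mat <- mats[setdiff(seq_along(mats), known_idx)]
  if (length(novel_mat))
    names(novel_mat) <- sprintf("novel-%03d", seq_along(novel_mat))

  prec_known <- vapply(mature, make_hairpin_precursor, character(1))
  names(prec_known) <- sub("miR", "mir", names(mature))
  prec_novel <- vapply(novel_mat, make_hairpin_precursor, character(1))

  ncrna <- list(
    rRNA = setNames(random_dna(rep(150L, 3)), sprintf("rRNA-%d", 1:3)),
    tRNA = setNames(random_dna(rep(76L, 4)), sprintf("tRNA-%d", 1:4)),
    snRNA = setNames(random_dna(rep(110L, 3)), sprintf("snRNA-%d", 1:3)),
    snoRNA = setNames(random_dna(rep(95L, 3)), sprintf("snoRNA-%d", 1:3)),
    scRNA = setNames(random_dna(rep(120L, 2)), sprintf("scRNA-%d", 1:2)),
    srpRNA = setNames(random_dna(rep(130L, 2)), sprintf("srpRNA-%d", 1:2))
  )

  # genomic blocks: (id, type, sequence, strand); novel loci carry no feature
  blocks <- data.table::data.table(
    id = c(names(prec_known), unlist(lapply(ncrna, names), use.names = FALSE)),
    type = c(rep("miRNA", length(prec_known)),
             rep(names(ncrna), lengths(ncrna))),
    seq_ = c(unname(prec_known), unlist(ncrna, use.names = FALSE))
  )
  rep_seqs <- random_dna(rep(180L, 3))
  blocks <- rbind(blocks, data.table::data.table(
    id = sprintf("repeat-%d", 1:6), type = "repeat",
    seq_ = rep(rep_seqs, each = 2)))
  for (g in 1:6) {
    ex1 <- random_dna(150L); intr <- random_dna(200L); ex2 <- random_dna(150L)
    blocks <- rbind(blocks, data.table::data.table(
      id = sprintf("gene%02d_%s", g, c("exon1", "intron1", "exon2")),
      type = c("exon", "intron", "exon"),
      seq_ = c(ex1, intr, ex2)))
  }
  if (length(prec_novel)) {
    names(prec_novel) <- names(novel_mat)
    blocks <- rbind(blocks, data.table::data.table(
      id = names(prec_novel), type = "novel", seq_ = unname(prec_novel)))
  }
  blocks[, strand := ifelse(type %in% c("exon", "intron"),
                            rep(sample(c("+", "-"), .N, replace = TRUE), 1), "+")]
  # keep the three segments of one gene on a common strand
  blocks[type %in% c("exon", "intron"),
         strand := strand[1L], by = .(sub("_.*", "", id))]
  blocks[type == "novel", strand := "+"]
  ord <- sample(nrow(blocks))
  blocks <- blocks[ord]

  n_chr <- 2L
  blocks[, chrom := sprintf("chr%d", rep_len(seq_len(n_chr), .N))]
  asm <- assemble_genome(blocks, config$genome_size)

  nov <- asm$features[asm$features$type == "novel", ]
  novel_loci <- data.table::data.table(
    id = nov$id, chrom = nov$chrom, start = nov$start, end = nov$end,
    strand = nov$strand,
    precursor_seq = unname(prec_novel[nov$id]),
    mature_seq = unname(novel_mat[nov$id])
  )
  # mature arm sits 10 nt into the precursor (5' flank length)
  novel_loci[, mature_start := start + 10L]
  novel_loci[, mature_end := mature_start + nchar(mature_seq)]

  feat <- asm$features[asm$features$type != "novel", ]
  features <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand, type = feat$type, id = feat$id)

  mirna_feat <- feat[feat$type == "miRNA", ]
  mature_meta <- data.table::data.table(
    mirna_id = names(mature),
    precursor_id = names(prec_known),
    mature_seq = unname(mature),
    mature_offset = 10L,
    chrom = mirna_feat$chrom[match(names(prec_known), mirna_feat$id)],
    start = mirna_feat$start[match(names(prec_known), mirna_feat$id)],
    strand = mirna_feat$strand[match(names(prec_known), mirna_feat$id)]
  )

  utr_len <- sample(200:600, config$n_genes, replace = TRUE)
  utr <- setNames(random_dna(utr_len), sprintf("gene%04d", seq_len(config$n_genes)))

  go_map <- make_term_map(names(utr),
                          ontologies = c("cellular_component",
                                         "molecular_function",
                                         "biological_process"),
                          n_terms = config$n_terms_per_ontology,
                          prefix = "GO")
  kegg_map <- make_term_map(names(utr), ontologies = "pathway",
                            n_terms = config$n_pathways, prefix = "path")

  out <- list(
    genome = asm$genome, features = features,
    mature = mature, precursor = prec_known,
    mature_meta = mature_meta, ncrna = ncrna, utr = utr,
    go_map = go_map, kegg_map = kegg_map, novel_loci = novel_loci,
    config = config
  )
  class(out) <- "ref_bundle"
  out
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("ref_bundle:", length(x$genome), "chromosomes (",
      sum(nchar(x$genome)), "bp ),", length(x$mature), "known miRNAs,",
      nrow(x$novel_loci), "planted novel loci,",
      length(x$utr), "UTRs\n")
  invisible(x)
}

# mature lengths are drawn from the 20-24 nt slice of the configured profile
mirna_lengths <- function(config, n) {
  lp <- config$length_profile
  core <- lp[names(lp) %in% as.character(20:24)]
  sample(as.integer(names(core)), n, replace = TRUE, prob = core / sum(core))
}

unique_random_dna <- function(n, lens) {
  out <- random_dna(lens)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_dna(lens[dup])
  }
  out
}

# 5' flank (10) + mature + loop (8) + star (revcomp mature, <=2 mutations) +
# 3' flank (10); mature arm is always the 5' arm.
make_hairpin_precursor <- function(mature, loop_len = 8L, flank = 10L) {
  star <- revcomp_chr(mature)
  n_mut <- sample(0:2, 1)
  if (n_mut > 0) {
    pos <- sample(nchar(star), n_mut)
    ch <- strsplit(star, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    star <- paste(ch, collapse = "")
  }
  paste0(random_dna(flank), mature, random_dna(loop_len), star, random_dna(flank))
}

# scalar/small-vector reverse complement; plain string ops, as the S4 route
# has noticeable per-call overhead (use revcomp_chr_vec for large vectors)
revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGTUacgtu", "TGCAAtgcaa", x), NULL),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Concatenate blocks with random spacers into chromosomes; returns genome and
# 0-based half-open feature coordinates. Minus-strand blocks are planted as
# their reverse complement.
assemble_genome <- function(blocks, genome_size = NULL) {
  chroms <- unique(blocks$chrom)
  genome <- character(0)
  feats <- list()
  for (ch in chroms) {
    b <- blocks[blocks$chrom == ch, ]
    pieces <- character(0)
    pos <- 0L
    for (i in seq_len(nrow(b))) {
      sp <- random_dna(sample(100:300, 1))
      pieces <- c(pieces, sp)
      pos <- pos + nchar(sp)
      s <- if (b$strand[i] == "-") revcomp_chr(b$seq_[i]) else b$seq_[i]
      pieces <- c(pieces, s)
      feats[[length(feats) + 1L]] <- data.table::data.table(
        chrom = ch, start = pos, end = pos + nchar(s),
        strand = b$strand[i], type = b$type[i], id = b$id[i])
      pos <- pos + nchar(s)
    }
    tail_sp <- random_dna(sample(100:300, 1))
    genome[ch] <- paste(c(pieces, tail_sp), collapse = "")
  }
  total <- sum(nchar(genome))
  if (!is.null(genome_size)) {
    if (genome_size < total)
      stop("genome_size ", genome_size,
           " too small to host all planted features (need >= ", total, ")")
    pad <- genome_size - total
    if (pad > 0) {
      per <- diff(round(seq(0, pad, length.out = length(genome) + 1L)))
      genome <- vapply(seq_along(genome), function(i)
        paste0(genome[i], random_dna(per[i])), character(1)) |>
        setNames(names(genome))
    }
  }
  list(genome = genome, features = data.table::rbindlist(feats))
}

# Skewed term sizes: each gene draws 1-3 terms per ontology, term popularity
# geometric-ish so a few terms are large (as real GO slims are).
make_term_map <- function(genes, ontologies, n_terms, prefix) {
  maps <- lapply(ontologies, function(ont) {
    terms <- sprintf("%s:%s%03d", prefix, substr(ont, 1, 2), seq_len(n_terms))
    w <- 1 / seq_len(n_terms)
    k <- sample(1:3, length(genes), replace = TRUE)
    data.table::data.table(
      gene_id = rep(genes, k),
      term_id = sample(terms, sum(k), replace = TRUE, prob = w),
      ontology = ont)
  })
  unique(data.table::rbindlist(maps))
}
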