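#' Simulate two small RNA sequencing libraries
#'
#' Draws per-read provenance categories from the configured contamination
#' fractions (remainder: known-miRNA signal), assembles 36-cycle reads as
#' `insert + 3' adapter + filler` (with category-specific deviations such as
#' missing adapters, adapter dimers, 5'-adapter prefixes, polyA artifacts and
#' injected low-quality reads), applies uniform substitution errors, and
#' writes Phred+33 FASTQ files. miRNA abundances are log-normal so a few
#' miRNAs dominate; a `de_fraction` of miRNAs carries a planted
#' `2^planted_log2fc` difference between the libraries (half up, half down in
#' library 2).
#'
#' @param config a [sim_config()].
#' @param refs a [build_reference_set()] bundle.
#' @param out_dir directory for `lib1.fastq` / `lib2.fastq`.
#' @return object of class `sim_truth`: list with `fastq` (paths), `mirna`
#'   (per-miRNA truth: abundance weights, expected and actually sampled
#'   counts per library, DE direction), `reads` (per-read provenance:
#'   library, read id, category, source id), `novel` (planted loci with
#'   sampled read counts), and `category_counts`.
#' @export
simulate_libraries <- function(config, refs,
                               out_dir = tempfile("ovamir_sim_")) {
  validate_sim_config(config)
  stopifnot(inherits(refs, "ref_bundle"))
  set.seed(sim_child_seed(config, 2L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n <- config$n_mirnas
  w <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  n_de <- floor(config$de_fraction * n)
  de_status <- integer(n)
  if (n_de > 0) {
    de_idx <- sample(n, n_de)
    de_status[de_idx] <- rep_len(c(1L, -1L), n_de)
  }
  w1 <- w
  w2 <- w * 2^(de_status * config$planted_log2fc)

  frac <- config$contamination_fractions
  frac_mirna <- 1 - sum(frac)
  cats <- c(names(frac), "mirna")
  probs <- c(unname(frac), frac_mirna)

  mirna_dt <- data.table::data.table(
    mirna_id = names(refs$mature), mature_seq = unname(refs$mature),
    de_status = de_status, w1 = w1, w2 = w2,
    expected_count_1 = config$library_depths[1] * frac_mirna * w1 / sum(w1),
    expected_count_2 = config$library_depths[2] * frac_mirna * w2 / sum(w2))

  gaps <- unannotated_gaps(refs)
  reads_truth <- list()
  fastq <- character(2)
  sampled <- list()
  for (l in 1:2) {
    D <- config$library_depths[l]
    fastq[l] <- file.path(out_dir, sprintf("lib%d.fastq", l))
    if (D == 0L) {
      file.create(fastq[l])
      next
    }
    categ <- sample(cats, D, replace = TRUE, prob = probs)
    lib <- simulate_one_library(config, refs, categ,
                                if (l == 1L) w1 else w2, gaps)
    ids <- sprintf("lib%d:%07d", l, seq_len(D))
    write_fastq(lib$seqs, lib$quals, ids, fastq[l])
    reads_truth[[l]] <- data.table::data.table(
      library_ = l, read_id = ids, category = categ, source_id = lib$source)
    sampled[[l]] <- lib
  }
  reads <- if (length(reads_truth)) data.table::rbindlist(reads_truth) else
    data.table::data.table(library_ = integer(), read_id = character(),
                           category = character(), source_id = character())

  mcounts <- reads[category == "mirna",
                   .(count = .N), by = .(library_, source_id)]
  mirna_dt[, count_1 := 0L][, count_2 := 0L]
  for (l in 1:2) {
    mc <- mcounts[library_ == l]
    col <- paste0("count_", l)
    mirna_dt[match(mc$source_id, mirna_id), (col) := mc$count]
  }

  ncounts <- reads[category == "novel", .(count = .N), by = .(library_, source_id)]
  novel <- data.table::copy(refs$novel_loci)
  if (nrow(novel)) {
    for (l in 1:2) {
      nc <- ncounts[library_ == l]
      col <- paste0("count_", l)
      novel[, (col) := 0L]
      novel[match(nc$source_id, id), (col) := nc$count]
    }
  }

  out <- list(
    fastq = fastq,
    mirna = mirna_dt,
    reads = reads,
    novel = novel,
    category_counts = reads[, .(n = .N), by = .(library_, category)]
  )
  class(out) <- "sim_truth"
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$reads), "reads in", sum(nzchar(x$fastq)),
      "libraries;", nrow(x$mirna), "miRNAs (",
      sum(x$mirna$de_status != 0), "planted DE );",
      nrow(x$novel), "novel loci\n")
  invisible(x)
}

# ---- internals ---------------------------------------------------------

simulate_one_library <- function(config, refs, categ, w, gaps) {
  D <- length(categ)
  L <- config$read_length
  inserts <- character(D)
  source <- rep(NA_character_, D)
  raw36 <- logical(D)     # reads emitted as-is, no adapter appended
  lowq <- categ == "low_quality"

  draw_len <- function(k, cap = Inf) {
    len <- sample(as.integer(names(config$length_profile)), k, replace = TRUE,
                  prob = config$length_profile)
    pmin(len, cap)
  }

  for (cat_i in unique(categ)) {
    idx <- which(categ == cat_i)
    k <- length(idx)
    if (cat_i %in% c("mirna", "low_quality")) {
      j <- sample(length(refs$mature), k, replace = TRUE, prob = w)
      inserts[idx] <- unname(refs$mature[j])
      source[idx] <- names(refs$mature)[j]
    } else if (cat_i %in% names(refs$ncrna)) {
      pool <- refs$ncrna[[cat_i]]
      j <- sample(length(pool), k, replace = TRUE)
      len <- draw_len(k, nchar(pool[j]))
      off <- floor(runif(k) * (nchar(pool[j]) - len + 1)) + 1L
      inserts[idx] <- substr(pool[j], off, off + len - 1L)
      source[idx] <- names(pool)[j]
    } else if (cat_i %in% c("repeat", "exon", "intron")) {
      ft <- refs$features[refs$features$type == cat_i]
      j <- sample(length(ft), k, replace = TRUE)
      wdt <- GenomicRanges::width(ft)[j]
      len <- draw_len(k, wdt)
      off <- floor(runif(k) * (wdt - len + 1))
      chrom <- as.character(GenomicRanges::seqnames(ft))[j]
      st <- GenomicRanges::start(ft)[j] + off
      s <- substr(refs$genome[chrom], st, st + len - 1L)
      flip <- runif(k) < 0.5
      s[flip] <- revcomp_chr_vec(s[flip])
      inserts[idx] <- s
      source[idx] <- ft$id[j]
    } else if (cat_i == "unann") {
      j <- sample(nrow(gaps), k, replace = TRUE, prob = gaps$width)
      len <- draw_len(k, gaps$width[j])
      off <- floor(runif(k) * (gaps$width[j] - len + 1))
      st <- gaps$start[j] + off + 1L
      inserts[idx] <- substr(refs$genome[gaps$chrom[j]], st, st + len - 1L)
      source[idx] <- sprintf("%s:%d", gaps$chrom[j], st - 1L)
    } else if (cat_i == "novel") {
      if (nrow(refs$novel_loci) == 0L) {
        inserts[idx] <- random_dna(draw_len(k)); source[idx] <- "none"
      } else {
        j <- sample(nrow(refs$novel_loci), k, replace = TRUE)
        ins <- refs$novel_loci$mature_seq[j]
        shift <- runif(k) < config$novel_end_jitter
        ins[shift] <- substr(refs$novel_loci$precursor_seq[j[shift]], 12L,
                             11L + nchar(ins[shift]))
        inserts[idx] <- ins
        source[idx] <- refs$novel_loci$id[j]
      }
    } else if (cat_i == "polyA") {
      inserts[idx] <- strrep("A", draw_len(k))
      source[idx] <- "polyA"
    } else if (cat_i == "short") {
      inserts[idx] <- random_dna(sample(10:17, k, replace = TRUE))
      source[idx] <- "short"
    } else if (cat_i == "adapter5") {
      # contaminant insert capped at 28 nt so the 3' adapter stays readable
      # within the fixed 36 cycles
      j <- sample(length(refs$mature), k, replace = TRUE, prob = w)
      pre <- substr(config$adapter5, 1L, sample(8:10, k, replace = TRUE))
      frag <- substr(unname(refs$mature[j]), 1L, 28L - nchar(pre))
      inserts[idx] <- paste0(pre, frag)
      source[idx] <- names(refs$mature)[j]
    } else if (cat_i == "insert_null") {
      inserts[idx] <- ""
      source[idx] <- "dimer"
    } else if (cat_i == "adapter3_null") {
      inserts[idx] <- random_dna(rep(L, k))
      source[idx] <- "no_adapter"
      raw36[idx] <- TRUE
    }
  }

  full <- ifelse(raw36, inserts, paste0(inserts, config$adapter3))
  short_of <- pmax(0L, L - nchar(full))
  need <- which(short_of > 0L)
  if (length(need))
    full[need] <- paste0(full[need], random_dna(short_of[need]))
  seqs <- substr(full, 1L, L)
  seqs <- apply_substitution_errors(seqs, config$error_rate, L)
  quals <- make_quality_strings(D, L, lowq)
  list(seqs = seqs, quals = quals, source = source)
}

revcomp_chr_vec <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_substitution_errors <- function(seqs, rate, L) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  total <- length(seqs) * L
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  pos <- sample.int(total, n_err)
  ri <- ((pos - 1L) %/% L) + 1L
  pj <- ((pos - 1L) %% L) + 1L
  bases <- c("A", "C", "G", "T")
  for (e in seq_len(n_err)) {
    old <- substr(seqs[ri[e]], pj[e], pj[e])
    substr(seqs[ri[e]], pj[e], pj[e]) <- sample(setdiff(bases, old), 1L)
  }
  seqs
}

# one long Phred+33 string, cut into per-read windows (all reads same width)
make_quality_strings <- function(D, L, lowq) {
  q <- integer(D * L)
  hi <- !rep(lowq, each = L)
  q[hi] <- sample(28:40, sum(hi), replace = TRUE)
  q[!hi] <- sample(3:17, sum(!hi), replace = TRUE)
  all_chr <- rawToChar(as.raw(33L + q))
  substring(all_chr, seq(1L, D * L, by = L), seq(L, D * L, by = L))
}

# inter-feature gaps wide enough to source unannotated background reads
unannotated_gaps <- function(refs, min_width = 40L) {
  chrom_len <- nchar(refs$genome)
  occupied <- refs$features
  if (nrow(refs$novel_loci))
    occupied <- c(occupied, GenomicRanges::GRanges(
      refs$novel_loci$chrom,
      IRanges::IRanges(refs$novel_loci$start + 1L, refs$novel_loci$end),
      strand = "*"))
  dt <- list()
  for (ch in names(chrom_len)) {
    occ <- IRanges::reduce(IRanges::ranges(
      occupied[as.character(GenomicRanges::seqnames(occupied)) == ch]))
    gap <- IRanges::gaps(occ, start = 1L, end = chrom_len[[ch]])
    gap <- gap[IRanges::width(gap) >= min_width]
    if (length(gap))
      dt[[ch]] <- data.table::data.table(
        chrom = ch, start = IRanges::start(gap) - 1L,
        width = IRanges::width(gap))
  }
  data.table::rbindlist(dt)
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Simulate a qPCR CT table from planted truth
#'
#' Emulates triplicate RT-PCR of selected miRNAs against a reference RNA
#' channel in the two groups. CT values follow the log2 model
#' `CT = 30 - log2(abundance) + noise` so a doubling of true abundance lowers
#' CT by one cycle; the reference channel sits at `CT = 18 + noise`.
#'
#' @param config a [sim_config()].
#' @param truth a [simulate_libraries()] truth object.
#' @param mirna_ids optional explicit miRNA selection; default: `n_qpcr`
#'   miRNAs sampled among those with expected count >= 20 in both libraries
#'   (topped up by total expression if too few qualify).
#' @return data.table with columns `mirna_id`, `group` ("Mul" control /
#'   "Uni" treatment), `replicate`, `ct`, `ct_ref`.
#' @export
simulate_ct_table <- function(config, truth, mirna_ids = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(sim_child_seed(config, 3L))
  mt <- truth$mirna
  if (is.null(mirna_ids)) {
    ok <- mt[expected_count_1 >= 20 & expected_count_2 >= 20, mirna_id]
    k <- min(config$n_qpcr, nrow(mt))
    if (length(ok) >= k) {
      mirna_ids <- sample(ok, k)
    } else {
      extra <- mt[order(-(expected_count_1 + expected_count_2))][
        !mirna_id %in% ok, mirna_id]
      mirna_ids <- c(ok, head(extra, k - length(ok)))
    }
  }
  sel <- mt[match(mirna_ids, mirna_id)]
  rows <- list()
  for (g in 1:2) {
    a <- pmax(0.5, sel[[paste0("expected_count_", g)]]) /
      max(1L, config$library_depths[g]) * 1e6
    for (r in 1:3) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        mirna_id = sel$mirna_id,
        group = c("Mul", "Uni")[g],
        replicate = r,
        ct = 30 - log2(a) + rnorm(nrow(sel), 0, config$ct_noise_sd),
        ct_ref = 18 + rnorm(nrow(sel), 0, config$ct_noise_sd))
    }
  }
  data.table::rbindlist(rows)[order(mirna_id, group, replicate)]
}
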