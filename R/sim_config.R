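#' Simulation configuration for a synthetic two-library small RNA study
#'
#' Builds and validates the single configuration object consumed by
#' [build_reference_set()], [simulate_libraries()] and [simulate_ct_table()].
#' Defaults describe the study being emulated: two ~36-cycle Solexa-era
#' libraries of 18-30 nt small RNA inserts dominated by 20-24 nt miRNA tags
#' (peak at 22 nt), with ligated 3'/5' adapters, a small fraction of
#' low-quality reads and technical contaminants at roughly the rates seen in
#' the emulated study's filter table, ncRNA contamination, and a log-normal
#' miRNA abundance skew so that a few miRNAs dominate both libraries.
#'
#' @param seed integer seed; every downstream stage derives its RNG stream
#'   from it, so a fixed config is byte-reproducible.
#' @param n_mirnas number of known (conserved) miRNAs in the reference.
#' @param n_novel_hairpins number of novel hairpin loci planted in the genome
#'   but absent from the miRNA reference.
#' @param library_depths integer pair, reads per library.
#' @param adapter3,adapter5 adapter sequences (defaults: Illumina small RNA
#'   adapters; the emulated protocol names none).
#' @param contamination_fractions named numeric vector of per-read category
#'   probabilities (see Details); the remainder is known-miRNA signal.
#' @param de_fraction fraction of miRNAs with a planted fold change.
#' @param planted_log2fc absolute log2 fold change planted into DE miRNAs
#'   (half up in library 2, half down).
#' @param length_profile named numeric vector of insert-length probabilities
#'   over 18..30 nt; normalized to sum to 1.
#' @param read_length fixed sequencing cycle count (36, adapter read-through
#'   is therefore the norm and trimming non-trivial).
#' @param error_rate per-base uniform substitution error rate.
#' @param abundance_sdlog sdlog of the log-normal miRNA abundance draw.
#' @param n_genes number of genes with a 3' UTR in the toy gene set.
#' @param n_terms_per_ontology GO terms simulated per ontology.
#' @param n_pathways pathways simulated.
#' @param n_qpcr miRNAs carried into the simulated CT table.
#' @param ct_noise_sd Gaussian SD (cycles) of simulated CT values.
#' @param novel_end_jitter fraction of novel-locus reads whose 5' end is
#'   shifted by 1 nt (the rest share the modal Dicer-like 5' end).
#' @param genome_size optional total genome size (bases); `NULL` sizes the
#'   genome automatically. An explicit value too small to host all planted
#'   features is an error.
#'
#' @details Categories recognized in `contamination_fractions`: `low_quality`,
#' `adapter3_null`, `insert_null`, `adapter5`, `short`, `polyA` (technical),
#' `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `scRNA`, `srpRNA` (ncRNA contamination),
#' `repeat`, `exon`, `intron`, `unann` (genomic background), `novel` (reads
#' from planted novel hairpins). Fractions must sum to < 1.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_mirnas = 20, library_depths = c(2000, 2000))
#' cfg$n_mirnas
sim_config <- function(seed = 1L,
                       n_mirnas = 50L,
                       n_novel_hairpins = 3L,
                       library_depths = c(100000L, 100000L),
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       contamination_fractions = c(
                         low_quality = 0.006,
                         adapter3_null = 0.0002,
                         insert_null = 0.0001,
                         adapter5 = 0.0016,
                         short = 0.0010,
                         polyA = 0.00002,
                         rRNA = 0.030,
                         tRNA = 0.008,
                         snRNA = 0.004,
                         snoRNA = 0.004,
                         scRNA = 0.001,
                         srpRNA = 0.001,
                         "repeat" = 0.002,
                         exon = 0.005,
                         intron = 0.005,
                         unann = 0.028,
                         novel = 0.002
                       ),
                       de_fraction = 0.1,
                       planted_log2fc = 2,
                       length_profile = c(
                         "18" = 0.010, "19" = 0.015, "20" = 0.050,
                         "21" = 0.150, "22" = 0.450, "23" = 0.150,
                         "24" = 0.080, "25" = 0.030, "26" = 0.020,
                         "27" = 0.015, "28" = 0.012, "29" = 0.010,
                         "30" = 0.008
                       ),
                       read_length = 36L,
                       error_rate = 0.001,
                       abundance_sdlog = 1.5,
                       n_genes = 300L,
                       n_terms_per_ontology = 20L,
                       n_pathways = 15L,
                       n_qpcr = 5L,
                       ct_noise_sd = 0.25,
                       novel_end_jitter = 0.1,
                       genome_size = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_mirnas = as.integer(n_mirnas),
    n_novel_hairpins = as.integer(n_novel_hairpins),
    library_depths = as.integer(library_depths),
    adapter3 = toupper(adapter3),
    adapter5 = toupper(adapter5),
    contamination_fractions = contamination_fractions,
    de_fraction = de_fraction,
    planted_log2fc = planted_log2fc,
    length_profile = length_profile / sum(length_profile),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    abundance_sdlog = abundance_sdlog,
    n_genes = as.integer(n_genes),
    n_terms_per_ontology = as.integer(n_terms_per_ontology),
    n_pathways = as.integer(n_pathways),
    n_qpcr = as.integer(n_qpcr),
    ct_noise_sd = ct_noise_sd,
    novel_end_jitter = novel_end_jitter,
    genome_size = if (is.null(genome_size)) NULL else as.integer(genome_size)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_mirnas < 1L) stop("n_mirnas must be >= 1")
  if (cfg$n_novel_hairpins < 0L) stop("n_novel_hairpins must be >= 0")
  if (length(cfg$library_depths) != 2L || any(cfg$library_depths < 0L))
    stop("library_depths must be two non-negative integers")
  if (!nzchar(cfg$adapter3) || !nzchar(cfg$adapter5))
    stop("adapters must be non-empty")
  fr <- cfg$contamination_fractions
  if (any(fr < 0) || any(fr > 1)) stop("contamination fractions must be in [0,1]")
  if (sum(fr) >= 1) stop("contamination fractions must sum to < 1 (remainder is miRNA signal)")
  bad <- setdiff(names(fr), .sim_categories)
  if (length(bad)) stop("unknown contamination categories: ", paste(bad, collapse = ", "))
  lp <- cfg$length_profile
  if (!all(names(lp) %in% as.character(18:30)))
    stop("length_profile must cover lengths 18..30 only")
  if (abs(sum(lp) - 1) > 1e-8) stop("length_profile must sum to 1")
  if (cfg$seed >= 2^31 - 10 || cfg$seed < 0) stop("seed out of range")
  invisible(cfg)
}

.sim_categories <- c(
  "low_quality", "adapter3_null", "insert_null", "adapter5", "short", "polyA",
  "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA",
  "repeat", "exon", "intron", "unann", "novel"
)

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_mirnas, "miRNAs +",
      x$n_novel_hairpins, "novel loci | depths",
      paste(x$library_depths, collapse = "/"), "\n")
  cat("  miRNA signal fraction:",
      format(1 - sum(x$contamination_fractions), digits = 4), "\n")
  invisible(x)
}

# Deterministic child seeds; kept < 2^31.
sim_child_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 97L + offset) %% (2^31 - 1))
}

# Random DNA of given lengths (vectorized).
random_dna <- function(lengths, alphabet = c("A", "C", "G", "T")) {
  vapply(lengths, function(n)
    paste(sample(alphabet, n, replace = TRUE), collapse = ""), character(1))
}
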