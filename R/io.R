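#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write genomic features as 6-column BED
#'
#' 0-based half-open on disk; the name column is `type|id`.
#' @param features `GRanges` with `type` and `id` metadata columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  gr <- features
  gr$name <- paste(features$type, features$id, sep = "|")
  gr$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a features BED written by [write_features_bed()]
#' @param path input file.
#' @return `GRanges` with `type` and `id` restored.
#' @export
read_features_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  gr$type <- vapply(parts, `[`, character(1), 1)
  gr$id <- vapply(parts, `[`, character(1), 2)
  gr$name <- NULL
  gr
}

#' Write the reference bundle to a directory
#'
#' Emits genome/mature/precursor/ncRNA/UTR FASTA files, the feature BED,
#' tab-separated term maps and the planted-novel-locus table.
#' @param refs a [build_reference_set()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(refs$genome, file.path(dir, "genome.fa"))
  write_fasta(refs$mature, file.path(dir, "mature.fa"))
  write_fasta(refs$precursor, file.path(dir, "precursor.fa"))
  nc <- unlist(unname(refs$ncrna))
  write_fasta(nc, file.path(dir, "ncrna.fa"))
  write_fasta(refs$utr, file.path(dir, "utr.fa"))
  write_features_bed(refs$features, file.path(dir, "features.bed"))
  write_tsv(refs$go_map, file.path(dir, "go_map.tsv"))
  write_tsv(refs$kegg_map, file.path(dir, "kegg_map.tsv"))
  write_tsv(refs$novel_loci, file.path(dir, "novel_loci_truth.tsv"))
  invisible(dir)
}

#' Tab-separated writer/reader used for all tabular outputs
#' @param x data.frame / data.table.
#' @param path file path.
#' @return `path` (writer) or a data.table (reader), invisibly for writer.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) data.table::fread(path, sep = "\t")
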