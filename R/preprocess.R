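#' Clean raw small RNA reads with per-category accounting
#'
#' Applies the fixed filter cascade of the emulated protocol, counting each
#' read in exactly the first category it fails:
#' low quality -> 3' adapter absent -> empty insert (adapter dimer) ->
#' 5' adapter contaminant -> shorter than 18 nt -> polyA. Survivors are
#' adapter-trimmed inserts ("clean reads"). The per-category counts obey the
#' accounting identity `high_quality = clean + sum(removed categories)` by
#' construction.
#'
#' @param fastq_path path to a Phred+33 FASTQ file.
#' @param adapter3,adapter5 adapter sequences (non-empty).
#' @param quality_threshold mean-Phred threshold below which (or when any
#'   non-ACGT base occurs) a read is low quality.
#' @param min_overlap minimum 3'-adapter suffix-overlap length.
#' @param mism_per_10 allowed mismatches per 10 nt of adapter overlap.
#' @param polyA_frac insert A-fraction at or above which it is polyA.
#' @param min_len minimum insert length (18 nt).
#' @param keep_adapterless_max_len reads no longer than this that lack an
#'   adapter are kept whole rather than counted `adapter3_null`; this makes
#'   cleaning idempotent on already-trimmed inserts while full-cycle raw
#'   reads (36 nt) without an adapter are still flagged.
#' @return list with `tags` (data.table `tag`, `count`: collapsed clean
#'   inserts) and `report` (a single-library [filter_report()]).
#' @export
clean_reads <- function(fastq_path, adapter3, adapter5,
                        quality_threshold = 20,
                        min_overlap = 6L, mism_per_10 = 1L,
                        polyA_frac = 0.8, min_len = 18L,
                        keep_adapterless_max_len = 30L) {
  stopifnot(nzchar(adapter3), nzchar(adapter5))
  fq <- read_fastq_checked(fastq_path)
  n <- length(fq$seq)
  if (n == 0L) {
    return(list(
      tags = data.table::data.table(tag = character(), count = integer()),
      report = filter_report(high_quality = 0L, adapter3_null = 0L,
                             insert_null = 0L, adapter5_contaminant = 0L,
                             shorter_than_18nt = 0L, polyA = 0L,
                             total_reads = 0L)))
  }

  ok_q <- fq$mean_q >= quality_threshold & !fq$has_n
  hq <- fq$seq[ok_q]
  n_hq <- length(hq)

  # all later filters are sequence-determined: work on unique sequences
  u <- data.table::data.table(seq_ = hq)[, .(count = .N), by = seq_]
  ins_len <- find_adapter3(u$seq_, adapter3, min_overlap, mism_per_10)
  keepable <- is.na(ins_len) & nchar(u$seq_) <= keep_adapterless_max_len
  ins_len[keepable] <- nchar(u$seq_)[keepable]
  insert <- substr(u$seq_, 1L, ifelse(is.na(ins_len), 0L, ins_len))

  cat_u <- rep("clean", nrow(u))
  cat_u[is_polyA(insert, polyA_frac)] <- "polyA"
  cat_u[nchar(insert) < min_len] <- "shorter_than_18nt"
  cat_u[is_adapter5_contaminant(insert, adapter5)] <- "adapter5_contaminant"
  cat_u[!is.na(ins_len) & ins_len == 0L] <- "insert_null"
  cat_u[is.na(ins_len)] <- "adapter3_null"

  cnt <- function(what) sum(u$count[cat_u == what])
  report <- filter_report(
    high_quality = n_hq,
    adapter3_null = cnt("adapter3_null"),
    insert_null = cnt("insert_null"),
    adapter5_contaminant = cnt("adapter5_contaminant"),
    shorter_than_18nt = cnt("shorter_than_18nt"),
    polyA = cnt("polyA"),
    total_reads = n)

  keep <- cat_u == "clean"
  tags <- data.table::data.table(tag = insert[keep], count = u$count[keep])
  tags <- tags[, .(count = sum(count)), by = tag]
  data.table::setorder(tags, -count, tag)
  list(tags = tags, report = report)
}

#' Per-category read-removal accounting
#'
#' Builds the single-library filter accounting from category counts. Clean
#' reads are derived through the accounting identity
#' `clean = high_quality - sum(removal categories)`, and percentages are
#' reported relative to `high_quality`, rounded to 2 decimals — so feeding
#' the emulated study's printed removal counts reproduces its printed
#' clean-read totals and percentages exactly.
#'
#' @param high_quality,adapter3_null,insert_null,adapter5_contaminant,shorter_than_18nt,polyA
#'   category counts.
#' @param total_reads raw read count before the quality filter (`NA` if
#'   unknown).
#' @return object of class `filter_report`: data.frame with columns `type`,
#'   `count`, `percent`.
#' @export
#' @examples
#' r <- filter_report(5965487, 973, 354, 9183, 6119, 21, total_reads = 6000000)
#' r$count[r$type == "clean_reads"]  # 5948837
filter_report <- function(high_quality, adapter3_null, insert_null,
                          adapter5_contaminant, shorter_than_18nt, polyA,
                          total_reads = NA_integer_) {
  counts <- c(adapter3_null, insert_null, adapter5_contaminant,
              shorter_than_18nt, polyA)
  if (any(counts < 0) || high_quality < 0) stop("counts must be >= 0")
  clean <- high_quality - sum(counts)
  if (clean < 0) stop("removal categories exceed high-quality reads")
  out <- data.frame(
    type = c("total_reads", "high_quality", "adapter3_null", "insert_null",
             "adapter5_contaminants", "shorter_than_18nt", "polyA",
             "clean_reads"),
    count = c(total_reads, high_quality, counts, clean),
    stringsAsFactors = FALSE)
  denom <- if (high_quality > 0) high_quality else NA_real_
  out$percent <- round(100 * out$count / denom, 2)
  out$percent[out$type == "total_reads"] <- NA_real_
  class(out) <- c("filter_report", "data.frame")
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  print.data.frame(x)
  invisible(x)
}

#' Combine per-library filter reports into one wide table
#'
#' @param reports named list of [filter_report()] objects (one per library).
#' @return data.frame with per-library count/percent columns plus a total
#'   count column.
#' @export
filter_report_table <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  out <- data.frame(type = reports[[1]]$type, stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    out[[paste0(nm, "_count")]] <- reports[[nm]]$count
    out[[paste0(nm, "_percent")]] <- reports[[nm]]$percent
  }
  out$total_count <- Reduce(`+`, lapply(reports, `[[`, "count"))
  out
}

#' Read-length distribution of cleaned tags
#'
#' @param tags data.table with `tag` and `count` (read multiplicities).
#' @return data.table `length_nt`, `count`, `fraction` (fractions sum to 1
#'   over observed lengths); empty input gives an empty table.
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0L)
    return(data.table::data.table(length_nt = integer(), count = integer(),
                                  fraction = numeric()))
  d <- tags[, .(count = sum(count)), by = .(length_nt = nchar(tag))]
  data.table::setorder(d, length_nt)
  d[, fraction := count / sum(count)]
  d[]
}

#' Collapse two clean tag streams into a unique-tag table
#'
#' One row per distinct sequence with per-library counts; tags outside the
#' library-construction size range (18-30 nt) are excluded. Rows are ordered
#' by total count descending, then lexicographically.
#'
#' @param tags1,tags2 data.tables with `tag`, `count` from [clean_reads()].
#' @param min_len,max_len retained tag length range.
#' @return data.table `tag`, `count_lib1`, `count_lib2`, `category`
#'   (initially `NA`), class `unique_tag_table`.
#' @export
collapse_tags <- function(tags1, tags2, min_len = 18L, max_len = 30L) {
  t1 <- data.table::data.table(tag = tags1$tag, count_lib1 = tags1$count)
  t2 <- data.table::data.table(tag = tags2$tag, count_lib2 = tags2$count)
  out <- merge(t1, t2, by = "tag", all = TRUE)
  for (col in c("count_lib1", "count_lib2"))
    out[is.na(get(col)), (col) := 0L]
  out <- out[nchar(tag) >= min_len & nchar(tag) <= max_len]
  out[, category := NA_character_]
  data.table::setorder(out, -count_lib1, -count_lib2, tag)
  ord <- order(-(out$count_lib1 + out$count_lib2), out$tag)
  out <- out[ord]
  class(out) <- c("unique_tag_table", class(out))
  out[]
}

# ---- internals ---------------------------------------------------------

# FASTQ reader returning sequences, mean Phred and N flags; a malformed file
# produces an error naming the offending record index.
read_fastq_checked <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L)
    return(list(seq = character(), mean_q = numeric(), has_n = logical()))
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- S4Vectors::mcols(x)$qualities
    list(x = x, qi = as(Biostrings::PhredQuality(quals), "IntegerList"))
  }, error = function(e) {
    nl <- length(readLines(path, warn = FALSE, skipNul = TRUE))
    stop("truncated or malformed FASTQ record at index ",
         nl %/% 4L + (nl %% 4L > 0L), " in ", path, call. = FALSE)
  })
  x <- parsed$x
  qi <- parsed$qi
  af <- Biostrings::alphabetFrequency(x)
  acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  list(seq = as.character(x),
       mean_q = vapply(qi, mean, numeric(1)),
       has_n = acgt < Biostrings::width(x))
}

# best (leftmost valid) suffix-overlap of the 3' adapter; returns insert
# length, or NA when no overlap of >= min_overlap with the allowed mismatch
# budget exists.
find_adapter3 <- function(seqs, adapter, min_overlap = 6L, mism_per_10 = 1L) {
  out <- rep(NA_integer_, length(seqs))
  if (!length(seqs)) return(out)
  achars <- strsplit(adapter, "")[[1]]
  alen <- length(achars)
  for (L in sort(unique(nchar(seqs)))) {
    idx <- which(nchar(seqs) == L)
    mat <- matrix(unlist(strsplit(seqs[idx], ""), use.names = FALSE),
                  ncol = L, byrow = TRUE)
    res <- rep(NA_integer_, length(idx))
    for (s in seq_len(L)) {
      o <- min(L - s + 1L, alen)
      if (o < min_overlap) break
      allowed <- (o %/% 10L) * mism_per_10
      cols <- s:(s + o - 1L)
      mm <- rowSums(mat[, cols, drop = FALSE] !=
                      matrix(achars[seq_len(o)], nrow = length(idx),
                             ncol = o, byrow = TRUE))
      hit <- is.na(res) & mm <= allowed
      res[hit] <- s - 1L
      if (!anyNA(res)) break
    }
    out[idx] <- res
  }
  out
}

is_polyA <- function(insert, frac = 0.8) {
  len <- nchar(insert)
  nA <- len - nchar(gsub("A", "", insert, fixed = TRUE))
  len > 0L & nA >= frac * len
}

# insert begins with >= 8 nt prefix of the 5' adapter, <= 1 mismatch
is_adapter5_contaminant <- function(insert, adapter5, probe = 8L,
                                    max_mismatch = 1L) {
  ok <- nchar(insert) >= probe
  out <- logical(length(insert))
  if (!any(ok)) return(out)
  pre <- substr(insert[ok], 1L, probe)
  ap <- strsplit(substr(adapter5, 1L, probe), "")[[1]]
  mm <- rowSums(matrix(unlist(strsplit(pre, ""), use.names = FALSE),
                       ncol = probe, byrow = TRUE) !=
                  matrix(ap, nrow = length(pre), ncol = probe, byrow = TRUE))
  out[ok] <- mm <= max_mismatch
  out
}
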