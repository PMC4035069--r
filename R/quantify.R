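#' Credit miRNA-category tags to known miRNAs
#'
#' Each tag annotated as `known_miRNA` is credited to exactly one mature
#' miRNA: an exact match when one exists, otherwise the nearest mature
#' within the tolerance (at most `max_mismatch` mismatches over the aligned
#' overlap and at most `max_offset` nt of 5'/3' end offset), ties broken by
#' fewest mismatches, then smallest total offset, then lexicographic id.
#' Tags with no mature within tolerance are reassigned to `unann` with a
#' warning.
#'
#' @param tag_table an annotated [collapse_tags()] table (only rows with
#'   `category == "known_miRNA"` are used).
#' @param refs a [build_reference_set()] bundle.
#' @param max_mismatch,max_offset crediting tolerance.
#' @return list with `records` (data.table `mirna_id`, `mature_seq`,
#'   `count_lib1`, `count_lib2`, covering every reference miRNA) and
#'   `unassigned` (tag rows reassigned to `unann`).
#' @export
assign_tags_to_mirnas <- function(tag_table, refs, max_mismatch = 2L,
                                  max_offset = 2L) {
  mir <- tag_table[category == "known_miRNA"]
  mm <- match_tags_to_mirnas(mir$tag, refs, max_mismatch = max_mismatch,
                             max_offset = max_offset,
                             allow_precursor_substring = FALSE)
  assigned <- !is.na(mm$mirna_id)
  if (any(!assigned))
    warning(sum(!assigned),
            " known_miRNA tag(s) had no mature within tolerance; ",
            "reassigned to unann")
  cred <- data.table::data.table(
    mirna_id = mm$mirna_id[assigned],
    count_lib1 = mir$count_lib1[assigned],
    count_lib2 = mir$count_lib2[assigned])
  cred <- cred[, .(count_lib1 = sum(count_lib1),
                   count_lib2 = sum(count_lib2)), by = mirna_id]
  records <- data.table::data.table(
    mirna_id = names(refs$mature), mature_seq = unname(refs$mature),
    count_lib1 = 0L, count_lib2 = 0L)
  records[cred, `:=`(count_lib1 = i.count_lib1, count_lib2 = i.count_lib2),
          on = "mirna_id"]
  list(records = records, unassigned = mir[!assigned])
}

#' Partition detected miRNAs into co-expressed and library-specific sets
#'
#' @param records the `records` table from [assign_tags_to_mirnas()].
#' @return list of id vectors `co` (nonzero in both), `spec1` / `spec2`
#'   (nonzero in exactly one library); the three sets partition the
#'   detected miRNAs.
#' @export
call_expression_sets <- function(records) {
  list(co = records[count_lib1 > 0 & count_lib2 > 0, mirna_id],
       spec1 = records[count_lib1 > 0 & count_lib2 == 0, mirna_id],
       spec2 = records[count_lib1 == 0 & count_lib2 > 0, mirna_id])
}

#' Report highly expressed library-specific miRNAs
#'
#' Reproduces the emulated study's "specific miRNAs with counts above the
#' threshold" table: for each library, the library-specific miRNAs whose raw
#' count exceeds `threshold`, with normalized expression (tags per million
#' of that library's clean reads) rendered to the nearest integer
#' (half away from zero), sorted by expression descending.
#'
#' @param records the `records` table from [assign_tags_to_mirnas()].
#' @param clean_totals clean-read totals, length 2.
#' @param threshold raw-count threshold (default 1000).
#' @return data.table `library_`, `mirna_id`, `count`, `std` (full
#'   precision), `std_rounded`.
#' @export
top_specific_report <- function(records, clean_totals, threshold = 1000) {
  sets <- call_expression_sets(records)
  rows <- list()
  for (l in 1:2) {
    ids <- sets[[paste0("spec", l)]]
    col <- paste0("count_lib", l)
    r <- records[mirna_id %in% ids & get(col) > threshold]
    if (nrow(r) == 0L) next
    std <- normalize_tpm(r[[col]], clean_totals[l])
    rows[[l]] <- data.table::data.table(
      library_ = l, mirna_id = r$mirna_id, count = r[[col]],
      std = std, std_rounded = round_half_away(std))[order(-std)]
  }
  if (!length(rows))
    return(data.table::data.table(library_ = integer(),
                                  mirna_id = character(), count = integer(),
                                  std = numeric(), std_rounded = numeric()))
  data.table::rbindlist(rows)
}

# ---- tag/mature matcher -----------------------------------------------

# Best mature miRNA for each tag within (max_mismatch, max_offset), or NA.
# Exact mature matches and (optionally) exact precursor substrings are
# accepted first; remaining tags are matched by an 8-mer seed index into the
# mature sequences, scoring every 5' shift in -max_offset..max_offset.
match_tags_to_mirnas <- function(tags, refs, max_mismatch = 2L,
                                 max_offset = 2L,
                                 allow_precursor_substring = TRUE) {
  n <- length(tags)
  res <- data.table::data.table(tag = tags, mirna_id = NA_character_,
                                n_mism = NA_integer_, offset = NA_integer_)
  if (!n) return(res)
  mats <- refs$mature

  exact <- match(tags, mats)
  hit <- !is.na(exact)
  res[hit, `:=`(mirna_id = names(mats)[exact[hit]], n_mism = 0L,
                offset = 0L)]

  if (allow_precursor_substring) {
    todo <- which(is.na(res$mirna_id))
    if (length(todo)) {
      inpre <- substring_of_any(tags[todo], refs$precursor)
      # precursor ids mirror mature ids (mir vs miR); find which precursor
      prec_of <- function(tg) {
        j <- which(vapply(refs$precursor, function(p)
          grepl(tg, p, fixed = TRUE), logical(1)))[1]
        refs$mature_meta$mirna_id[match(names(refs$precursor)[j],
                                        refs$mature_meta$precursor_id)]
      }
      for (i in todo[inpre]) {
        res[i, `:=`(mirna_id = prec_of(tags[i]), n_mism = 0L, offset = 0L)]
      }
    }
  }

  todo <- which(is.na(res$mirna_id))
  if (length(todo)) {
    idx <- mature_kmer_index(mats, k = 8L)
    for (i in todo) {
      cand <- candidate_matures(tags[i], idx, k = 8L)
      if (!length(cand)) next
      best <- best_mature_alignment(tags[i], mats[cand], max_mismatch,
                                    max_offset)
      if (!is.null(best))
        res[i, `:=`(mirna_id = best$id, n_mism = best$mism,
                    offset = best$offset)]
    }
  }
  res
}

mature_kmer_index <- function(mats, k = 8L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(mats)) {
    s <- mats[[j]]
    for (p in seq_len(nchar(s) - k + 1L)) {
      key <- substr(s, p, p + k - 1L)
      env[[key]] <- c(env[[key]], j)
    }
  }
  env
}

candidate_matures <- function(tag, idx, k = 8L) {
  np <- nchar(tag) - k + 1L
  if (np < 1L) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(np)) {
    key <- substr(tag, p, p + k - 1L)
    v <- idx[[key]]
    if (!is.null(v)) hits <- c(hits, v)
  }
  unique(hits)
}

# score tag against each candidate mature over 5' shifts; returns the best
# within tolerance or NULL. offset reported is |5' shift| + |3' overhang|.
best_mature_alignment <- function(tag, mats, max_mismatch, max_offset) {
  best <- NULL
  tl <- nchar(tag)
  for (j in order(names(mats))) {
    m <- mats[[j]]
    ml <- nchar(m)
    for (sh in -max_offset:max_offset) {
      # sh: tag start relative to mature start
      off3 <- (sh + tl) - ml
      if (abs(off3) > max_offset) next
      a <- substr(tag, max(1L, 1L - sh), tl - max(0L, off3))
      b <- substr(m, max(1L, 1L + sh), ml + min(0L, off3))
      if (nchar(a) != nchar(b) || nchar(a) < 10L) next
      mism <- hamming(a, b)
      if (mism > max_mismatch) next
      score <- c(mism, abs(sh) + abs(off3))
      if (is.null(best) || score[1] < best$mism ||
          (score[1] == best$mism && score[2] < best$offset)) {
        best <- list(id = names(mats)[j], mism = mism, offset = score[2])
      }
    }
  }
  best
}

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Round half away from zero
#'
#' Integer rendering used for displayed normalized expression values (R's
#' `round()` rounds half to even, which does not reproduce the emulated
#' study's printed values in general).
#' @param x numeric.
#' @return numeric of rounded values.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
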