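#' Map unique tags to the genome
#'
#' Reports all exact (or up to `max_mismatch`) hits of each tag on both
#' strands of the genome, in 0-based half-open coordinates.
#'
#' @param tags character vector of tag sequences.
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatch allowed mismatches (0 by default; exact matching is
#'   done with a per-width `PDict`, mismatch matching per tag).
#' @return data.table `tag`, `chrom`, `start` (0-based), `strand`. Tags with
#'   non-ACGT characters get zero hits with a warning.
#' @export
map_to_genome <- function(tags, genome, max_mismatch = 0L) {
  tags <- unique(tags)
  bad <- grepl("[^ACGT]", tags)
  if (any(bad))
    warning(sum(bad), " tag(s) with non-ACGT characters: zero hits")
  ok <- tags[!bad]
  subj <- Biostrings::DNAStringSet(genome)
  hit_list <- list()
  if (max_mismatch == 0L) {
    # one constant-width PDict of tag prefixes per strand, full-length
    # matches verified against the genome string (cheap; spurious
    # prefix-only hits are rare)
    add_hits <- function(tag_seqs, query_seqs, strand) {
      w <- min(nchar(query_seqs))
      pd <- Biostrings::PDict(substr(query_seqs, 1L, w))
      for (ch in names(genome)) {
        m <- Biostrings::matchPDict(pd, subj[[ch]])
        si <- Biostrings::startIndex(m)
        cnt <- lengths(si)
        if (!sum(cnt)) next
        st <- unlist(si, use.names = FALSE)
        qs <- rep(query_seqs, cnt)
        ts <- rep(tag_seqs, cnt)
        full <- substring(genome[[ch]], st, st + nchar(qs) - 1L)
        hit <- full == qs
        if (!any(hit)) next
        hit_list[[length(hit_list) + 1L]] <<- data.table::data.table(
          tag = ts[hit], chrom = ch, start = st[hit] - 1L, strand = strand)
      }
    }
  } else {
    add_hits <- function(tag_seqs, query_seqs, strand) {
      for (i in seq_along(query_seqs)) {
        m <- Biostrings::vmatchPattern(query_seqs[i], subj,
                                       max.mismatch = max_mismatch)
        cnt <- lengths(m)
        if (!sum(cnt)) next
        st <- unlist(IRanges::start(m), use.names = FALSE)
        hit_list[[length(hit_list) + 1L]] <<- data.table::data.table(
          tag = tag_seqs[i], chrom = rep(names(genome), cnt),
          start = st - 1L, strand = strand)
      }
    }
  }
  if (length(ok)) {
    add_hits(ok, ok, "+")
    add_hits(ok, revcomp_chr_vec(ok), "-")
  }
  if (!length(hit_list))
    return(data.table::data.table(tag = character(), chrom = character(),
                                  start = integer(), strand = character()))
  out <- data.table::rbindlist(hit_list)
  data.table::setorder(out, tag, chrom, start, strand)
  unique(out)
}

#' Annotate unique tags by the priority rule
#'
#' Assigns every tag exactly one category following the precedence
#' `rRNA-class ncRNAs > known miRNA > repeat > exon > intron > unannotated`.
#' ncRNA membership is exact substring containment in the class reference
#' set (subtype precedence `rRNA > tRNA > snRNA > snoRNA > scRNA > srpRNA`,
#' configurable). Known-miRNA membership is an exact mature match, exact
#' precursor substring, or a near-match within the quantification tolerance.
#' Repeat/exon/intron follow from genomic hits overlapping features, the
#' best-priority annotation over all loci; exon and intron are split into
#' sense/antisense by the relative strand of hit and feature (sense wins
#' when both exist). Tags matching nothing are `unann`.
#'
#' @param tag_table a [collapse_tags()] table.
#' @param refs a [build_reference_set()] bundle (only `mature`, `precursor`,
#'   `ncrna`, `features` are used).
#' @param hits optional precomputed [map_to_genome()] table; computed when
#'   missing.
#' @param max_mismatch genome-mapping mismatches (when `hits` is missing).
#' @param mirna_max_mismatch,mirna_max_offset near-match tolerance against
#'   mature miRNAs.
#' @param ncrna_priority subtype precedence within the ncRNA block.
#' @return the tag table with `category` filled and an `n_hits` column,
#'   plus attribute `"hits"` carrying the genome hit table.
#' @export
annotate_tags <- function(tag_table, refs, hits = NULL, max_mismatch = 0L,
                          mirna_max_mismatch = 2L, mirna_max_offset = 2L,
                          ncrna_priority = c("rRNA", "tRNA", "snRNA",
                                             "snoRNA", "scRNA", "srpRNA")) {
  out <- data.table::copy(tag_table)
  if (nrow(out) == 0L) {
    out[, n_hits := integer()]
    data.table::setattr(out, "hits", NULL)
    return(out)
  }
  if (is.null(hits)) hits <- map_to_genome(out$tag, refs$genome, max_mismatch)
  nh <- hits[, .N, by = tag]
  out[, n_hits := 0L]
  out[nh, n_hits := i.N, on = "tag"]

  cat_v <- rep(NA_character_, nrow(out))

  for (cls in ncrna_priority) {
    pool <- refs$ncrna[[cls]]
    if (is.null(pool)) next
    todo <- which(is.na(cat_v))
    if (!length(todo)) break
    hit <- substring_of_any(out$tag[todo], pool)
    cat_v[todo[hit]] <- cls
  }

  todo <- which(is.na(cat_v))
  if (length(todo)) {
    mm <- match_tags_to_mirnas(out$tag[todo], refs,
                               max_mismatch = mirna_max_mismatch,
                               max_offset = mirna_max_offset,
                               allow_precursor_substring = TRUE)
    cat_v[todo[!is.na(mm$mirna_id)]] <- "known_miRNA"
  }

  todo <- which(is.na(cat_v))
  if (length(todo) && nrow(hits)) {
    fc <- feature_category(out$tag[todo], hits, refs$features)
    cat_v[todo] <- fc
  }
  cat_v[is.na(cat_v)] <- "unann"
  out[, category := cat_v]
  data.table::setattr(out, "hits", hits)
  out[]
}

#' Composition of small RNA classes
#'
#' @param annotated an [annotate_tags()] table.
#' @return data.table with per-category unique-tag counts, read counts, and
#'   fractions of unique tags and of total reads, per library. Fractions
#'   sum to 1 within each metric; read counts sum to the clean-read totals.
#' @export
summarize_composition <- function(annotated) {
  lv <- annotation_categories()
  d <- annotated[, .(
    unique_lib1 = sum(count_lib1 > 0), unique_lib2 = sum(count_lib2 > 0),
    reads_lib1 = sum(count_lib1), reads_lib2 = sum(count_lib2)
  ), by = category]
  full <- data.table::data.table(category = lv)
  d <- merge(full, d, by = "category", all.x = TRUE, sort = FALSE)
  for (col in setdiff(names(d), "category")) d[is.na(get(col)), (col) := 0L]
  for (col in c("unique_lib1", "unique_lib2", "reads_lib1", "reads_lib2")) {
    tot <- sum(d[[col]])
    d[[paste0("frac_", sub("s_", "_", col))]] <-
      if (tot > 0) d[[col]] / tot else 0
  }
  d[]
}

#' All annotation categories, in reporting order
#' @return character vector of category names.
#' @export
annotation_categories <- function() {
  c("rRNA", "scRNA", "snRNA", "snoRNA", "srpRNA", "tRNA", "known_miRNA",
    "repeat", "exon_sense", "exon_antisense", "intron_sense",
    "intron_antisense", "unann")
}

#' Genome-mapping summary
#'
#' Read-weighted fraction of clean reads whose tag maps to the genome.
#'
#' @param annotated an [annotate_tags()] table carrying `n_hits`.
#' @return data.table with per-library mapped read counts and fractions.
#' @export
genome_mapping_summary <- function(annotated) {
  mapped <- annotated$n_hits > 0
  data.table::data.table(
    library_ = 1:2,
    mapped_reads = c(sum(annotated$count_lib1[mapped]),
                     sum(annotated$count_lib2[mapped])),
    clean_reads = c(sum(annotated$count_lib1), sum(annotated$count_lib2))
  )[, fraction := ifelse(clean_reads > 0, mapped_reads / clean_reads, 0)][]
}

# ---- internals ---------------------------------------------------------

# is each tag an exact substring of any sequence in pool? The pool is
# collapsed into one subject ("\n"-separated so matches cannot straddle
# records); per-tag fixed grepl beats PDict construction at these sizes.
substring_of_any <- function(tags, pool) {
  if (!length(tags)) return(logical(0))
  subject <- paste(unname(pool), collapse = "\n")
  vapply(tags, function(tg) grepl(tg, subject, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

# repeat > exon > intron, sense preferred over antisense within a type
feature_category <- function(tags, hits, features) {
  h <- hits[tag %in% tags]
  out <- rep(NA_character_, length(tags))
  if (!nrow(h)) return(out)
  gr <- GenomicRanges::GRanges(h$chrom,
                               IRanges::IRanges(h$start + 1L,
                                                h$start + nchar(h$tag)),
                               strand = "*")
  ov <- GenomicRanges::findOverlaps(gr, features, ignore.strand = TRUE)
  if (!length(ov)) return(out)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ftype <- features$type[sh]
  fstrand <- as.character(GenomicRanges::strand(features))[sh]
  sense <- fstrand == h$strand[qh] | fstrand == "*"
  prio <- c(`repeat` = 1, exon_sense = 2, exon_antisense = 3,
            intron_sense = 4, intron_antisense = 5)
  keep <- ftype %in% c("repeat", "exon", "intron")
  if (!any(keep)) return(out)
  dt <- data.table::data.table(tag = h$tag[qh][keep],
                               lab = ifelse(ftype[keep] == "repeat", "repeat",
                                            paste0(ftype[keep],
                                                   ifelse(sense[keep],
                                                          "_sense",
                                                          "_antisense"))))
  dt[, p := prio[lab]]
  best <- dt[, .(lab = lab[which.min(p)]), by = tag]
  out[match(best$tag, tags)] <- best$lab
  out
}
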