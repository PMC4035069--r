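#' Fold an RNA/DNA sequence into its minimum-score secondary structure
#'
#' A Nussinov-style dynamic program over non-crossing base pairings with a
#' minimum hairpin loop of `min_loop` unpaired bases. Two scoring models are
#' built in:
#' \describe{
#'   \item{`stack`}{(default) each pair contributes a Watson-Crick/wobble
#'     energy (GC -3, AU -2, GU -1) and each pair stacked directly on
#'     another contributes an extra -1, a nearest-neighbour-flavoured
#'     simplification with Turner-like magnitudes. Scores are kcal/mol-like:
#'     more negative is more stable.}
#'   \item{`pairmax`}{plain base-pair maximization (-1 per pair).}
#' }
#' Ties are broken deterministically: at each traceback step the first rule
#' in the fixed order (3' base unpaired, then bifurcations by ascending
#' pairing partner, then stacked before non-stacked inner structure) that
#' reproduces the optimal score is taken.
#'
#' @param sequence ACGU/ACGT string (T and U are equivalent).
#' @param model scoring model, `"stack"` or `"pairmax"`.
#' @param min_loop minimum unpaired bases enclosed by a pair.
#' @return list with `structure` (dot-bracket), `energy` (optimal score),
#'   `n_pairs`.
#' @export
#' @examples
#' fold_sequence("GGGGAAACCCC")$structure   # "((((...))))"
fold_sequence <- function(sequence, model = c("stack", "pairmax"),
                          min_loop = 3L) {
  model <- match.arg(model)
  s <- chartr("Uu", "Tt", toupper(sequence))
  if (grepl("[^ACGT]", s)) stop("invalid characters in sequence")
  n <- nchar(s)
  b <- strsplit(s, "")[[1]]
  if (n < min_loop + 2L)
    return(list(structure = strrep(".", n), energy = 0, n_pairs = 0L))

  pe <- pair_energy_matrix(b, model)          # n x n pair energies (Inf = no pair)
  stack_bonus <- if (model == "stack") -1 else 0

  V <- matrix(Inf, n, n)   # energy when i pairs j
  W <- matrix(0, n, n)     # optimal energy of region [i, j]
  for (j in seq_len(n)) {
    i <- j - min_loop - 1L
    while (i >= 1L) {
      if (is.finite(pe[i, j])) {
        inner_w <- if (j - i > min_loop + 1L) W[i + 1L, j - 1L] else 0
        v <- pe[i, j] + inner_w
        if (j - i > min_loop + 2L && is.finite(V[i + 1L, j - 1L]))
          v <- min(v, pe[i, j] + V[i + 1L, j - 1L] + stack_bonus)
        V[i, j] <- v
      }
      # W recurrence: j unpaired, or j pairs some k in [i, j-min_loop-1]
      best <- W[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      vkj <- V[ks, j]
      fin <- is.finite(vkj)
      if (any(fin)) {
        wl <- c(0, W[i, ks[-1L] - 1L])[fin]
        best <- min(best, min(wl + vkj[fin]))
      }
      W[i, j] <- best
      i <- i - 1L
    }
  }

  pairs <- integer(n)
  trace_fold(1L, n, "W", V, W, pe, pairs_env <- new.env(), min_loop,
             stack_bonus)
  pairs <- get("pairs", envir = pairs_env, inherits = FALSE)
  db <- rep(".", n)
  db[pairs > seq_len(n) & pairs > 0] <- "("
  db[pairs < seq_len(n) & pairs > 0] <- ")"
  list(structure = paste(db, collapse = ""), energy = W[1L, n],
       n_pairs = sum(pairs > 0) %/% 2L)
}

pair_energy_matrix <- function(b, model) {
  n <- length(b)
  e <- c("GC" = -3, "CG" = -3, "AT" = -2, "TA" = -2, "GT" = -1, "TG" = -1)
  if (model == "pairmax") e[] <- -1
  key <- outer(b, b, paste0)
  m <- matrix(Inf, n, n)
  hit <- key %in% names(e)
  m[hit] <- e[key[hit]]
  m
}

# iterative traceback writing 1-based partner indices into env$pairs;
# tie-break order: 3' base unpaired first, then bifurcations by ascending k,
# then stacked inner structure before a general inner region
trace_fold <- function(i, j, what, V, W, pe, env, min_loop, stack_bonus) {
  assign("pairs", integer(nrow(V)), envir = env)
  todo <- list(list(i = i, j = j, what = what))
  eps <- 1e-9
  while (length(todo)) {
    fr <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    i <- fr$i; j <- fr$j
    if (j - i < min_loop + 1L) next
    if (fr$what == "W") {
      if (abs(W[i, j] - W[i, j - 1L]) < eps) {
        todo[[length(todo) + 1L]] <- list(i = i, j = j - 1L, what = "W")
        next
      }
      for (k in i:(j - min_loop - 1L)) {
        wl <- if (k > i) W[i, k - 1L] else 0
        if (is.finite(V[k, j]) && abs(wl + V[k, j] - W[i, j]) < eps) {
          if (k > i)
            todo[[length(todo) + 1L]] <- list(i = i, j = k - 1L, what = "W")
          todo[[length(todo) + 1L]] <- list(i = k, j = j, what = "V")
          break
        }
      }
    } else {
      p <- get("pairs", envir = env, inherits = FALSE)
      p[i] <- j; p[j] <- i
      assign("pairs", p, envir = env)
      if (j - i <= min_loop + 1L) next
      stacked_ok <- j - i > min_loop + 2L && is.finite(V[i + 1L, j - 1L]) &&
        abs(pe[i, j] + V[i + 1L, j - 1L] + stack_bonus - V[i, j]) < eps
      if (stacked_ok) {
        todo[[length(todo) + 1L]] <- list(i = i + 1L, j = j - 1L, what = "V")
      } else {
        todo[[length(todo) + 1L]] <- list(i = i + 1L, j = j - 1L, what = "W")
      }
    }
  }
  invisible(NULL)
}

#' Excise candidate precursor windows around unannotated tag loci
#'
#' Tags with more than `max_loci` genomic hits are discarded as repeats;
#' each remaining hit spawns a window of the tag extended by `flank` on
#' both sides (clipped at chromosome bounds), and overlapping windows are
#' merged.
#'
#' @param unann_hits data.table with `tag`, `chrom`, `start` (0-based),
#'   `strand` plus per-library tag counts `count_lib1`, `count_lib2`.
#' @param genome named character vector of chromosomes.
#' @param flank window extension (nt) each side.
#' @param max_loci repeat-filter threshold on per-tag hit count.
#' @return list with `windows` (data.table `window_id`, `chrom`, `start`,
#'   `end`, 0-based half-open) and `support` (tag hits mapped to windows).
#' @export
extract_candidates <- function(unann_hits, genome, flank = 70L,
                               max_loci = 15L) {
  h <- data.table::copy(unann_hits)
  if (nrow(h)) {
    nh <- h[, .N, by = tag]
    h <- h[tag %in% nh[N <= max_loci, tag]]
  }
  if (nrow(h) == 0L)
    return(list(windows = data.table::data.table(
      window_id = integer(), chrom = character(), start = integer(),
      end = integer()),
      support = data.table::data.table()))
  h[, end := start + nchar(tag)]
  gr <- GenomicRanges::GRanges(
    h$chrom,
    IRanges::IRanges(pmax(1L, h$start + 1L - flank),
                     pmin(nchar(genome)[h$chrom], h$end + flank)))
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  h[, window_id := S4Vectors::subjectHits(ov)]
  windows <- data.table::data.table(
    window_id = seq_along(red),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red))
  list(windows = windows, support = h)
}

#' Call novel miRNA hairpin candidates
#'
#' For each window the most abundant supporting tag is taken as the mature
#' arm candidate; precursor hypotheses placing the mature on the 5' or 3'
#' stem arm (in both orientations) are excised and folded, and the best
#' passing hypothesis (lowest energy) is reported. A candidate passes when
#' all criteria hold: fold energy at most `energy_max`; at least
#' `pair_fraction` of mature bases paired with bases outside the mature
#' (stem pairing with the star arm); mature arm not spanning the loop;
#' mature length 20-24 nt; at least `dicer_fraction` of supporting reads
#' sharing the modal 5' end (Dicer-consistent processing); total read
#' support at least `min_reads`; and no overlap with any known annotation.
#'
#' @param cands output of [extract_candidates()].
#' @param genome named character vector of chromosomes.
#' @param features known-annotation [GenomicRanges::GRanges].
#' @param energy_max maximum (most positive) acceptable fold energy.
#' @param pair_fraction minimum paired fraction of mature bases.
#' @param dicer_fraction minimum modal 5'-end read fraction.
#' @param min_reads minimum total supporting reads.
#' @param mature_length_range allowed mature-arm length.
#' @param model folding model passed to [fold_sequence()].
#' @param fold_all fold every window; by default windows already failing the
#'   cheap read-based criteria (support, Dicer consistency, mature length)
#'   are reported unfolded (structure `NA`), which keeps large runs fast.
#' @return data.table of candidates with locus, precursor, dot-bracket
#'   structure, energy, mature arm, support statistics, individual criterion
#'   flags and an overall `pass`.
#' @export
call_novel <- function(cands, genome, features, energy_max = -18,
                       pair_fraction = 0.6, dicer_fraction = 0.7,
                       min_reads = 3L, mature_length_range = c(20L, 24L),
                       model = "stack", fold_all = FALSE) {
  empty <- data.table::data.table(
    window_id = integer(), chrom = character(), start = integer(),
    end = integer(), strand = character(), precursor_seq = character(),
    structure = character(), energy = numeric(), n_pairs = integer(),
    mature_seq = character(), mature_start = integer(),
    count_lib1 = integer(), count_lib2 = integer(), n_reads = integer(),
    dicer_frac = numeric(), pair_frac = numeric(),
    ok_energy = logical(), ok_pairing = logical(), ok_loop = logical(),
    ok_length = logical(), ok_dicer = logical(), ok_reads = logical(),
    ok_unannotated = logical(), pass = logical())
  if (nrow(cands$windows) == 0L) return(empty)
  rows <- list()
  for (wi in cands$windows$window_id) {
    sup <- cands$support[window_id == wi]
    win <- cands$windows[window_id == wi]
    tot <- sup[, .(n = sum(count_lib1 + count_lib2)), by = .(tag, start)]
    best_tag <- tot[order(-n, tag)][1]
    m_start <- best_tag$start
    m_seq <- best_tag$tag
    mlen <- nchar(m_seq)
    # Dicer consistency and read support are judged on mature-arm reads:
    # every supporting read overlapping the candidate mature span (reads
    # elsewhere in a merged window belong to other loci, but a read across
    # the mature with a shifted 5' end argues against precise processing)
    arm <- sup[start < m_start + mlen & start + nchar(tag) > m_start]
    n_reads_tot <- sum(arm$count_lib1 + arm$count_lib2)
    modal <- arm[, .(n = sum(count_lib1 + count_lib2)), by = start][
      order(-n, start)][1]
    dfrac <- modal$n / n_reads_tot

    ok_support <- list(
      ok_length = mlen >= mature_length_range[1] &&
        mlen <= mature_length_range[2],
      ok_dicer = dfrac >= dicer_fraction,
      ok_reads = n_reads_tot >= min_reads)
    if (!fold_all && !all(unlist(ok_support))) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        window_id = wi, chrom = win$chrom, start = win$start,
        end = win$end, strand = NA_character_,
        precursor_seq = NA_character_, structure = NA_character_,
        energy = NA_real_, n_pairs = NA_integer_,
        mature_seq = m_seq, mature_start = m_start,
        count_lib1 = sum(arm$count_lib1), count_lib2 = sum(arm$count_lib2),
        n_reads = n_reads_tot, dicer_frac = dfrac, pair_frac = NA_real_,
        ok_energy = NA, ok_pairing = NA, ok_loop = NA,
        ok_length = ok_support$ok_length, ok_dicer = ok_support$ok_dicer,
        ok_reads = ok_support$ok_reads, ok_unannotated = NA,
        pass = FALSE)
      next
    }

    hyps <- precursor_hypotheses(m_start, mlen, win, nchar(genome[win$chrom]))
    best <- NULL
    for (hi in seq_len(nrow(hyps))) {
      pseq <- substr(genome[win$chrom], hyps$start[hi] + 1L, hyps$end[hi])
      for (orient in c("+", "-")) {
        if (orient == "+") {
          seqo <- pseq
          mpos <- m_start - hyps$start[hi] + 1L
        } else {
          seqo <- revcomp_chr(pseq)
          mpos <- hyps$end[hi] - (m_start + mlen) + 1L
        }
        if (mpos < 1L || mpos + mlen - 1L > nchar(seqo)) next
        f <- fold_sequence(seqo, model = model)
        stats <- mature_pairing_stats(f$structure, mpos, mlen)
        cand <- list(seq = seqo, strand = orient, fold = f,
                     start = hyps$start[hi], end = hyps$end[hi],
                     mpos = mpos, stats = stats)
        score <- f$energy + ifelse(stats$pair_frac >= pair_fraction, -100, 0)
        if (is.null(best) || score < best$score) {
          cand$score <- score
          best <- cand
        }
      }
    }
    if (is.null(best)) next
    gr_cand <- GenomicRanges::GRanges(
      win$chrom, IRanges::IRanges(best$start + 1L, best$end))
    ok <- list(
      ok_energy = best$fold$energy <= energy_max,
      ok_pairing = best$stats$pair_frac >= pair_fraction,
      ok_loop = !best$stats$spans_loop,
      ok_length = ok_support$ok_length,
      ok_dicer = ok_support$ok_dicer,
      ok_reads = ok_support$ok_reads,
      ok_unannotated = length(GenomicRanges::findOverlaps(
        gr_cand, features, ignore.strand = TRUE)) == 0L)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      window_id = wi, chrom = win$chrom, start = best$start,
      end = best$end, strand = best$strand,
      precursor_seq = best$seq, structure = best$fold$structure,
      energy = best$fold$energy, n_pairs = best$fold$n_pairs,
      mature_seq = m_seq, mature_start = m_start,
      count_lib1 = sum(arm$count_lib1), count_lib2 = sum(arm$count_lib2),
      n_reads = n_reads_tot, dicer_frac = dfrac,
      pair_frac = best$stats$pair_frac,
      ok_energy = ok$ok_energy, ok_pairing = ok$ok_pairing,
      ok_loop = ok$ok_loop, ok_length = ok$ok_length,
      ok_dicer = ok$ok_dicer, ok_reads = ok$ok_reads,
      ok_unannotated = ok$ok_unannotated,
      pass = all(unlist(ok)))
  }
  if (!length(rows)) return(empty)
  data.table::rbindlist(rows)
}

# candidate precursor spans (0-based half-open), mature on 5' or 3' arm,
# with a narrower and a wider flank each; clipped to chromosome bounds
precursor_hypotheses <- function(m_start, mlen, win, chrom_len) {
  m_end <- m_start + mlen
  spans <- rbind(
    c(m_start - 12L, m_end + mlen + 22L),
    c(m_start - (mlen + 22L), m_end + 12L),
    c(m_start - 20L, m_end + mlen + 40L),
    c(m_start - (mlen + 40L), m_end + 20L))
  spans[, 1] <- pmax(0L, spans[, 1])
  spans[, 2] <- pmin(chrom_len, spans[, 2])
  data.table::data.table(start = spans[, 1], end = spans[, 2])
}

# fraction of mature bases paired with partners outside the mature span,
# and whether the mature substructure spans the loop (holds both brackets)
mature_pairing_stats <- function(structure, mpos, mlen) {
  ch <- strsplit(structure, "")[[1]]
  partner <- dotbracket_partners(ch)
  span <- mpos:(mpos + mlen - 1L)
  pp <- partner[span]
  paired_out <- sum(pp > 0 & !(pp %in% span))
  sub <- ch[span]
  list(pair_frac = paired_out / mlen,
       spans_loop = any(sub == "(") && any(sub == ")"))
}

dotbracket_partners <- function(ch) {
  n <- length(ch)
  partner <- integer(n)
  st <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Export novel candidates as BED and dot-bracket text
#'
#' @param candidates a [call_novel()] table.
#' @param bed_path,structure_path output files (`NULL` to skip either).
#' @return invisibly, the candidate table.
#' @export
export_novel <- function(candidates, bed_path = NULL,
                         structure_path = NULL) {
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(
      candidates$chrom,
      IRanges::IRanges(candidates$start + 1L, candidates$end),
      strand = candidates$strand)
    gr$name <- sprintf("novel_cand_%d", candidates$window_id)
    gr$score <- 0L
    rtracklayer::export.bed(gr, bed_path)
  }
  if (!is.null(structure_path)) {
    lines <- unlist(lapply(seq_len(nrow(candidates)), function(i) c(
      sprintf(">novel_cand_%d %s:%d-%d(%s) energy=%.1f",
              candidates$window_id[i], candidates$chrom[i],
              candidates$start[i], candidates$end[i],
              candidates$strand[i], candidates$energy[i]),
      candidates$precursor_seq[i], candidates$structure[i])))
    writeLines(lines, structure_path)
  }
  invisible(candidates)
}
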