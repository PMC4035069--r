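# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own computational paths.

# -- secondary-structure enumeration -------------------------------------
# All non-crossing pairings with a minimum hairpin loop, scored directly
# from the pair list; returns the optimal (minimum) energy.

oracle_pair_energy <- function(a, b, model) {
  e <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)
  if (model == "pairmax") e[] <- -1
  v <- e[paste0(a, b)]
  ifelse(is.na(v), NA_real_, v)
}

# enumerate all structures of b[i..j] as lists of pair matrices (2 cols)
oracle_enum_structures <- function(b, i, j, min_loop = 3L, memo = NULL) {
  if (j - i < min_loop + 1L) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  # i unpaired
  for (s in oracle_enum_structures(b, i + 1L, j, min_loop))
    out[[length(out) + 1L]] <- s
  # i paired with k
  for (k in (i + min_loop + 1L):j) {
    if (is.na(oracle_pair_energy(b[i], b[k], "stack"))) next
    left <- oracle_enum_structures(b, i + 1L, k - 1L, min_loop)
    right <- oracle_enum_structures(b, k + 1L, j, min_loop)
    for (sl in left) for (sr in right)
      out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), sl, sr)
  }
  out
}

# minimum energy over all enumerated structures of a sequence
oracle_fold <- function(sequence, model = "stack", min_loop = 3L) {
  b <- strsplit(chartr("Uu", "Tt", toupper(sequence)), "")[[1]]
  structs <- oracle_enum_structures(b, 1L, length(b), min_loop)
  best <- 0
  for (p in structs) {
    if (nrow(p) == 0L) next
    en <- sum(oracle_pair_energy(b[p[, 1]], b[p[, 2]], model))
    if (model == "stack") {
      key <- paste(p[, 1], p[, 2])
      stacked <- paste(p[, 1] + 1L, p[, 2] - 1L) %in% key
      en <- en + -1 * sum(stacked)
    }
    if (en < best) best <- en
  }
  best
}

# -- Audic-Claverie tail summation ---------------------------------------
# each term from its closed form p(k|x) = (N2/N1)^k (x+k)!/(x! k!) /
# (1+N2/N1)^(x+k+1), via lgamma; both tails summed directly term by term
# (the upper tail until geometric decay makes further terms negligible).
# Independent of pnbinom.

oracle_ac_pvalue <- function(x, y, N1, N2) {
  p1 <- N1 / (N1 + N2)
  q <- N2 / (N1 + N2)
  logterm <- function(k) (x + 1) * log(p1) + k * log(q) +
    lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1)
  lower <- sum(exp(logterm(0:y)))
  nb_mean <- (x + 1) * q / p1
  upper <- 0
  k <- y
  repeat {
    t <- exp(logterm(k))
    upper <- upper + t
    k <- k + 1
    if (k > nb_mean + 10 && (t < upper * 1e-18 || k > y + 2e5)) break
  }
  min(1, 2 * min(lower, upper))
}

# -- hypergeometric enumeration ------------------------------------------
# exhaustive subsets of size n from N, counting those with >= m specials

oracle_hypergeom <- function(N, n, M, m) {
  specials <- seq_len(M)
  combs <- utils::combn(N, n)
  hits <- colSums(matrix(combs %in% specials, nrow = n))
  mean(hits >= m)
}

# -- plain FASTQ writer for hand-built fixtures --------------------------

write_test_fastq <- function(seqs, path, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%03d", seq_along(seqs))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))   # Phred 40
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# naive full-scan genome mapping oracle (both strands, fixed matching)
oracle_scan_genome <- function(tag, genome) {
  rc <- function(x) vapply(
    strsplit(chartr("ACGT", "TGCA", x), NULL),
    function(ch) paste(rev(ch), collapse = ""), character(1))
  out <- list()
  for (ch in names(genome)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else rc(tag)
      m <- gregexpr(q, genome[[ch]], fixed = TRUE)[[1]]
      if (m[1] == -1) next
      out[[length(out) + 1L]] <- data.table::data.table(
        tag = tag, chrom = ch, start = as.integer(m) - 1L, strand = strand)
    }
  }
  if (!length(out))
    return(data.table::data.table(tag = character(), chrom = character(),
                                  start = integer(), strand = character()))
  data.table::rbindlist(out)
}
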