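#' Tags-per-million normalization
#'
#' `Normalized expression = count / total clean reads * 10^6`, at full
#' precision.
#'
#' @param count non-negative count(s).
#' @param clean_total positive clean-read total of the library.
#' @return numeric normalized expression.
#' @export
#' @examples
#' normalize_tpm(5214, 5948837)   # 876.47...
normalize_tpm <- function(count, clean_total) {
  if (any(clean_total <= 0)) stop("clean_total must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  1e6 * count / clean_total
}

#' Two-library exact count test (Audic-Claverie)
#'
#' Probability model for the count `y` of a transcript in a library of total
#' depth `N2` given its count `x` in a library of depth `N1`:
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`, which is a
#' negative binomial with size `x+1` and success probability `N1/(N1+N2)`.
#' The two-sided p-value doubles the smaller tail and caps at 1. Tails are
#' computed with [stats::pnbinom()], stable for counts up to 10^6 and
#' beyond.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param N1,N2 positive library totals.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' exact_count_pvalue(50, 5, 1e6, 1e6)
exact_count_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be integers")
  p1 <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = p1)
  upper <- pnbinom(y - 1, size = x + 1, prob = p1, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Log2 fold change and scatter ratio class
#'
#' `log2fc = log2(std_treatment / std_control)`; the ratio class follows the
#' scatter-plot coloring of the emulated study: ratio > 2, 1/2 < ratio <= 2,
#' ratio <= 1/2, with ratio = treatment / control.
#'
#' @param std_control,std_treatment positive normalized expression values
#'   (after the zero-revision to 0.01).
#' @return list with `log2fc` and `ratio_class`.
#' @export
fold_change <- function(std_control, std_treatment) {
  if (any(std_control <= 0) || any(std_treatment <= 0))
    stop("normalized expression must be positive (apply zero revision first)")
  ratio <- std_treatment / std_control
  list(log2fc = log2(ratio),
       ratio_class = ifelse(ratio > 2, ">2",
                            ifelse(ratio > 0.5, "(1/2,2]", "<=1/2")))
}

#' Significance label from fold change and p-value
#'
#' `**` when |log2fc| > 1 and p < 0.01; `*` when |log2fc| > 1 and
#' 0.01 <= p < 0.05; `None` otherwise.
#'
#' @param log2fc,p finite numerics (vectorized).
#' @return character vector of labels.
#' @export
sig_label <- function(log2fc, p) {
  ifelse(abs(log2fc) > 1 & p < 0.01, "**",
         ifelse(abs(log2fc) > 1 & p >= 0.01 & p < 0.05, "*", "None"))
}

#' Build the two-library differential expression table
#'
#' Normalizes counts to tags per million, revises a zero normalized
#' expression to 0.01, drops miRNAs whose normalized expression is below 1
#' in both libraries, and computes log2 fold change
#' (treatment over control), the exact count-difference p-value (on raw
#' counts and library totals), the significance label, the scatter ratio
#' class, and an auxiliary Benjamini-Hochberg column (not used for labels,
#' matching the emulated study, which applies no multiple-testing
#' correction).
#'
#' @param records quantification `records` (`mirna_id`, `count_lib1`,
#'   `count_lib2`); miRNAs with zero counts in both libraries are not
#'   considered detected and are excluded.
#' @param clean_totals clean-read totals, length 2.
#' @param control which library (1 or 2) is the control / X axis.
#' @return data.table of class `de_table`: `mirna_id`, `x`, `y` (control /
#'   treatment raw counts), `std1`, `std2` (revised normalized expression,
#'   control / treatment), `log2fc`, `pvalue`, `padj_bh`, `sig_label`,
#'   `ratio_class`.
#' @export
de_table <- function(records, clean_totals, control = 1L) {
  stopifnot(control %in% c(1L, 2L), length(clean_totals) == 2L)
  treatment <- 3L - control
  r <- records[count_lib1 > 0 | count_lib2 > 0]
  x <- r[[paste0("count_lib", control)]]
  y <- r[[paste0("count_lib", treatment)]]
  N1 <- clean_totals[control]
  N2 <- clean_totals[treatment]
  std_c <- normalize_tpm(x, N1)
  std_t <- normalize_tpm(y, N2)
  std_c_rev <- ifelse(std_c == 0, 0.01, std_c)
  std_t_rev <- ifelse(std_t == 0, 0.01, std_t)
  keep <- !(std_c_rev < 1 & std_t_rev < 1)
  d <- data.table::data.table(
    mirna_id = r$mirna_id[keep], x = x[keep], y = y[keep],
    std1 = std_c_rev[keep], std2 = std_t_rev[keep])
  fc <- fold_change(d$std1, d$std2)
  d[, log2fc := fc$log2fc]
  d[, pvalue := exact_count_pvalue(x, y, N1, N2)]
  d[, padj_bh := p.adjust(pvalue, method = "BH")]
  d[, sig_label := sig_label(log2fc, pvalue)]
  d[, ratio_class := fc$ratio_class]
  class(d) <- c("de_table", class(d))
  d[]
}

#' Hierarchically cluster differentially expressed miRNAs
#'
#' Average-linkage clustering of Euclidean distances between per-miRNA
#' log2 normalized-expression vectors (one entry per library).
#'
#' @param de a [de_table()] (typically filtered to labelled miRNAs).
#' @return object of class `de_cluster`: list with the `hclust` tree, the
#'   log2 expression matrix, and the deterministic leaf order.
#' @export
cluster_de <- function(de) {
  if (nrow(de) < 2L) stop("need at least 2 records to cluster")
  mat <- cbind(lib_control = log2(de$std1), lib_treatment = log2(de$std2))
  rownames(mat) <- de$mirna_id
  hc <- hclust(dist(mat), method = "average")
  structure(list(hclust = hc, matrix = mat, leaves = hc$labels[hc$order]),
            class = "de_cluster")
}

#' @export
print.de_cluster <- function(x, ...) {
  cat("de_cluster:", nrow(x$matrix), "miRNAs, average linkage\n")
  invisible(x)
}

#' Export a DE cluster tree as Newick
#'
#' @param cluster a [cluster_de()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(cluster, path) {
  stopifnot(inherits(cluster, "de_cluster"))
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Scatter-class and significance summaries of a DE table
#'
#' The emulated study reports both a ratio-class breakdown and a
#' significance breakdown; both are emitted because the text is ambiguous
#' about which defines its percentages.
#'
#' @param de a [de_table()].
#' @return list of two data.tables: `by_ratio_class`, `by_significance`.
#' @export
de_summaries <- function(de) {
  list(
    by_ratio_class = de[, .(n = .N, fraction = .N / nrow(de)),
                        by = ratio_class],
    by_significance = de[, .(n = .N, fraction = .N / nrow(de)),
                         by = sig_label])
}
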