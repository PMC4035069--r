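#' Relative qPCR expression by the delta-Ct method
#'
#' Per replicate, `rel_expr = 2^-(ct_mirna - ct_reference)`; the per-group
#' summary reports mean and SD over replicates. Adding a constant number of
#' cycles to both channels leaves the result unchanged.
#'
#' @param ct_table data.table with `mirna_id`, `group`, `replicate`, `ct`,
#'   `ct_ref` (as from [simulate_ct_table()]).
#' @return list with `replicates` (the table plus `rel_expr`) and `summary`
#'   (mean and SD of `rel_expr` per miRNA and group).
#' @export
#' @examples
#' relative_expression(data.frame(mirna_id = "m", group = "Mul",
#'                                replicate = 1, ct = 25, ct_ref = 20))
relative_expression <- function(ct_table) {
  d <- data.table::as.data.table(ct_table)
  stopifnot(all(c("mirna_id", "group", "ct", "ct_ref") %in% names(d)))
  d[, rel_expr := 2^(-(ct - ct_ref))]
  list(replicates = d[],
       summary = d[, .(mean_rel = mean(rel_expr), sd_rel = sd(rel_expr),
                       n = .N), by = .(mirna_id, group)])
}

#' Two-group comparison of qPCR expression
#'
#' Ordinary linear model on log2 relative expression with a two-level group
#' factor (equivalent to a pooled-variance two-sample t-test); realizes the
#' "GLM on two samples" analysis of the emulated study.
#'
#' @param ct_table as in [relative_expression()]; `control` names the
#'   reference group level.
#' @param control control group label.
#' @param alpha significance threshold (0.01, matching the emulated
#'   figure's labelling).
#' @return data.table per miRNA: `log2_ratio` (treatment minus control),
#'   `pvalue`, `significant`.
#' @export
group_compare <- function(ct_table, control = "Mul", alpha = 0.01) {
  d <- relative_expression(ct_table)$replicates
  groups <- unique(d$group)
  if (length(groups) != 2L) stop("need exactly two groups")
  reps <- d[, .N, by = .(mirna_id, group)]
  if (any(reps$N < 2L)) stop("each group needs at least 2 replicates")
  treatment <- setdiff(groups, control)
  d[, group := factor(group, levels = c(control, treatment))]
  res <- d[, {
    yv <- log2(rel_expr)
    fit <- lm(yv ~ group, data = .SD)
    est <- unname(coef(fit)[2])
    sm <- suppressWarnings(summary(fit))
    scale_ <- abs(mean(yv)) + 1
    # an (essentially) perfect fit has no usable error estimate: identical
    # groups are a clear null, a zero-variance difference a clear effect
    if (sm$sigma < 1e-9 * scale_ || !is.finite(sm$coefficients[2, 4])) {
      p <- if (abs(est) < 1e-9 * scale_) 1 else 0
      if (p == 1) est <- 0
    } else {
      p <- sm$coefficients[2, 4]
    }
    list(log2_ratio = est, pvalue = p)
  }, by = mirna_id]
  res[, significant := pvalue < alpha][]
}

#' Direction agreement between qPCR and sequencing
#'
#' Compares the sign of the qPCR log2 group ratio with the sign of the
#' sequencing log2 fold change for shared miRNAs; zero-change miRNAs carry
#' no direction and are excluded from the agreement fraction.
#'
#' @param qpcr a [group_compare()] table.
#' @param de a [de_table()].
#' @return list with `table` (per-miRNA directions and agreement) and
#'   `agreement` (fraction among directional miRNAs).
#' @export
concordance_with_sequencing <- function(qpcr, de) {
  shared <- intersect(qpcr$mirna_id, de$mirna_id)
  if (!length(shared)) stop("no shared miRNA ids between qPCR and DE table")
  q <- qpcr[match(shared, mirna_id)]
  s <- de[match(shared, mirna_id)]
  tab <- data.table::data.table(
    mirna_id = shared,
    qpcr_log2_ratio = q$log2_ratio,
    seq_log2fc = s$log2fc,
    direction = ifelse(sign(q$log2_ratio) == 0 | sign(s$log2fc) == 0,
                       "none",
                       ifelse(sign(q$log2_ratio) == sign(s$log2fc),
                              "agree", "disagree")))
  frac <- {
    dir <- tab$direction[tab$direction != "none"]
    if (length(dir)) mean(dir == "agree") else NA_real_
  }
  list(table = tab, agreement = frac)
}
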