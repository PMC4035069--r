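#' Hypergeometric upper-tail enrichment probability
#'
#' `P = sum_{i=m}^{min(n,M)} C(M,i) C(N-M,n-i) / C(N,n)`: the probability
#' of observing at least `m` annotated genes among `n` targets drawn from a
#' background of `N` genes of which `M` carry the term. Computed in log
#' space (`lchoose` + log-sum-exp), stable for `N` up to 10^5 and beyond.
#'
#' @param N background genes with annotation.
#' @param n target genes within the background.
#' @param M background genes with the term.
#' @param m target genes with the term.
#' @return upper-tail probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # 6/252
hypergeom_upper_tail <- function(N, n, M, m) {
  if (length(N) > 1L)
    return(mapply(hypergeom_upper_tail, N, n, M, m))
  if (any(c(N, n, M, m) < 0) || n > N || M > N || m > min(n, M))
    stop("invalid hypergeometric configuration (need m <= min(n, M) <= N)")
  if (m == 0L) return(1)
  i <- m:min(n, M)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Per-term enrichment counts and raw p-values
#'
#' @param target_genes character vector of target gene ids.
#' @param term_map data.table/data.frame with `gene_id`, `term_id`,
#'   `ontology`.
#' @return data.table with one row per (ontology, term): `N`, `n`, `M`,
#'   `m`, `p_raw`.
#' @export
enrich_terms <- function(target_genes, term_map) {
  tm <- data.table::as.data.table(term_map)
  stopifnot(all(c("gene_id", "term_id", "ontology") %in% names(tm)))
  target_genes <- unique(target_genes)
  out <- list()
  for (ont in unique(tm$ontology)) {
    sub <- tm[ontology == ont]
    bg <- unique(sub$gene_id)
    N <- length(bg)
    tg <- intersect(target_genes, bg)
    n <- length(tg)
    per <- sub[, .(M = data.table::uniqueN(gene_id),
                   m = data.table::uniqueN(intersect(gene_id, tg))),
               by = term_id]
    per[, `:=`(ontology = ont, N = N, n = n)]
    per[, p_raw := hypergeom_upper_tail(N, n, M, m), by = term_id]
    out[[ont]] <- per
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("ontology", "term_id", "N", "n", "M", "m",
                                 "p_raw"))
  res[]
}

#' Bonferroni correction for GO terms
#'
#' `p_adj = min(1, p_raw * k)` with `k` the number of terms tested within
#' the same ontology (per-ontology correction); significant when
#' `p_adj <= 0.05`.
#'
#' @param terms an [enrich_terms()] table.
#' @param alpha significance cutoff.
#' @return the table with `p_adj` and `significant` added.
#' @export
correct_go <- function(terms, alpha = 0.05) {
  out <- data.table::copy(terms)
  out[, p_adj := pmin(1, p_raw * .N), by = ontology]
  out[, significant := p_adj <= alpha]
  out[]
}

#' Benjamini-Hochberg FDR for pathways
#'
#' Step-up q-values over all pathway terms; significant when `q <= 0.05`.
#'
#' @param terms an [enrich_terms()] table (pathway ontology).
#' @param alpha significance cutoff.
#' @return the table with `p_adj` (q-value) and `significant` added.
#' @export
correct_pathways <- function(terms, alpha = 0.05) {
  out <- data.table::copy(terms)
  out[, p_adj := p.adjust(p_raw, method = "BH")]
  out[, significant := p_adj <= alpha]
  out[]
}
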