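#' Seed-region target prediction against 3' UTRs
#'
#' A target site is every exact occurrence of the reverse complement of the
#' miRNA seed (positions 2-8, a 7-mer) in a 3' UTR; U and T are equivalent.
#' UTRs shorter than 7 nt are skipped.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of 3' UTR sequences (DNA).
#' @return list with `hits` (data.table `mirna_id`, `gene_id`, `pos0`:
#'   0-based site offset) and `tally` (per-miRNA `n_sites`, `n_genes`).
#' @export
#' @examples
#' scan_targets(c(m = "TAGCTTATCAGACTGATGTTGA"),
#'              c(g = "GGAUAAGCUAGG"))$tally
scan_targets <- function(mirnas, utrs) {
  stopifnot(length(mirnas) > 0, !is.null(names(mirnas)))
  utrs <- chartr("Uu", "Tt", toupper(utrs))
  utrs <- utrs[nchar(utrs) >= 7L]
  tally <- data.table::data.table(mirna_id = names(mirnas), n_sites = 0L,
                                  n_genes = 0L)
  hits <- list()
  if (length(utrs)) {
    # all UTRs are scanned as one "\n"-joined subject (sites cannot span
    # the separator); matches are mapped back to records by offset
    subject <- paste(unname(utrs), collapse = "\n")
    bounds <- cumsum(nchar(utrs) + 1L)
    starts0 <- c(0L, bounds[-length(bounds)])
    for (i in seq_along(mirnas)) {
      seed <- substr(chartr("Uu", "Tt", toupper(mirnas[[i]])), 2L, 8L)
      if (nchar(seed) < 7L) next
      site <- revcomp_chr(seed)
      m <- gregexpr(site, subject, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      rec <- findInterval(m - 1L, starts0)
      hits[[length(hits) + 1L]] <- data.table::data.table(
        mirna_id = names(mirnas)[i],
        gene_id = names(utrs)[rec],
        pos0 = as.integer(m) - 1L - starts0[rec])
      tally[i, `:=`(n_sites = length(m),
                    n_genes = length(unique(rec)))]
    }
  }
  hits <- if (length(hits)) data.table::rbindlist(hits) else
    data.table::data.table(mirna_id = character(), gene_id = character(),
                           pos0 = integer())
  list(hits = hits, tally = tally)
}
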