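#' Run the full synthetic two-library study end to end
#'
#' Orchestrates `simulate -> clean -> annotate -> quantify -> diffexpr ->
#' novel -> targets -> enrich -> qpcr` from one configuration, writing every
#' stage output as plain text plus a JSON run manifest with input/output
#' digests. Re-running with an identical configuration yields identical
#' digests for all outputs.
#'
#' @param config a [sim_config()] (or a list of arguments for it, or a path
#'   to a YAML file holding such arguments).
#' @param out_dir output directory.
#' @param control control library index (1 or 2) for DE orientation.
#' @param quality_threshold mean-Phred low-quality threshold.
#' @param de_label_filter restrict clustering to labelled (`*`/`**`) miRNAs.
#' @param novel_energy_max,novel_min_reads novel-candidate thresholds (see
#'   [call_novel()]).
#' @return invisibly, a list with all in-memory stage results and
#'   `manifest`.
#' @export
run_all <- function(config, out_dir, control = 1L, quality_threshold = 20,
                    de_label_filter = TRUE, novel_energy_max = -18,
                    novel_min_reads = 3L) {
  config <- as_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[ovamir] ", ...)

  log_stage("simulate: building references")
  refs <- build_reference_set(config)
  ref_dir <- file.path(out_dir, "references")
  write_reference_set(refs, ref_dir)

  log_stage("simulate: libraries at depths ",
            paste(config$library_depths, collapse = "/"))
  truth <- simulate_libraries(config, refs, file.path(out_dir, "reads"))
  write_tsv(truth$mirna, file.path(out_dir, "truth_mirna.tsv"))
  write_tsv(truth$category_counts, file.path(out_dir, "truth_categories.tsv"))

  log_stage("clean: filtering reads")
  cl <- lapply(1:2, function(l)
    clean_reads(truth$fastq[l], config$adapter3, config$adapter5,
                quality_threshold = quality_threshold))
  reports <- list(lib1 = cl[[1]]$report, lib2 = cl[[2]]$report)
  write_tsv(filter_report_table(reports), file.path(out_dir, "filter_report.tsv"))
  clean_totals <- vapply(reports, function(r)
    r$count[r$type == "clean_reads"], numeric(1))

  ld <- length_distribution(rbind(cl[[1]]$tags, cl[[2]]$tags))
  write_tsv(ld, file.path(out_dir, "length_distribution.tsv"))

  tags <- collapse_tags(cl[[1]]$tags, cl[[2]]$tags)
  log_stage("annotate: ", nrow(tags), " unique tags")
  ann <- annotate_tags(tags, refs)
  write_tsv(ann, file.path(out_dir, "unique_tags.tsv"))
  comp <- summarize_composition(ann)
  write_tsv(comp, file.path(out_dir, "composition.tsv"))
  gm <- genome_mapping_summary(ann)
  write_tsv(gm, file.path(out_dir, "genome_mapping.tsv"))

  log_stage("quantify: crediting miRNA tags")
  qr <- suppressWarnings(assign_tags_to_mirnas(ann, refs))
  sets <- call_expression_sets(qr$records)
  expr <- data.table::copy(qr$records)
  expr[, std_lib1 := if (clean_totals[1] > 0)
    normalize_tpm(count_lib1, clean_totals[1]) else 0]
  expr[, std_lib2 := if (clean_totals[2] > 0)
    normalize_tpm(count_lib2, clean_totals[2]) else 0]
  expr[, set_label := ifelse(mirna_id %in% sets$co, "co-expressed",
                      ifelse(mirna_id %in% sets$spec1, "specific_lib1",
                      ifelse(mirna_id %in% sets$spec2, "specific_lib2",
                             "undetected")))]
  write_tsv(expr, file.path(out_dir, "expression.tsv"))

  de <- NULL
  if (all(clean_totals > 0)) {
    log_stage("diffexpr: exact test, control = lib", control)
    de <- de_table(qr$records, clean_totals, control = control)
    write_tsv(de, file.path(out_dir, "de_table.tsv"))
    labelled <- if (de_label_filter) de[sig_label != "None"] else de
    if (nrow(labelled) >= 2L) {
      cls <- cluster_de(labelled)
      export_newick(cls, file.path(out_dir, "de_cluster.nwk"))
    }
  }

  log_stage("novel: hairpin candidates from unannotated tags")
  hits <- attr(ann, "hits")
  if (is.null(hits))
    hits <- data.table::data.table(tag = character(), chrom = character(),
                                   start = integer(), strand = character())
  unann_hits <- merge(hits, ann[category == "unann",
                                .(tag, count_lib1, count_lib2)],
                      by = "tag")
  cands <- extract_candidates(unann_hits, refs$genome)
  novel <- call_novel(cands, refs$genome, refs$features,
                      energy_max = novel_energy_max,
                      min_reads = novel_min_reads)
  write_tsv(novel, file.path(out_dir, "novel_candidates.tsv"))
  if (nrow(novel[pass == TRUE]))
    export_novel(novel[pass == TRUE],
                 bed_path = file.path(out_dir, "novel_candidates.bed"),
                 structure_path = file.path(out_dir, "novel_structures.txt"))

  log_stage("targets: seed scan over ", length(refs$utr), " UTRs")
  detected <- expr[count_lib1 > 0 | count_lib2 > 0]
  tg <- if (nrow(detected)) {
    scan_targets(setNames(detected$mature_seq, detected$mirna_id), refs$utr)
  } else {
    list(hits = data.table::data.table(mirna_id = character(),
                                       gene_id = character(),
                                       pos0 = integer()),
         tally = data.table::data.table(mirna_id = character(),
                                        n_sites = integer(),
                                        n_genes = integer()))
  }
  write_tsv(tg$tally, file.path(out_dir, "target_tally.tsv"))

  log_stage("enrich: GO and pathway")
  target_genes <- unique(tg$hits$gene_id)
  go <- correct_go(enrich_terms(target_genes, refs$go_map))
  kegg <- correct_pathways(enrich_terms(target_genes, refs$kegg_map))
  write_tsv(go, file.path(out_dir, "go_enrichment.tsv"))
  write_tsv(kegg, file.path(out_dir, "kegg_enrichment.tsv"))

  log_stage("qpcr: delta-Ct validation")
  qpcr_res <- conc <- NULL
  if (nrow(truth$mirna)) {
    ct <- simulate_ct_table(config, truth)
    write_tsv(ct, file.path(out_dir, "ct_table.tsv"))
    qpcr_res <- group_compare(ct, control = c("Mul", "Uni")[control])
    write_tsv(qpcr_res, file.path(out_dir, "qpcr_results.tsv"))
    if (!is.null(de) && length(intersect(qpcr_res$mirna_id, de$mirna_id))) {
      conc <- concordance_with_sequencing(qpcr_res, de)
      write_tsv(conc$table, file.path(out_dir, "concordance.tsv"))
    }
  }

  manifest <- write_manifest(config, out_dir)
  log_stage("done: ", out_dir)
  invisible(list(config = config, refs = refs, truth = truth,
                 reports = reports, tags = ann, composition = comp,
                 expression = expr, sets = sets, de = de, novel = novel,
                 targets = tg, go = go, kegg = kegg, qpcr = qpcr_res,
                 concordance = conc, manifest = manifest))
}

# accept sim_config, list of args, or YAML path
as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$contamination_fractions))
      config$contamination_fractions <- unlist(config$contamination_fractions)
    if (!is.null(config$length_profile))
      config$length_profile <- unlist(config$length_profile)
    if (!is.null(config$library_depths))
      config$library_depths <- as.integer(unlist(config$library_depths))
  }
  stopifnot(is.list(config))
  do.call(sim_config, config)
}

write_manifest <- function(config, out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "ovamir",
    version = as.character(utils::packageVersion("ovamir")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    outputs = setNames(as.list(unname(digests)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}

#' Minimal command-line front end
#'
#' Subcommands: `simulate` (references + libraries + CT table only) and
#' `run` (full pipeline). Arguments: `--config FILE.yaml`, `--out DIR`,
#' optional `--seed N` override. Invoked by the `inst/cli/ovamir.R` script:
#' `Rscript ovamir.R run --config demo.yaml --out results/`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
ovamir_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h")) {
    cat("usage: ovamir <simulate|run> --config FILE.yaml --out DIR",
        "[--seed N]\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat("ovamir", as.character(utils::packageVersion("ovamir")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  out <- opt("--out")
  cfg_path <- opt("--config")
  if (is.null(out)) stop("--out is required")
  cfg <- if (is.null(cfg_path)) list() else {
    y <- yaml::read_yaml(cfg_path)
    y
  }
  seed <- opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  config <- as_sim_config(cfg)
  if (cmd == "simulate") {
    refs <- build_reference_set(config)
    write_reference_set(refs, file.path(out, "references"))
    truth <- simulate_libraries(config, refs, file.path(out, "reads"))
    write_tsv(truth$mirna, file.path(out, "truth_mirna.tsv"))
    ct <- simulate_ct_table(config, truth)
    write_tsv(ct, file.path(out, "ct_table.tsv"))
  } else if (cmd == "run") {
    run_all(config, out)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
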