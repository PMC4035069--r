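# One modest simulated study shared across test files (built lazily once).
# Depths are kept small so the default suite stays fast; the planted-signal
# tests that need more reads build their own configurations.

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (!is.null(.sim_cache$res)) return(.sim_cache$res)
  cfg <- sim_config(seed = 42L, n_mirnas = 25L,
                    library_depths = c(12000L, 12000L),
                    n_novel_hairpins = 3L,
                    contamination_fractions = c(
                      low_quality = 0.006, adapter3_null = 0.0005,
                      insert_null = 0.0005, adapter5 = 0.002,
                      short = 0.002, polyA = 0.001,
                      rRNA = 0.03, tRNA = 0.008, snRNA = 0.004,
                      snoRNA = 0.004, scRNA = 0.001, srpRNA = 0.001,
                      "repeat" = 0.002, exon = 0.005, intron = 0.005,
                      unann = 0.02, novel = 0.005))
  refs <- build_reference_set(cfg)
  truth <- simulate_libraries(cfg, refs, file.path(tempdir(), "ovamir_shared"))
  cl <- lapply(1:2, function(l)
    clean_reads(truth$fastq[l], cfg$adapter3, cfg$adapter5))
  tags <- collapse_tags(cl[[1]]$tags, cl[[2]]$tags)
  ann <- annotate_tags(tags, refs)
  clean_totals <- vapply(cl, function(x)
    x$report$count[x$report$type == "clean_reads"], numeric(1))
  .sim_cache$res <- list(cfg = cfg, refs = refs, truth = truth, cl = cl,
                         tags = tags, ann = ann,
                         clean_totals = clean_totals)
  .sim_cache$res
}
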