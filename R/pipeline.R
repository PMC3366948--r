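#' Read a pipeline run configuration from YAML
#'
#' The configuration mirrors [run_pipeline()]'s argument list: either a
#' `sim:` block (passed to [sim_config()]) or explicit input paths
#' (`reference`, `sam_a`, `sam_b`, `targets`, `models`, `known`, `truth`),
#' plus `caller`, `min_doc`, `min_vaf`, `consensus`, `seed`, `out_dir`.
#'
#' @param path YAML file.
#' @return a named list usable as `config` in [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the full pipeline: simulate/ingest, dedup, pileup, call, annotate,
#' benchmark
#'
#' With a `sim` block in the configuration the synthetic panel is generated
#' first and its files written to the output directory; otherwise the
#' configured input paths are loaded. Both alignment views are then
#' deduplicated, piled up, called with the configured caller, post-filtered,
#' intersected when `consensus` is on, annotated against the gene models
#' and the known-variant list, and benchmarked over the DoC x VAF grid.
#' Every output carries the seed in its name-side manifest entry; the
#' manifest records an MD5 checksum per file, so two runs of the same
#' configuration can be compared file by file.
#'
#' @param config named list (see [read_run_config()]). Recognised fields:
#'   `sim` (list of [sim_config()] arguments), `reference`, `sam_a`,
#'   `sam_b`, `targets`, `models`, `known`, `truth` (paths), `caller`
#'   (`"threshold"` or `"hcdiff"`), `min_doc`, `min_vaf`, `consensus`
#'   (logical), `seed`, `out_dir`.
#' @return invisibly, a data.table manifest (file, md5) with the run's
#'   summary attached as attribute `"summary"`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  caller <- if (is.null(config$caller)) "threshold" else config$caller
  min_doc <- if (is.null(config$min_doc)) 3 else config$min_doc
  min_vaf <- if (is.null(config$min_vaf)) 0.20 else config$min_vaf
  consensus <- !isFALSE(config$consensus)

  if (!is.null(config$sim)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
    panel_obj <- build_panel(scfg)
    truth <- plant_variants(panel_obj, scfg)
    rs <- emit_reads(panel_obj, truth, scfg, sample = 1L)
    files <- write_simulation(panel_obj, truth, list(rs), out_dir)
    reference <- panel_obj$reference
    panel <- panel_obj$panel
    models <- panel_obj$models
    known <- unique(truth[known == TRUE, .(contig, pos, ref, alt)])
    sam_a <- files[["sam_s1_A"]]
    sam_b <- files[["sam_s1_B"]]
  } else {
    for (f in c("reference", "sam_a", "targets", "models")) {
      if (is.null(config[[f]])) stop("config$", f, " is required")
      if (!file.exists(config[[f]])) stop("input file not found: ",
                                          config[[f]])
    }
    if (consensus && is.null(config$sam_b))
      stop("consensus is on but only one SAM view was configured")
    reference <- Biostrings::readDNAStringSet(config$reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    panel <- fread(config$targets, header = FALSE,
                   col.names = c("contig", "start", "end"))
    models <- read_gene_models(config$models)
    known <- if (!is.null(config$known)) fread(config$known) else NULL
    truth <- if (!is.null(config$truth)) fread(config$truth) else NULL
    sam_a <- config$sam_a
    sam_b <- config$sam_b
    files <- c()
  }

  reads_a <- read_alignments(sam_a, view_id = "A", reference = reference)
  dedup_a <- remove_duplicates(reads_a)
  pile_a <- build_pileup(dedup_a$reads, panel, reference)
  calls_a <- single_view_calls(caller, pile_a, reference, "A",
                               min_doc, min_vaf)
  calls_a <- pass_calls(var_filter(calls_a, pile_a))
  if (consensus) {
    reads_b <- read_alignments(sam_b, view_id = "B", reference = reference)
    dedup_b <- remove_duplicates(reads_b)
    pile_b <- build_pileup(dedup_b$reads, panel, reference)
    calls_b <- single_view_calls(caller, pile_b, reference, "B",
                                 min_doc, min_vaf)
    calls_b <- pass_calls(var_filter(calls_b, pile_b))
    calls <- consensus_intersect(calls_a, calls_b)
  } else {
    pile_b <- NULL
    calls <- calls_a
  }

  fk <- filter_known(calls, known)
  annotated <- classify_calls(fk$novel, models, reference,
                              known_list = known)
  annotated[, sample_id := 1L]

  files["calls_vcf"] <- file.path(out_dir, "calls.vcf")
  write_vcf(annotated, files[["calls_vcf"]], reference)
  files["annotated_tsv"] <- file.path(out_dir, "calls_annotated.tsv")
  fwrite(annotated, files[["annotated_tsv"]], sep = "\t")

  clusters <- snp_clusters(annotated, window_bp = 200, min_snvs = 3)
  files["clusters_tsv"] <- file.path(out_dir, "snp_clusters.tsv")
  fwrite(clusters, files[["clusters_tsv"]], sep = "\t")

  summary <- list(seed = seed, caller = caller, consensus = consensus,
                  n_calls = nrow(calls), n_known = fk$n_known,
                  n_dedup_removed_a = dedup_a$n_removed,
                  n_clusters = nrow(clusters))

  if (!is.null(truth) && nrow(truth) && !is.null(pile_b)) {
    truth1 <- truth[truth$sample_id == 1L, ]
    pooled <- rbind(
      base_calls("threshold", pile_a, reference, "A"),
      base_calls("hcdiff", pile_a, reference, "A"))
    validation <- make_validation_set(truth1, pooled, panel, seed = seed)
    bench <- benchmark_sweep(pile_a, pile_b, validation, reference)
    files["benchmark_tsv"] <- file.path(out_dir, "benchmark.tsv")
    write_benchmark_tsv(bench, files[["benchmark_tsv"]])
    files["roc_tsv"] <- paste0(files[["benchmark_tsv"]], ".roc.tsv")
    summary$benchmark <- bench
  }

  gca <- gc_coverage_assoc(panel, pile_a, reference = reference)
  files["gc_coverage_tsv"] <- file.path(out_dir, "gc_coverage.tsv")
  fwrite(gca$table, files[["gc_coverage_tsv"]], sep = "\t")
  summary$gc_coverage_p <- gca$p_value

  manifest <- data.table(file = unname(files),
                         md5 = unname(tools::md5sum(unname(files))))
  manifest[, seed := seed]
  files["manifest"] <- file.path(out_dir, "manifest.tsv")
  fwrite(manifest, files[["manifest"]], sep = "\t")
  setattr(manifest, "summary", summary)
  invisible(manifest)
}

single_view_calls <- function(caller, pileup, reference, view_id,
                              min_doc, min_vaf) {
  switch(caller,
         threshold = threshold_call(pileup, min_doc = min_doc,
                                    min_vaf = min_vaf, view_id = view_id),
         hcdiff = apply_thresholds(
           hcdiff_call(pileup, reference, view_id = view_id),
           min_doc = min_doc, min_vaf = min_vaf),
         stop("unknown caller: ", caller))
}
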