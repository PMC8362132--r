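#' @title Pipeline orchestration
#' @description Config-driven end-to-end runs: simulate or ingest a
#'   dataset, build observation scales, map habitat transitions, run all
#'   comparisons, apply reduce-and-retain, compute alignments and the
#'   mechanism ledger, and write every stage as TSV plus a JSON run
#'   manifest.  All randomness flows from one root seed through logged
#'   per-stage seeds.
#' @name pipeline
NULL

#' Build and validate a run configuration
#'
#' Either `tree`/`taxa` paths or a `simulate` block must be given.
#'
#' @param tree,taxa input paths (Newick, TSV taxon table), or `NULL` when
#'   simulating.
#' @param simulate `NULL` or a list of [sim_config()] arguments.
#' @param scales observation scales to build.
#' @param tax_sections section counts for the tax scales.
#' @param min_n,n_sim,n_perm,n_maps,top_m engine and mapping parameters.
#' @param metrics size metrics to run.
#' @param variance_metrics include variance-vs-simulated metrics.
#' @param mk_constraint Mk constraint for transition mapping.
#' @param seed root seed.
#' @return validated `run_config` list.
#' @export
run_config <- function(tree = NULL, taxa = NULL, simulate = NULL,
                       scales = c("order", "tax3", "tax4", "tax5", "tax6",
                                  "full"),
                       tax_sections = c(tax3 = 13, tax4 = 9, tax5 = 5,
                                        tax6 = 3),
                       min_n = 3, n_sim = 999, n_perm = 999, n_maps = 100,
                       top_m = 2, metrics = SIZE_METRICS,
                       variance_metrics = FALSE,
                       mk_constraint = "ARD", seed = 1L) {
  if (is.null(simulate) && (is.null(tree) || is.null(taxa)))
    stop("config needs either input paths (tree + taxa) or a simulate ",
         "block", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields mirror [run_config()] arguments.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$tax_sections)) raw$tax_sections <- unlist(raw$tax_sections)
  if (!is.null(raw$simulate)) raw$simulate <- as.list(raw$simulate)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate/ingest, partition into scales, transition mapping
#' (when hotspot scales or `run_transitions` are requested), comparisons,
#' reduce-and-retain, alignment, mechanisms.  Every stage's table is
#' written under `out_dir` and a `manifest.json` records the seed,
#' per-stage seeds, row counts and timings.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param run_transitions force the transition-mapping stage even without
#'   hotspot scales.
#' @return list of in-memory stage results, invisibly; side effect: TSVs
#'   plus `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, run_transitions = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L,
                        c("simulate", "transitions", "compare", "retain"))
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   package_version =
                     as.character(utils::packageVersion("habsize")),
                   counts = list(), timings = list())
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- ingest / simulate -------------------------------------------------
  history <- NULL
  if (!is.null(config$simulate)) {
    sargs <- config$simulate
    sargs$seed <- sargs$seed %||% seeds[["simulate"]]
    sim <- simulate_dataset(do.call(sim_config, sargs))
    dataset <- sim$dataset
    history <- sim$history
    write_dataset_bundle(sim, file.path(out_dir, "dataset"))
  } else {
    dataset <- match_tree_table(read_newick(config$tree),
                                read_taxon_table(config$taxa))
  }
  validate_dataset(dataset)
  manifest$counts$n_tips <- length(dataset$tree$tip.label)
  manifest$timings$ingest <- tic() - t0

  # --- transitions (needed for hotspot scales) ---------------------------
  t0 <- tic()
  need_maps <- run_transitions ||
    any(c("hotspot", "hotspot_expanded") %in% config$scales)
  trans <- NULL
  if (need_maps) {
    tips <- setNames(dataset$records$habitat, dataset$records$species)
    fit <- fit_mk(dataset$tree, tips, constraint = config$mk_constraint,
                  seed = seeds[["transitions"]])
    trans <- stochastic_maps(dataset$tree, tips, fit,
                             n_maps = config$n_maps,
                             seed = seeds[["transitions"]])
    write_tsv(transition_table(trans), file.path(out_dir,
                                                 "transitions.tsv"))
    manifest$counts$mean_transitions <- sum(trans$mean_counts)
  }
  manifest$timings$transitions <- tic() - t0

  # --- scales ------------------------------------------------------------
  t0 <- tic()
  scales <- build_scales(dataset, config$scales, config$tax_sections,
                         transition_summary = trans, top_m = config$top_m)
  write_tsv(scales_to_table(scales), file.path(out_dir, "scales.tsv"))
  manifest$counts$n_scales <- length(scales)
  manifest$counts$n_clades <- sum(vapply(scales, function(s)
    length(s$clades), integer(1)))
  manifest$timings$scales <- tic() - t0

  # --- comparisons -------------------------------------------------------
  t0 <- tic()
  eng_cfg <- list(min_n = config$min_n, metrics = config$metrics,
                  summary_metrics = TRUE,
                  variance_metrics = config$variance_metrics,
                  n_sim = config$n_sim, n_perm = config$n_perm,
                  seed = seeds[["compare"]])
  results <- run_all(dataset, scales, eng_cfg)
  if (is.null(results)) stop("comparison stage produced no results",
                             call. = FALSE)
  write_tsv(as.data.frame(results), file.path(out_dir, "results.tsv"))
  write_tsv(attr(results, "summaries"), file.path(out_dir,
                                                  "summaries.tsv"))
  maj <- do.call(rbind, lapply(unique(results$metric), function(m)
    majority_summaries(results, m)))
  write_tsv(maj, file.path(out_dir, "majority.tsv"))
  if ("order" %in% names(scales)) {
    dn <- donut_table(results, scale = "order")
    if (!is.null(dn)) write_tsv(dn, file.path(out_dir, "donut.tsv"))
  }
  manifest$counts$n_comparisons <-
    nrow(unique(results[, c("scale", "clade_id", "first", "second")]))
  manifest$counts$n_result_rows <- nrow(results)
  manifest$timings$compare <- tic() - t0

  # --- reduce and retain, alignment, mechanisms --------------------------
  t0 <- tic()
  eng_cfg$seed <- seeds[["retain"]]
  reduced <- tryCatch(
    reduce_and_retain(dataset, scales, eng_cfg, full_results = results),
    error = function(e) NULL)
  ledger <- NULL; mech <- NULL
  if (!is.null(reduced)) {
    write_tsv(reduced$retained, file.path(out_dir, "retained.tsv"))
    write_tsv(as.data.frame(reduced$results),
              file.path(out_dir, "reduced_results.tsv"))
    write_tsv(attr(reduced$results, "summaries"),
              file.path(out_dir, "reduced_summaries.tsv"))
    align <- percentage_alignment(reduced$results, "phylo_mean",
                                  "trophic_phylo_mean")
    if (nrow(align)) write_tsv(align, file.path(out_dir, "alignment.tsv"))
    ledger <- mechanism_ledger(reduced)
    if (!is.null(ledger)) {
      write_tsv(ledger, file.path(out_dir, "mechanism_ledger.tsv"))
      mech <- aggregate_mechanisms(ledger)
      write_tsv(mech, file.path(out_dir, "mechanism_summary.tsv"))
      manifest$counts$n_retained <- nrow(ledger)
    }
    manifest$counts$n_reduced_comparisons <-
      nrow(reduced$retained)
  }
  manifest$timings$mechanisms <- tic() - t0

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, history = history, scales = scales,
                 transitions = trans, results = results,
                 reduced = reduced, ledger = ledger,
                 mechanism_summary = mech, manifest = manifest))
}
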