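#' Characterize one or more panels and write reports
#'
#' For each panel: a JSON report (`<name>_report.json`, schema-versioned, with
#' every parameter and seed echoed) and a per-gene importance TSV
#' (`<name>_genes.tsv`). With two or more panels, a combined
#' standardized-score matrix (`panel_comparison.tsv`) is also written.
#'
#' @param ds an [expression_dataset()] with a lognorm layer
#' @param panels a [gene_panel()] or list of them
#' @param out_dir output directory
#' @param db,lr_table,graph,pmodel optional inputs, see [category_scores()]
#' @param config a [score_config()]
#' @return invisibly, the list of `panel_report` objects
#' @export
run_characterize <- function(ds, panels, out_dir, db = NULL, lr_table = NULL,
                             graph = NULL, pmodel = NULL,
                             config = score_config()) {
  if (inherits(panels, "gene_panel")) panels <- list(panels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(panels, function(p) {
    rep <- characterize_panel(ds, p, db = db, lr_table = lr_table,
                              graph = graph, pmodel = pmodel, config = config)
    write_report_json(rep, file.path(out_dir, paste0(rep$panel, "_report.json")))
    utils::write.table(rep$per_gene_importance,
                       file.path(out_dir, paste0(rep$panel, "_genes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })
  if (length(reports) >= 2) {
    utils::write.table(standardized_scores(reports),
                       file.path(out_dir, "panel_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(reports)
}

write_report_json <- function(rep, path) {
  payload <- list(
    schema_version = rep$provenance$schema_version,
    panel = rep$panel,
    overall = rep$overall,
    category_scores = as.list(rep$category_scores$values),
    available = rep$category_scores$available,
    per_gene_importance = rep$per_gene_importance,
    provenance = rep$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the genetic-algorithm optimizer and write its outputs
#'
#' Writes `best_panel.txt`, `ga_state.json` (best objective, iterations,
#' convergence, seed) and `trajectory.csv` (iteration, best, mean).
#'
#' @param ds an [expression_dataset()] with a lognorm layer
#' @param ga a [ga_config()]
#' @param out_dir output directory
#' @param db,graph optional objective inputs
#' @param config a [score_config()]
#' @param objective optional injected objective, see [optimize_panel()]
#' @return invisibly, the `ga_state`
#' @export
run_optimize <- function(ds, ga, out_dir, db = NULL, graph = NULL,
                         config = score_config(), objective = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- optimize_panel(ga, ds = ds, db = db, graph = graph,
                          config = config, objective = objective)
  write_panel(state$best_panel, file.path(out_dir, "best_panel.txt"))
  jsonlite::write_json(
    list(schema_version = "1.0",
         best_objective = state$best_objective,
         best_panel = state$best_panel$genes,
         iterations_run = state$iterations_run,
         converged = state$converged,
         n_evaluations = state$n_evaluations,
         seed = state$seed,
         config = unclass(state$config)),
    file.path(out_dir, "ga_state.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(tidy.ga_state(state),
                   file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  invisible(state)
}

#' Simulate a full fixture directory
#'
#' Writes everything [run_characterize()] needs: the count matrix
#' (MTX + identifier lists), `labels.csv`, `coords.csv`, `pathways.gmt`,
#' `lr_table.csv`, and ground-truth panels (`panel_marker.txt`,
#' `panel_noise.txt`).
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory
#' @param lr_fraction fraction of genes annotated as ligand/receptor
#' @param n_extra random pathways in the simulated database
#' @return invisibly, the simulated [expression_dataset()]
#' @export
run_simulate <- function(cfg = sim_config(), out_dir, lr_fraction = 0.2,
                         n_extra = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(cfg)
  save_expression(ds, out_dir, format = "mtx")
  write_gmt(simulate_pathway_db(cfg, n_extra = n_extra),
            file.path(out_dir, "pathways.gmt"))
  utils::write.csv(simulate_lr_table(cfg, lr_fraction = lr_fraction),
                   file.path(out_dir, "lr_table.csv"), row.names = FALSE)
  write_panel(simulated_panel(ds, "marker"),
              file.path(out_dir, "panel_marker.txt"))
  noise_size <- min(cfg$n_types * cfg$markers_per_type, cfg$n_noise)
  if (noise_size >= 1) {
    write_panel(simulated_panel(ds, "noise", size = noise_size,
                                seed = cfg$seed),
                file.path(out_dir, "panel_noise.txt"))
  }
  invisible(ds)
}
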