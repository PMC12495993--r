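#' Scoring configuration
#'
#' Bundles every tunable metric parameter, the category weights for the
#' overall score, and the per-metric weights of the optimizer objective.
#'
#' @param epsilon gsc pseudocount (default 0.01)
#' @param tau feature-diversity redundancy threshold on `|rho|` (default 0.3)
#' @param alpha pathway significance level on q-values (default 0.05)
#' @param jaccard_cut pathway-diversity similarity cut (default 0.7)
#' @param k_neighbors spatial graph neighbors (default 6)
#' @param delta perturbation effect threshold (default 0.1)
#' @param n_folds classifier cross-validation folds (default 5)
#' @param weights named non-negative category weights over
#'   specificity/diversity/biology/spatial/forward; renormalized over the
#'   categories actually available
#' @param ga_weights named non-negative weights of the optimizer objective
#'   constituents (diversity, pathway, entropy, spatial, nmi)
#' @param seed RNG seed for every stochastic step (k-means, folds, forests)
#' @return a `score_config` list
#' @export
score_config <- function(epsilon = 0.01, tau = 0.3, alpha = 0.05,
                         jaccard_cut = 0.7, k_neighbors = 6, delta = 0.1,
                         n_folds = 5,
                         weights = c(specificity = 1, diversity = 1,
                                     biology = 1, spatial = 1, forward = 1),
                         ga_weights = c(diversity = 1, pathway = 1,
                                        entropy = 1, spatial = 1, nmi = 1),
                         seed = 1) {
  stopifnot(epsilon > 0, tau > 0, tau < 1, alpha > 0, alpha < 1,
            jaccard_cut >= 0, jaccard_cut <= 1, delta >= 0, n_folds >= 2,
            all(weights >= 0), all(ga_weights >= 0))
  categories <- c("specificity", "diversity", "biology", "spatial", "forward")
  w <- stats::setNames(rep(1, 5), categories)
  w[names(weights)] <- weights
  gw <- stats::setNames(rep(1, 5), c("diversity", "pathway", "entropy",
                                     "spatial", "nmi"))
  gw[names(ga_weights)] <- ga_weights
  structure(list(epsilon = epsilon, tau = tau, alpha = alpha,
                 jaccard_cut = jaccard_cut, k_neighbors = k_neighbors,
                 delta = delta, n_folds = n_folds, weights = w,
                 ga_weights = gw, seed = seed),
            class = "score_config")
}

#' Category scores for a panel
#'
#' Computes the five metric categories, each mapped to `[0, 1]`:
#' \describe{
#'   \item{specificity}{mean of classifier balanced accuracy, `1 - entropy`,
#'     and variation-recovery NMI}
#'   \item{diversity}{feature diversity mapped via `(D + 1) / 2`}
#'   \item{biology}{mean of the proportion of enriched panel genes, the
#'     pathway diversity score, and the ligand/receptor proportion — requires
#'     a pathway database (a missing LR table counts as an empty one)}
#'   \item{spatial}{mean over genes of `(Moran's I + 1) / 2` — requires
#'     coordinates}
#'   \item{forward}{panel perturbation score — requires a perturbation model}
#' }
#' Categories whose optional inputs are absent are dropped from `available`.
#'
#' @param ds an [expression_dataset()] with a lognorm layer
#' @param panel a [gene_panel()]
#' @param db optional [pathway_database()]
#' @param lr_table optional ligand/receptor table (`gene`, `category`)
#' @param graph optional [build_knn_graph()] (built from coordinates when the
#'   dataset has them and this is NULL)
#' @param pmodel optional [perturbation_model()]
#' @param config a [score_config()]
#' @return a `category_scores` object: `values` (named numeric over available
#'   categories), `available`, `weights`, and the per-metric intermediates
#' @export
category_scores <- function(ds, panel, db = NULL, lr_table = NULL,
                            graph = NULL, pmodel = NULL,
                            config = score_config()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(config, "score_config"))
  panel <- intersect_panel(panel, ds)
  inter <- list(panel = panel)

  sm <- gene_specificity_matrix(ds, panel, epsilon = config$epsilon)
  ent <- panel_entropy_score(sm)
  clf <- classification_performance(ds, panel, n_folds = config$n_folds,
                                    seed = config$seed)
  v_nmi <- variation_recovery_nmi(ds, panel, seed = config$seed)
  inter$specificity_matrix <- sm
  inter$entropy <- ent
  inter$classification <- clf
  inter$nmi <- v_nmi
  values <- c(specificity = mean(c(clf$balanced_accuracy,
                                   1 - ent$entropy, v_nmi)))

  div <- feature_diversity_score(ds, panel, tau = config$tau)
  inter$diversity <- div
  values["diversity"] <- (div$score + 1) / 2

  if (!is.null(db)) {
    enr <- enrich_pathways(panel, db, universe = ds$gene_ids,
                           alpha = config$alpha)
    pdiv <- pathway_diversity_score(enr, jaccard_cut = config$jaccard_cut)
    lr <- ligand_receptor_summary(panel, lr_table)
    inter$enrichment <- enr
    inter$pathway_diversity <- pdiv
    inter$lr <- lr
    inter$lr_table <- lr_table
    values["biology"] <- mean(c(enr$pct_genes_enriched, pdiv,
                                lr$lr_proportion))
  }

  if (!is.null(graph) || !is.null(ds$coords)) {
    graph <- graph %||% build_knn_graph(ds$coords, k = config$k_neighbors)
    spat <- spatial_metrics(ds, panel, graph)
    inter$spatial <- spat
    ok <- !spat$per_gene$degenerate
    values["spatial"] <- mean((spat$per_gene$morans_i[ok] + 1) / 2)
  }

  if (!is.null(pmodel)) {
    pert <- panel_perturbation_score(pmodel, panel, delta = config$delta)
    inter$perturbation <- pert
    values["forward"] <- pert$panel_score
  }

  if (length(values) == 0) stop("no category computable from the given inputs")

  structure(list(values = values, available = names(values),
                 weights = config$weights, intermediates = inter,
                 panel = panel$name),
            class = "category_scores")
}

#' @export
print.category_scores <- function(x, ...) {
  cat("<category_scores> '", x$panel, "': ",
      paste(sprintf("%s = %.3f", names(x$values), x$values), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn category_scores tibble (`category`, `score`, `weight`)
#' @param x a `category_scores`
#' @param ... unused
#' @export
tidy.category_scores <- function(x, ...) {
  w <- x$weights[x$available]
  tibble::tibble(category = names(x$values), score = unname(x$values),
                 weight = unname(w / sum(w)))
}

#' Weighted overall score
#'
#' `sum(w_c * s_c)` over available categories with the weights renormalized to
#' sum to 1 — hence invariant to a positive rescaling of all weights.
#'
#' @param cs a [category_scores()] result
#' @param weights optional override of the category weights
#' @return overall score in `[0, 1]`
#' @export
overall_score <- function(cs, weights = NULL) {
  stopifnot(inherits(cs, "category_scores"))
  w <- (weights %||% cs$weights)[cs$available]
  if (anyNA(w) || all(w == 0)) stop("weights must be non-negative, not all zero")
  w <- w / sum(w)
  sum(w * cs$values[cs$available])
}

#' Per-gene importance scores
#'
#' Quantifies each gene's contribution to its panel. Raw per-gene sub-scores —
#' specificity: `max_t gsc(g, t)`; diversity: `1 - mean_j |rho(g, j)|`;
#' biology: `0.5 * 1[g in a significant pathway] + 0.5 * 1[g is
#' ligand/receptor]`; spatial: Moran's I; forward: rank-normalized
#' perturbation score — are each min-max normalized within the panel, then
#' combined as a weighted mean over the available categories. A degenerate
#' min-max range (e.g. a single-gene panel) yields 0.5 for that sub-score with
#' a warning.
#'
#' @param cs a [category_scores()] result
#' @param weights optional override of the category weights
#' @return tibble (`gene`, one column per available category, `importance`)
#' @export
gene_importance_scores <- function(cs, weights = NULL) {
  stopifnot(inherits(cs, "category_scores"))
  inter <- cs$intermediates
  genes <- inter$panel$genes

  raw <- list()
  raw$specificity <- apply(inter$specificity_matrix$values[genes, , drop = FALSE],
                           1, max)
  rho <- inter$diversity$correlations
  mean_abs <- vapply(genes, function(g) {
    r <- abs(c(rho$rho[rho$gene_a == g], rho$rho[rho$gene_b == g]))
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  raw$diversity <- 1 - mean_abs

  if ("biology" %in% cs$available) {
    enr <- inter$enrichment
    sig_sets <- enr$members[enr$per_pathway$pathway[enr$per_pathway$significant]]
    in_sig <- genes %in% unique(unlist(sig_sets, use.names = FALSE))
    raw$biology <- 0.5 * in_sig + 0.5 * lr_flags(genes, inter$lr_table)
  }
  if ("spatial" %in% cs$available) {
    sp <- inter$spatial$per_gene
    raw$spatial <- sp$morans_i[match(genes, sp$gene)]
  }
  if ("forward" %in% cs$available) {
    pert <- inter$perturbation
    raw$forward <- unname(pert$normalized[genes])   # NA for uncovered genes
  }

  norm <- lapply(raw, minmax_or_half)
  w <- (weights %||% cs$weights)[names(norm)]
  w <- w / sum(w)
  mat <- do.call(cbind, norm)
  importance <- apply(mat, 1, function(r) {
    ok <- !is.na(r)
    if (!any(ok)) return(NA_real_)
    sum(r[ok] * w[ok] / sum(w[ok]))
  })
  out <- tibble::as_tibble(as.data.frame(mat))
  tibble::tibble(gene = genes, out, importance = unname(importance))
}

minmax_or_half <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    warning("degenerate min-max range; sub-scores set to 0.5")
    return(ifelse(is.na(x), NA_real_, 0.5))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

lr_flags <- function(genes, lr_table) {
  if (is.null(lr_table) || nrow(lr_table) == 0) return(rep(0, length(genes)))
  as.numeric(genes %in% lr_table$gene)
}

#' Full panel characterization report
#'
#' Runs every available metric category, the per-gene importance scores and
#' the weighted overall score, and records the configuration and seed used.
#'
#' @inheritParams category_scores
#' @return a `panel_report`
#' @export
characterize_panel <- function(ds, panel, db = NULL, lr_table = NULL,
                               graph = NULL, pmodel = NULL,
                               config = score_config()) {
  cs <- category_scores(ds, panel, db = db, lr_table = lr_table,
                        graph = graph, pmodel = pmodel, config = config)
  structure(list(
    panel = cs$panel,
    per_gene_importance = gene_importance_scores(cs),
    category_scores = cs,
    overall = overall_score(cs),
    provenance = list(config = unclass(config),
                      seed = config$seed,
                      n_cells = n_cells(ds), n_genes = n_genes(ds),
                      schema_version = "1.0")
  ), class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("<panel_report> '", x$panel, "': overall = ", signif(x$overall, 4),
      "\n", sep = "")
  print(x$category_scores)
  invisible(x)
}

#' @describeIn characterize_panel per-gene importance tibble
#' @param x a `panel_report`
#' @param ... unused
#' @export
tidy.panel_report <- function(x, ...) x$per_gene_importance

#' @describeIn characterize_panel one-row tibble of category and overall
#'   scores
#' @export
glance.panel_report <- function(x, ...) {
  vals <- x$category_scores$values
  tibble::tibble(panel = x$panel, !!!as.list(vals), overall = x$overall)
}

#' Optimizer objective for a panel
#'
#' The cheap multi-metric objective maximized by the genetic algorithm: an
#' equally weighted (overridable via `config$ga_weights`) mean of the
#' constituents already in `[0, 1]` — feature diversity `(D + 1) / 2`, pathway
#' diversity, `1 - panel entropy`, the spatial score `mean (I + 1) / 2`, and
#' variation-recovery NMI. Constituents whose inputs are absent (no pathway
#' database, no coordinates) are dropped and the weights renormalized. The
#' classifier and perturbation model are deliberately excluded to keep each
#' evaluation fast.
#'
#' @inheritParams category_scores
#' @return objective value in `[0, 1]`
#' @export
ga_objective <- function(ds, panel, db = NULL, graph = NULL,
                         config = score_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  panel <- intersect_panel(panel, ds)
  vals <- c()

  div <- feature_diversity_score(ds, panel, tau = config$tau)
  vals["diversity"] <- (div$score + 1) / 2

  if (!is.null(db)) {
    enr <- enrich_pathways(panel, db, universe = ds$gene_ids,
                           alpha = config$alpha)
    vals["pathway"] <- pathway_diversity_score(enr,
                                               jaccard_cut = config$jaccard_cut)
  }

  sm <- gene_specificity_matrix(ds, panel, epsilon = config$epsilon)
  vals["entropy"] <- 1 - panel_entropy_score(sm)$entropy

  if (!is.null(graph) || !is.null(ds$coords)) {
    graph <- graph %||% build_knn_graph(ds$coords, k = config$k_neighbors)
    spat <- spatial_metrics(ds, panel, graph)
    ok <- !spat$per_gene$degenerate
    vals["spatial"] <- mean((spat$per_gene$morans_i[ok] + 1) / 2)
  }

  vals["nmi"] <- variation_recovery_nmi(ds, panel, seed = config$seed)

  w <- config$ga_weights[names(vals)]
  w <- w / sum(w)
  sum(w * vals)
}
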