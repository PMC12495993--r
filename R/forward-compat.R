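#' Perturbation model contract
#'
#' Forward compatibility is scored against any model that can report, for each
#' covered gene, the per-gene response magnitudes of perturbing it. A
#' perturbation model is a list with `covered_genes` (character) and
#' `respond(gene)` returning a named numeric vector of log-fold-change-like
#' effects over the covered genes. Deep-learning simulators or precomputed
#' response matrices plug in through the same contract.
#'
#' @param covered_genes character vector of genes the model can perturb
#' @param respond function(gene) -> named numeric response vector
#' @return a `perturbation_model`
#' @export
perturbation_model <- function(covered_genes, respond) {
  covered_genes <- unique(as.character(covered_genes))
  stopifnot(length(covered_genes) > 0, is.function(respond))
  structure(list(covered_genes = covered_genes, respond = respond),
            class = "perturbation_model")
}

#' @export
print.perturbation_model <- function(x, ...) {
  cat("<perturbation_model> ", length(x$covered_genes), " covered genes\n",
      sep = "")
  invisible(x)
}

#' Perturbation model from a response matrix
#'
#' Rows are perturbed genes, columns responding genes; entry (g, j) is the
#' effect of perturbing g on j.
#'
#' @param mat numeric matrix with row and column names
#' @return a [perturbation_model()]
#' @export
response_matrix_model <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("response matrix needs row (perturbed) and column (responding) gene names")
  }
  if (!all(is.finite(mat))) stop("non-finite response values")
  perturbation_model(rownames(mat), function(gene) mat[gene, ])
}

#' @rdname response_matrix_model
#' @param path CSV with perturbed genes as the first column, responding genes
#'   as header
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  response_matrix_model(mat)
}

#' Seeded sparse linear-response model
#'
#' A synthetic perturbation source: a sparse random effect matrix where
#' perturbing gene g elicits effects on a random `density` fraction of genes,
#' with normal(0, 1) magnitudes. Optional `hub_genes` respond on a denser
#' target set (`hub_density`), emulating broadly connected regulators whose
#' perturbation cascades widely.
#'
#' @param n_genes number of covered genes
#' @param density fraction of genes affected per perturbation, in (0, 1]
#' @param seed RNG seed (the model is fully deterministic given the seed)
#' @param gene_ids optional gene names (default `G1..Gn`)
#' @param hub_genes optional subset of `gene_ids` given denser responses
#' @param hub_density density for hub genes (default `min(1, 10 * density)`)
#' @return a [perturbation_model()]
#' @export
linear_response_model <- function(n_genes, density = 0.1, seed = 1,
                                  gene_ids = NULL, hub_genes = NULL,
                                  hub_density = min(1, 10 * density)) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  gene_ids <- gene_ids %||% paste0("G", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  if (!is.null(hub_genes) && !all(hub_genes %in% gene_ids)) {
    stop("hub_genes must be a subset of gene_ids")
  }
  mat <- withr::with_seed(seed, {
    m <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
    for (g in seq_len(n_genes)) {
      d <- if (gene_ids[g] %in% hub_genes) hub_density else density
      n_hit <- max(1L, round(d * n_genes))
      hit <- sample(n_genes, n_hit)
      m[g, hit] <- stats::rnorm(n_hit)
    }
    m
  })
  response_matrix_model(mat)
}

#' Perturbation impact of one gene
#'
#' Combines the number and magnitude of influenced genes as a thresholded L1
#' mass: `sum_j |delta_j| * 1[|delta_j| >= delta]` over responding genes
#' `j != gene`. Sign-invariant by construction.
#'
#' @param model a [perturbation_model()]
#' @param gene a covered gene
#' @param delta effect-magnitude threshold (default 0.1)
#' @return non-negative score
#' @export
perturbation_gene_score <- function(model, gene, delta = 0.1) {
  stopifnot(inherits(model, "perturbation_model"))
  if (!gene %in% model$covered_genes) stop("gene not covered by the model: ", gene)
  r <- model$respond(gene)
  r <- r[names(r) != gene]
  a <- abs(r)
  sum(a[a >= delta])
}

#' Panel-level perturbation score
#'
#' Scores every covered gene with [perturbation_gene_score()], rank-normalizes
#' the scores to `[0, 1]` across all covered genes (ties get their mid-rank),
#' and averages the normalized scores over the covered panel genes. Panel
#' genes outside the model's coverage are excluded and reported via
#' `coverage`.
#'
#' @param model a [perturbation_model()]
#' @param panel a [gene_panel()]
#' @param delta effect-magnitude threshold (default 0.1)
#' @return a `perturbation_summary` with `per_gene_score` (raw, covered panel
#'   genes), `normalized` (all covered genes), `panel_score`, `coverage`,
#'   `delta`
#' @export
panel_perturbation_score <- function(model, panel, delta = 0.1) {
  stopifnot(inherits(model, "perturbation_model"), inherits(panel, "gene_panel"))
  covered <- intersect(panel$genes, model$covered_genes)
  if (length(covered) == 0) {
    stop("no panel gene covered by the perturbation model (coverage 0/",
         length(panel), ")")
  }
  raw_all <- vapply(model$covered_genes, perturbation_gene_score,
                    numeric(1), model = model, delta = delta)
  n <- length(raw_all)
  normalized <- if (n == 1) stats::setNames(1, names(raw_all)) else {
    (rank(raw_all, ties.method = "average") - 1) / (n - 1)
  }
  structure(list(
    per_gene_score = raw_all[covered],
    normalized = normalized,
    panel_score = mean(normalized[covered]),
    coverage = length(covered) / length(panel),
    delta = delta, panel = panel$name
  ), class = "perturbation_summary")
}

#' @export
print.perturbation_summary <- function(x, ...) {
  cat("<perturbation_summary> '", x$panel, "': panel score = ",
      signif(x$panel_score, 4), " (coverage ", signif(x$coverage, 3),
      ", delta = ", x$delta, ")\n", sep = "")
  invisible(x)
}

#' @describeIn panel_perturbation_score per-covered-panel-gene tibble
#' @param x a `perturbation_summary`
#' @param ... unused
#' @export
tidy.perturbation_summary <- function(x, ...) {
  tibble::tibble(gene = names(x$per_gene_score),
                 score = unname(x$per_gene_score),
                 normalized = unname(x$normalized[names(x$per_gene_score)]))
}

#' @describeIn panel_perturbation_score one-row summary tibble
#' @export
glance.perturbation_summary <- function(x, ...) {
  tibble::tibble(panel_score = x$panel_score, coverage = x$coverage,
                 delta = x$delta)
}
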