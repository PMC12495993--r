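#' Build a k-nearest-neighbor spatial graph
#'
#' Neighbors by Euclidean distance in the plane, distance ties broken by lower
#' cell index (so duplicate coordinates are allowed). Weights are binary or
#' row-standardized (each cell's outgoing weights sum to 1, the usual choice
#' for Moran's I).
#'
#' @param coords n x 2 numeric matrix (or an [expression_dataset()] with
#'   coordinates)
#' @param k number of neighbors, `2 <= k < n` (default 6, the
#'   hexagonal-packing convention for tissue)
#' @param row_standardize row-standardize the weight matrix (default TRUE)
#' @return a `spatial_graph`: neighbor index matrix (n x k), sparse weight
#'   matrix `W`, `k`, `row_standardized`
#' @export
build_knn_graph <- function(coords, k = 6, row_standardize = TRUE) {
  if (inherits(coords, "expression_dataset")) {
    if (is.null(coords$coords)) stop("dataset has no coordinates")
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k < 1) stop("k must be at least 1")
  if (!all(is.finite(coords))) stop("non-finite coordinates")

  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nb <- t(vapply(seq_len(n), function(i) {
    order(d[i, ], seq_len(n))[seq_len(k)]   # tie-break: lower index first
  }, integer(k)))

  W <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nb)),
                            x = 1, dims = c(n, n))
  if (row_standardize) W <- W / k

  structure(list(neighbors = nb, W = W, k = k,
                 row_standardized = row_standardize, n = n),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph> ", x$n, " cells, k = ", x$k,
      if (x$row_standardized) ", row-standardized", "\n", sep = "")
  invisible(x)
}

#' Export a spatial graph as an edge-list TSV
#' @param graph a `spatial_graph`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_graph_tsv <- function(graph, path) {
  el <- Matrix::summary(graph$W)
  utils::write.table(
    data.frame(from = el$i, to = el$j, weight = el$x),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij`. Values near +1 indicate spatial clustering, near 0
#' spatial randomness, negative values dispersion. Zero-variance input returns
#' 0 with a `degenerate` attribute. Invariant to affine transforms of the
#' values.
#'
#' @param values numeric vector, one value per graph node
#' @param graph a [build_knn_graph()] result (or any object with a sparse
#'   weight matrix in `$W`)
#' @return Moran's I (numeric scalar; `attr(, "degenerate")` flags
#'   zero-variance input)
#' @export
morans_i <- function(values, graph) {
  W <- graph$W
  if (length(values) != nrow(W)) {
    stop("values length (", length(values), ") does not match graph size (",
         nrow(W), ")")
  }
  x <- values - mean(values)
  ss <- sum(x^2)
  if (ss == 0) {
    return(structure(0, degenerate = TRUE))
  }
  num <- as.numeric(Matrix::crossprod(x, W %*% x))
  structure((length(x) / sum(W)) * num / ss, degenerate = FALSE)
}

#' Spatial metrics for a panel
#'
#' Per gene: Moran's I of the lognorm expression over the spatial graph, and
#' the nearest-neighbor correlation — Pearson correlation between each cell's
#' expression and the mean expression over its k spatial neighbors.
#' Zero-variance genes are flagged degenerate (Moran's I reported as 0,
#' correlation as NA).
#'
#' @param ds an [expression_dataset()] with coordinates and a lognorm layer
#' @param panel a [gene_panel()]
#' @param graph a [build_knn_graph()] on the same cells (default: built from
#'   the dataset coordinates with `k = 6`)
#' @return a `spatial_result`: tibble (`gene`, `morans_i`, `nn_correlation`,
#'   `degenerate`) plus the list of degenerate genes
#' @export
spatial_metrics <- function(ds, panel, graph = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$coords)) stop("dataset has no coordinates")
  graph <- graph %||% build_knn_graph(ds$coords)
  if (graph$n != n_cells(ds)) stop("graph and dataset sizes differ")
  panel <- intersect_panel(panel, ds)
  x <- lognorm_submatrix(ds, panel$genes)

  # row-standardized neighbor mean, independent of the graph's weighting
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(graph$n), each = graph$k),
    j = as.vector(t(graph$neighbors)),
    x = 1 / graph$k, dims = c(graph$n, graph$n))
  nn_mean <- as.matrix(M %*% x)

  res <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::var(v) == 0) {
      tibble::tibble(gene = colnames(x)[j], morans_i = 0,
                     nn_correlation = NA_real_, degenerate = TRUE)
    } else {
      tibble::tibble(gene = colnames(x)[j],
                     morans_i = as.numeric(morans_i(v, graph)),
                     nn_correlation = stats::cor(v, nn_mean[, j]),
                     degenerate = FALSE)
    }
  })
  structure(list(per_gene = res,
                 degenerate_genes = res$gene[res$degenerate],
                 panel = panel$name),
            class = "spatial_result")
}

#' Nearest-neighbor expression correlation
#'
#' Convenience wrapper returning only the `gene`/`nn_correlation` columns of
#' [spatial_metrics()].
#'
#' @inheritParams spatial_metrics
#' @return tibble (`gene`, `nn_correlation`); degenerate genes are NA
#' @export
nearest_neighbor_correlation <- function(ds, panel, graph = NULL) {
  spatial_metrics(ds, panel, graph)$per_gene[, c("gene", "nn_correlation")]
}

#' @export
print.spatial_result <- function(x, ...) {
  cat("<spatial_result> '", x$panel, "': ", nrow(x$per_gene), " genes, median Moran's I = ",
      signif(stats::median(x$per_gene$morans_i[!x$per_gene$degenerate]), 4),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn spatial_metrics per-gene tibble
#' @param x a `spatial_result`
#' @param ... unused
#' @export
tidy.spatial_result <- function(x, ...) x$per_gene

#' @describeIn spatial_metrics one-row summary with the panel-level spatial
#'   score: mean Moran's I over non-degenerate genes mapped to `[0, 1]` via
#'   `(I + 1) / 2`
#' @export
glance.spatial_result <- function(x, ...) {
  ok <- !x$per_gene$degenerate
  tibble::tibble(
    mean_morans_i = mean(x$per_gene$morans_i[ok]),
    median_morans_i = stats::median(x$per_gene$morans_i[ok]),
    mean_nn_correlation = mean(x$per_gene$nn_correlation[ok]),
    spatial_score = (mean(x$per_gene$morans_i[ok]) + 1) / 2,
    n_degenerate = sum(!ok)
  )
}
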