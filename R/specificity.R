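#' Gene specificity scores
#'
#' For each panel gene and cell type, the gene specificity score (gsc) is the
#' log2 ratio of detection proportions between the target type and all other
#' types, with a pseudocount on both proportions:
#' `gsc(g, t) = log2((p_in + eps) / (p_out + eps))` where `p_in` is the
#' fraction of cells of type `t` with a nonzero count for `g` and `p_out` the
#' same fraction over all other cells. Positive values indicate higher
#' specificity for the target type.
#'
#' @param ds an [expression_dataset()] (raw counts are used — gsc is a
#'   detection-rate statistic)
#' @param panel a [gene_panel()]; genes absent from the dataset are dropped
#'   with a message
#' @param epsilon pseudocount added to both proportions (default 0.01)
#' @return a `specificity_matrix`: panel genes x cell types matrix of gsc
#'   values plus the `epsilon` used
#' @export
gene_specificity_matrix <- function(ds, panel, epsilon = 0.01) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (epsilon <= 0) stop("epsilon must be positive")
  types <- sort(unique(ds$cell_types))
  if (length(types) < 2) stop("gene specificity needs at least 2 cell types")
  panel <- intersect_panel(panel, ds)

  detected <- ds$counts[, panel$genes, drop = FALSE] > 0   # cells x genes logical
  n <- nrow(detected)
  vals <- vapply(types, function(t) {
    in_t <- ds$cell_types == t
    p_in <- Matrix::colSums(detected[in_t, , drop = FALSE]) / sum(in_t)
    p_out <- Matrix::colSums(detected[!in_t, , drop = FALSE]) / sum(!in_t)
    log2((p_in + epsilon) / (p_out + epsilon))
  }, numeric(length(panel$genes)))
  vals <- matrix(vals, nrow = length(panel$genes),
                 dimnames = list(panel$genes, types))

  structure(list(values = vals, epsilon = epsilon, panel = panel$name),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("<specificity_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cell types (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' @describeIn gene_specificity_matrix long-format tibble
#'   (`gene`, `cell_type`, `gsc`)
#' @param x a `specificity_matrix`
#' @param ... unused
#' @export
tidy.specificity_matrix <- function(x, ...) {
  as.data.frame.table(x$values, responseName = "gsc",
                      stringsAsFactors = FALSE) |>
    stats::setNames(c("gene", "cell_type", "gsc")) |>
    tibble::as_tibble()
}

#' Export a specificity matrix as TSV (genes x cell types)
#' @param sm a `specificity_matrix`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_specificity_tsv <- function(sm, path) {
  utils::write.table(data.frame(gene = rownames(sm$values), sm$values,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Panel entropy score
#'
#' A panel-level non-specificity summary of a gsc matrix, lower is better.
#' The matrix is hierarchically clustered on rows and columns (average
#' linkage, Euclidean distance), reordered by leaf order, and the spatial
#' autocorrelation of the reordered grid is measured by Moran's I with binary
#' rook adjacency between matrix entries. With `p0` the fraction of
#' non-specific entries (gsc <= 0), the score is the equally weighted convex
#' combination `0.5 * (1 - (I + 1) / 2) + 0.5 * p0`, in `[0, 1]`. `p0` is the
#' proportion of low-specificity genes: panel genes whose gsc is non-positive
#' for every cell type, i.e. genes not specific to any type. A clustered
#' (block-structured) specificity pattern gives high I and a low score; a
#' dispersed or largely non-specific pattern scores high.
#'
#' @param sm a `specificity_matrix` with at least 2 rows and 2 columns
#' @return an `entropy_result` with fields `entropy`, `grid_moran`,
#'   `nonspecific_fraction`, `row_order`, `col_order`, `degenerate`
#' @export
panel_entropy_score <- function(sm) {
  stopifnot(inherits(sm, "specificity_matrix"))
  v <- sm$values
  if (nrow(v) < 2 || ncol(v) < 2) {
    stop("panel entropy needs a gsc matrix with >= 2 rows and >= 2 columns")
  }
  row_order <- hclust_leaf_order(v)
  col_order <- hclust_leaf_order(t(v))
  reordered <- v[row_order, col_order, drop = FALSE]

  degenerate <- stats::var(as.vector(v)) == 0
  grid_moran <- if (degenerate) 0 else grid_morans_i(reordered)
  p0 <- mean(apply(v, 1, max) <= 0)
  entropy <- 0.5 * (1 - (grid_moran + 1) / 2) + 0.5 * p0

  structure(list(entropy = entropy, grid_moran = grid_moran,
                 nonspecific_fraction = p0,
                 row_order = row_order, col_order = col_order,
                 degenerate = degenerate),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("<entropy_result> entropy = ", signif(x$entropy, 4),
      " (grid Moran's I = ", signif(x$grid_moran, 4),
      ", nonspecific fraction = ", signif(x$nonspecific_fraction, 4),
      if (x$degenerate) ", degenerate", ")\n", sep = "")
  invisible(x)
}

#' @describeIn panel_entropy_score one-row tibble of the score and its terms
#' @param x an `entropy_result`
#' @param ... unused
#' @export
glance.entropy_result <- function(x, ...) {
  tibble::tibble(entropy = x$entropy, grid_moran = x$grid_moran,
                 nonspecific_fraction = x$nonspecific_fraction,
                 degenerate = x$degenerate)
}

# leaf order of average-linkage Euclidean clustering of the rows;
# stats::hclust breaks distance ties deterministically by merge index
hclust_leaf_order <- function(m) {
  stats::hclust(stats::dist(m), method = "average")$order
}

# Moran's I over an r x c grid with binary rook (4-neighbor) adjacency
grid_morans_i <- function(m) {
  r <- nrow(m); c <- ncol(m)
  x <- as.vector(m) - mean(m)                    # column-major: unit (i,j) -> i + (j-1) r
  ss <- sum(x^2)
  if (ss == 0) return(0)
  num <- 0; W <- 0
  # vertical neighbors (within columns) and horizontal (within rows),
  # each undirected pair counted twice as in the double-sum definition
  if (r > 1) {
    up <- as.vector(matrix(seq_len(r * c), r, c)[-r, , drop = FALSE])
    num <- num + 2 * sum(x[up] * x[up + 1L])
    W <- W + 2 * length(up)
  }
  if (c > 1) {
    left <- as.vector(matrix(seq_len(r * c), r, c)[, -c, drop = FALSE])
    num <- num + 2 * sum(x[left] * x[left + r])
    W <- W + 2 * length(left)
  }
  (length(x) / W) * num / ss
}

#' Normalized mutual information between two partitions
#'
#' Arithmetic-mean normalization: `NMI = 2 I(U; V) / (H(U) + H(V))`, using
#' natural-log entropies of the label distributions. Returns 1 when both
#' partitions are single clusters (zero entropy on both sides).
#'
#' @param u,v label vectors of equal length
#' @return NMI in `[0, 1]`
#' @export
nmi <- function(u, v) {
  stopifnot(length(u) == length(v))
  tab <- table(u, v)
  n <- sum(tab)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu + hv == 0) return(1)
  pj <- tab / n
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pu, pv)[nz]))
  2 * mi / (hu + hv)
}

#' Variation recovery via normalized mutual information
#'
#' Measures how much of the annotated transcriptional structure a panel
#' retains: cells are clustered with k-means (10 restarts, seeded) on the top
#' `min(20, n_panel_genes - 1)` principal components of the panel-gene lognorm
#' submatrix, and the clustering is compared with the annotated cell-type
#' labels by [nmi()].
#'
#' @param ds an [expression_dataset()] with a lognorm layer
#' @param panel a [gene_panel()] with >= 2 genes in the dataset
#' @param k number of clusters (default: number of cell types)
#' @param seed RNG seed for the k-means restarts
#' @return NMI in `[0, 1]`
#' @export
variation_recovery_nmi <- function(ds, panel, k = NULL, seed = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  panel <- intersect_panel(panel, ds)
  if (length(panel) < 2) stop("variation recovery needs >= 2 panel genes in the dataset")
  k <- k %||% length(unique(ds$cell_types))
  if (k < 2) stop("k must be >= 2")

  x <- lognorm_submatrix(ds, panel$genes)
  npc <- min(20, ncol(x) - 1, nrow(x) - 1)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = npc)$x
  cl <- withr::with_seed(seed,
    stats::kmeans(pcs, centers = k, nstart = 10, iter.max = 50)$cluster)
  nmi(ds$cell_types, cl)
}

#' Cell-type classification performance of a panel
#'
#' Stratified k-fold cross-validation of a random forest (500 trees) on the
#' panel-gene lognorm submatrix. Balanced accuracy is the unweighted mean of
#' per-class recall pooled over folds, robust to cell-type imbalance; per-fold
#' balanced accuracies are kept for error bars.
#'
#' @param ds an [expression_dataset()] with a lognorm layer
#' @param panel a [gene_panel()]
#' @param n_folds number of cross-validation folds (default 5); every cell
#'   type must have at least this many cells
#' @param seed RNG seed for fold assignment and forests
#' @param num_trees forest size (default 500)
#' @return a `classification_result` with `balanced_accuracy`,
#'   `per_type_accuracy`, `fold_scores`, `seed`
#' @export
classification_performance <- function(ds, panel, n_folds = 5, seed = 1,
                                       num_trees = 500) {
  stopifnot(inherits(ds, "expression_dataset"))
  panel <- intersect_panel(panel, ds)
  y <- factor(ds$cell_types)
  small <- table(y) < n_folds
  if (any(small)) {
    stop("cell type(s) with fewer than n_folds cells (",
         paste(names(which(small)), collapse = ", "),
         "); lower n_folds or filter the dataset")
  }
  x <- lognorm_submatrix(ds, panel$genes)

  folds <- withr::with_seed(seed, stratified_folds(y, n_folds))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_scores <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    fit <- ranger::ranger(
      x = x[!test, , drop = FALSE], y = y[!test],
      num.trees = num_trees, seed = seed + f, num.threads = 1
    )
    pred[test] <- stats::predict(fit, data = x[test, , drop = FALSE],
                                 num.threads = 1)$predictions
    fold_scores[f] <- balanced_accuracy(y[test], pred[test])
  }
  per_type <- per_class_recall(y, pred)
  structure(list(balanced_accuracy = mean(per_type),
                 per_type_accuracy = per_type,
                 fold_scores = fold_scores, seed = seed),
            class = "classification_result")
}

stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

per_class_recall <- function(truth, pred) {
  vapply(levels(truth),
         function(lev) mean(pred[truth == lev] == lev, na.rm = TRUE),
         numeric(1))
}

balanced_accuracy <- function(truth, pred) {
  mean(per_class_recall(droplevels(factor(truth)), pred))
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> balanced accuracy = ",
      signif(x$balanced_accuracy, 4), " (", length(x$fold_scores),
      " folds)\n", sep = "")
  invisible(x)
}

#' @describeIn classification_performance per-cell-type recall tibble
#' @param x a `classification_result`
#' @param ... unused
#' @export
tidy.classification_result <- function(x, ...) {
  tibble::tibble(cell_type = names(x$per_type_accuracy),
                 recall = unname(x$per_type_accuracy))
}

#' @describeIn classification_performance one-row summary tibble
#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(balanced_accuracy = x$balanced_accuracy,
                 se = stats::sd(x$fold_scores) / sqrt(length(x$fold_scores)),
                 n_folds = length(x$fold_scores))
}
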