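#' Construct an expression dataset
#'
#' The central container scored by every panel metric: a cells x genes count
#' matrix with per-cell type labels, optional planar spatial coordinates and an
#' optional log-normalized expression layer.
#'
#' @param counts cells x genes matrix of non-negative integer counts (dense or
#'   sparse). Row names are cell identifiers, column names gene symbols; both
#'   must be unique.
#' @param cell_types character or factor of cell-type labels, one per cell
#'   (recycled names are matched to `rownames(counts)` when named).
#' @param coords optional numeric matrix or data frame with one `(x, y)` pair
#'   per cell.
#' @param lognorm optional cells x genes matrix of log-normalized expression
#'   with the same dimensions and dimnames as `counts`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts`, `cell_ids`, `gene_ids`, `cell_types`, `coords`, `lognorm`.
#' @export
expression_dataset <- function(counts, cell_types, coords = NULL, lognorm = NULL) {
  counts <- as_count_matrix(counts)
  cell_ids <- rownames(counts)
  gene_ids <- colnames(counts)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("`counts` must have cell identifiers as rownames and gene symbols as colnames")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene symbols")
  if (any(counts@x < 0)) stop("negative counts")

  cell_types <- as.character(cell_types)
  if (length(cell_types) != nrow(counts)) {
    stop("need exactly one cell-type label per cell (", nrow(counts), " cells, ",
         length(cell_types), " labels)")
  }
  if (anyNA(cell_types)) stop("unlabeled cell: every cell needs a cell-type label")
  names(cell_types) <- cell_ids

  if (!is.null(coords)) {
    coords <- as.matrix(coords[, c("x", "y"), drop = FALSE])
    storage.mode(coords) <- "double"
    if (nrow(coords) != nrow(counts)) stop("need one coordinate pair per cell")
    if (!all(is.finite(coords))) stop("non-finite coordinates")
    rownames(coords) <- cell_ids
  }
  if (!is.null(lognorm)) {
    lognorm <- as(as(Matrix::Matrix(lognorm, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    if (!identical(dim(lognorm), dim(counts))) stop("lognorm must match counts dimensions")
    dimnames(lognorm) <- dimnames(counts)
  }

  structure(
    list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
         cell_types = cell_types, coords = coords, lognorm = lognorm),
    class = "expression_dataset"
  )
}

as_count_matrix <- function(m) {
  m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  as(as(m, "generalMatrix"), "CsparseMatrix")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", length(x$cell_ids), " cells x ", length(x$gene_ids),
      " genes, ", length(unique(x$cell_types)), " cell types",
      if (!is.null(x$coords)) ", with coordinates",
      if (!is.null(x$lognorm)) ", log-normalized", "\n", sep = "")
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds an [expression_dataset()]
#' @return integer scalar
#' @export
n_cells <- function(ds) length(ds$cell_ids)

#' @rdname n_cells
#' @export
n_genes <- function(ds) length(ds$gene_ids)

#' Load an expression dataset from disk
#'
#' Reads a count matrix (MatrixMarket triplet or dense CSV, auto-detected from
#' the file extension), a cell-type label table, and optional spatial
#' coordinates. MatrixMarket files are stored genes x cells (the 10x
#' convention) and transposed to cells x genes on load; dense CSV has a
#' `cell_id` first column and one column per gene.
#'
#' @param matrix_path path to `.mtx` or `.csv` counts.
#' @param genes_path,cells_path identifier lists (one per line), required for
#'   `.mtx` input.
#' @param labels_path CSV with columns `cell_id,label`; every cell in the
#'   matrix must appear.
#' @param coords_path optional CSV with columns `cell_id,x,y`.
#' @return an [expression_dataset()]
#' @export
load_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                            labels_path, coords_path = NULL) {
  ext <- tolower(tools::file_ext(matrix_path))
  if (ext == "mtx") {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("MatrixMarket input needs `genes_path` and `cells_path`")
    }
    m <- Matrix::readMM(matrix_path)           # genes x cells on disk
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("dimension mismatch between matrix and identifier lists")
    }
    counts <- Matrix::t(m)
    dimnames(counts) <- list(cells, genes)
  } else if (ext == "csv") {
    df <- utils::read.csv(matrix_path, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df[[1]])
  } else {
    stop("unsupported matrix format: .", ext)
  }

  labels <- utils::read.csv(labels_path, check.names = FALSE)
  if (!all(c("cell_id", "label") %in% names(labels))) {
    stop("labels file needs columns cell_id,label")
  }
  extra <- setdiff(labels$cell_id, rownames(counts))
  if (length(extra)) stop("cell_id in labels absent from matrix: ", extra[1])
  idx <- match(rownames(counts), labels$cell_id)
  if (anyNA(idx)) {
    stop("unlabeled cell: ", rownames(counts)[which(is.na(idx))[1]])
  }
  cell_types <- labels$label[idx]

  coords <- NULL
  if (!is.null(coords_path)) {
    cdf <- utils::read.csv(coords_path, check.names = FALSE)
    cidx <- match(rownames(counts), cdf$cell_id)
    if (anyNA(cidx)) stop("cell missing from coordinates: ",
                          rownames(counts)[which(is.na(cidx))[1]])
    coords <- cdf[cidx, c("x", "y")]
  }

  expression_dataset(counts, cell_types, coords = coords)
}

#' Write an expression dataset to a directory
#'
#' Emits `matrix.mtx` (genes x cells) + `genes.txt` + `cells.txt`, or a dense
#' `matrix.csv`, plus `labels.csv` and, when present, `coords.csv` — the exact
#' formats [load_expression()] reads.
#'
#' @param ds an [expression_dataset()]
#' @param dir output directory (created if needed)
#' @param format `"mtx"` or `"csv"`
#' @return invisibly, a named character vector of file paths written
#' @export
save_expression <- function(ds, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  if (format == "mtx") {
    mp <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(Matrix::t(ds$counts), mp)
    writeLines(ds$gene_ids, file.path(dir, "genes.txt"))
    writeLines(ds$cell_ids, file.path(dir, "cells.txt"))
    paths <- c(matrix = mp, genes = file.path(dir, "genes.txt"),
               cells = file.path(dir, "cells.txt"))
  } else {
    mp <- file.path(dir, "matrix.csv")
    df <- data.frame(cell_id = ds$cell_ids, as.matrix(ds$counts),
                     check.names = FALSE)
    utils::write.csv(df, mp, row.names = FALSE)
    paths <- c(matrix = mp)
  }
  lp <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(cell_id = ds$cell_ids, label = unname(ds$cell_types)),
                   lp, row.names = FALSE)
  paths <- c(paths, labels = lp)
  if (!is.null(ds$coords)) {
    cp <- file.path(dir, "coords.csv")
    utils::write.csv(data.frame(cell_id = ds$cell_ids,
                                x = ds$coords[, 1], y = ds$coords[, 2]),
                     cp, row.names = FALSE)
    paths <- c(paths, coords = cp)
  }
  invisible(paths)
}

#' Filtering thresholds for quality control
#'
#' Cells, genes and cell types below these totals are removed by
#' [filter_dataset()]. "Less than" is strict: items exactly at a threshold are
#' kept.
#'
#' @param min_gene_total minimum total counts per gene (default 10)
#' @param min_cell_total minimum total counts per cell (default 200)
#' @param min_cells_per_type minimum cells per cell type (default 10)
#' @return a `filter_thresholds` list
#' @export
filter_thresholds <- function(min_gene_total = 10, min_cell_total = 200,
                              min_cells_per_type = 10) {
  stopifnot(min_gene_total >= 0, min_cell_total >= 0, min_cells_per_type >= 0)
  structure(list(min_gene_total = min_gene_total,
                 min_cell_total = min_cell_total,
                 min_cells_per_type = min_cells_per_type),
            class = "filter_thresholds")
}

#' Apply quality-control filters
#'
#' Removes, in order: genes with total counts below `min_gene_total`, then
#' cells with total counts below `min_cell_total`, then all cells of any cell
#' type left with fewer than `min_cells_per_type` cells. Totals are recomputed
#' after each step. The removal counts are attached as a tibble in
#' `attr(, "filter_log")`.
#'
#' @param ds an [expression_dataset()]
#' @param thresholds a [filter_thresholds()]
#' @return the filtered `expression_dataset`
#' @export
filter_dataset <- function(ds, thresholds = filter_thresholds()) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(thresholds, "filter_thresholds"))
  counts <- ds$counts
  types <- ds$cell_types
  coords <- ds$coords

  keep_g <- Matrix::colSums(counts) >= thresholds$min_gene_total
  removed_genes <- sum(!keep_g)
  counts <- counts[, keep_g, drop = FALSE]

  keep_c <- Matrix::rowSums(counts) >= thresholds$min_cell_total
  removed_cells <- sum(!keep_c)
  counts <- counts[keep_c, , drop = FALSE]
  types <- types[keep_c]
  if (!is.null(coords)) coords <- coords[keep_c, , drop = FALSE]

  tab <- table(types)
  keep_t <- types %in% names(tab)[tab >= thresholds$min_cells_per_type]
  removed_type_cells <- sum(!keep_t)
  counts <- counts[keep_t, , drop = FALSE]
  types <- types[keep_t]
  if (!is.null(coords)) coords <- coords[keep_t, , drop = FALSE]

  if (nrow(counts) == 0 || ncol(counts) == 0) {
    stop("empty dataset after filtering")
  }

  out <- expression_dataset(counts, types, coords = coords)
  attr(out, "filter_log") <- tibble::tibble(
    step = c("genes", "cells", "cell_types"),
    removed = c(removed_genes, removed_cells, removed_type_cells),
    kept = c(ncol(counts), nrow(counts), length(unique(types)))
  )
  out
}

#' Log-normalize counts
#'
#' Counts-per-`scale` followed by natural log1p, the single-cell convention:
#' `lognorm[i, g] = ln(1 + scale * counts[i, g] / total_i)`. Raw counts are
#' kept unchanged; correlation and clustering metrics operate on this layer.
#'
#' @param ds an [expression_dataset()]
#' @param scale library-size scaling constant (default `1e4`)
#' @return the dataset with its `lognorm` layer filled in
#' @export
normalize_counts <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "expression_dataset"), scale > 0)
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals == 0)) {
    stop("cell with zero total counts; run filter_dataset() first")
  }
  # dgCMatrix is column-compressed: @x entries map to row indices @i
  ln <- ds$counts
  ln@x <- log1p(scale * ln@x / totals[ln@i + 1L])
  ds$lognorm <- ln
  ds
}

#' Extract a dense lognorm submatrix for a panel
#' @noRd
lognorm_submatrix <- function(ds, genes) {
  if (is.null(ds$lognorm)) {
    stop("dataset has no lognorm layer; call normalize_counts() first")
  }
  as.matrix(ds$lognorm[, genes, drop = FALSE])
}
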