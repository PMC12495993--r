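# shared fixtures, built in code and memoized per test run

.fixture_env <- new.env(parent = emptyenv())

# default simulated tissue: 3 types x 100 cells, markers + housekeeping block
# + noise background, spatial blobs; filtered lightly (the simulator does not
# produce empty cells at these means) and log-normalized
sim_fixture <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(seed = seed)
    ds <- simulate_dataset(cfg)
    ds <- filter_dataset(ds, filter_thresholds(min_gene_total = 1,
                                               min_cell_total = 1,
                                               min_cells_per_type = 1))
    .fixture_env[[key]] <- list(cfg = cfg, ds = normalize_counts(ds))
  }
  .fixture_env[[key]]
}

# tiny deterministic dataset for exact arithmetic checks
tiny_dataset <- function(with_coords = FALSE) {
  counts <- matrix(
    c(5, 0, 2, 1,
      0, 3, 0, 4,
      6, 1, 3, 0,
      0, 0, 1, 2,
      2, 5, 0, 1,
      1, 0, 4, 3),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
  coords <- if (with_coords) {
    cbind(x = c(0, 1, 0.5, 10, 11, 10.5), y = c(0, 0, 1, 10, 10, 11))
  }
  expression_dataset(counts, rep(c("A", "B"), each = 3), coords = coords)
}

# specificity matrix built directly from a value matrix
sm_from_values <- function(values, epsilon = 0.01) {
  structure(list(values = values, epsilon = epsilon, panel = "manual"),
            class = "specificity_matrix")
}

# brute-force Moran's I by explicit double loop over a dense weight matrix
moran_brute <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

# rook-adjacency binary weight matrix of an r x c grid, column-major units
rook_grid_W <- function(r, c) {
  n <- r * c
  W <- matrix(0, n, n)
  idx <- function(i, j) i + (j - 1) * r
  for (i in seq_len(r)) for (j in seq_len(c)) {
    if (i < r) W[idx(i, j), idx(i + 1, j)] <- W[idx(i + 1, j), idx(i, j)] <- 1
    if (j < c) W[idx(i, j), idx(i, j + 1)] <- W[idx(i, j + 1), idx(i, j)] <- 1
  }
  W
}

graph_from_W <- function(W) list(W = Matrix::Matrix(W, sparse = TRUE))
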