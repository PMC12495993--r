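#' Simulation configuration
#'
#' Parameters of the synthetic single-cell/spatial generator. The defaults
#' describe a small but structured tissue: 3 cell types of 100 cells, 5
#' markers per type at 4-fold elevation over a baseline mean of 1 count, a
#' 10-gene housekeeping block sharing one latent per-cell factor (inducing the
#' co-expression that makes stably-expressed-gene panels redundant), 200
#' independent noise genes (a background wide enough for over-representation
#' tests to have power), negative-binomial overdispersion 0.5, 30%
#' library-size coefficient of variation, and cell types placed at distinct
#' spatial blob centers.
#'
#' @param n_types number of cell types (default 3)
#' @param cells_per_type cells per type (default 100)
#' @param markers_per_type marker genes per type (default 5)
#' @param n_housekeeping correlated housekeeping genes (default 10)
#' @param n_noise independent noise genes (default 200)
#' @param marker_fold mean fold-elevation of a marker in its own type,
#'   `> 1` (default 4)
#' @param base_mean baseline negative-binomial mean (default 1)
#' @param dispersion NB dispersion; `size = 1 / dispersion` (default 0.5)
#' @param spatial_blob_sd Gaussian scatter of cells around their type's blob
#'   center, in the same arbitrary units as the unit-spaced centers
#'   (default 1)
#' @param library_size_cv coefficient of variation of the log-normal per-cell
#'   library-size multipliers (default 0.3)
#' @param seed RNG seed
#' @return a `sim_config`
#' @export
sim_config <- function(n_types = 3, cells_per_type = 100, markers_per_type = 5,
                       n_housekeeping = 10, n_noise = 200, marker_fold = 4,
                       base_mean = 1, dispersion = 0.5, spatial_blob_sd = 1,
                       library_size_cv = 0.3, seed = 1) {
  stopifnot(n_types >= 2, cells_per_type >= 1, markers_per_type >= 1,
            n_housekeeping >= 0, n_noise >= 0, marker_fold > 1,
            base_mean > 0, dispersion > 0, spatial_blob_sd > 0,
            library_size_cv >= 0)
  structure(list(n_types = n_types, cells_per_type = cells_per_type,
                 markers_per_type = markers_per_type,
                 n_housekeeping = n_housekeeping, n_noise = n_noise,
                 marker_fold = marker_fold, base_mean = base_mean,
                 dispersion = dispersion, spatial_blob_sd = spatial_blob_sd,
                 library_size_cv = library_size_cv, seed = seed),
            class = "sim_config")
}

#' Simulate a structured single-cell spatial dataset
#'
#' Negative-binomial counts with the statistical structure every panel metric
#' assumes: cell-type markers (mean `base_mean * marker_fold` in their own
#' type, `base_mean` elsewhere — hence higher detection rates and positive
#' specificity scores for marker/type pairs), a housekeeping block sharing one
#' log-normal latent factor per cell (pairwise-correlated, type-independent),
#' independent noise genes, log-normal library-size multipliers, and cell
#' types scattered around distinct 2D blob centers so that marker expression
#' is spatially clustered. Gene names encode the ground truth:
#' `M{type}_{i}` (marker i of type `type`), `HK_{i}`, `NZ_{i}`.
#'
#' @param cfg a [sim_config()]
#' @return an [expression_dataset()] of raw counts with coordinates (apply
#'   [filter_dataset()] and [normalize_counts()] before scoring)
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n_cells <- cfg$n_types * cfg$cells_per_type
    types <- rep(paste0("T", seq_len(cfg$n_types)), each = cfg$cells_per_type)

    marker_names <- unlist(lapply(seq_len(cfg$n_types), function(t) {
      paste0("M", t, "_", seq_len(cfg$markers_per_type))
    }))
    hk_names <- if (cfg$n_housekeeping) paste0("HK_", seq_len(cfg$n_housekeeping)) else character(0)
    nz_names <- if (cfg$n_noise) paste0("NZ_", seq_len(cfg$n_noise)) else character(0)
    genes <- c(marker_names, hk_names, nz_names)
    n_genes <- length(genes)

    # per-cell multipliers: library size and the shared housekeeping factor
    cv <- cfg$library_size_cv
    sdlog <- sqrt(log(1 + cv^2))
    libsize <- if (cv > 0) stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog) else rep(1, n_cells)
    hk_factor <- stats::rlnorm(n_cells, -0.5 * 0.75^2, 0.75)

    mu <- matrix(cfg$base_mean, n_cells, n_genes,
                 dimnames = list(paste0("C", seq_len(n_cells)), genes))
    for (t in seq_len(cfg$n_types)) {
      own <- types == paste0("T", t)
      cols <- paste0("M", t, "_", seq_len(cfg$markers_per_type))
      mu[own, cols] <- cfg$base_mean * cfg$marker_fold
    }
    if (length(hk_names)) {
      mu[, hk_names] <- cfg$base_mean * 2 * hk_factor
    }
    mu <- mu * libsize

    counts <- matrix(
      stats::rnbinom(n_cells * n_genes, mu = as.vector(mu),
                     size = 1 / cfg$dispersion),
      n_cells, n_genes, dimnames = dimnames(mu))

    # cell types at distinct blob centers on a circle of radius 5
    angles <- 2 * pi * (seq_len(cfg$n_types) - 1) / cfg$n_types
    centers <- cbind(5 * cos(angles), 5 * sin(angles))
    type_idx <- rep(seq_len(cfg$n_types), each = cfg$cells_per_type)
    coords <- centers[type_idx, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_cells, sd = cfg$spatial_blob_sd), n_cells, 2)
    colnames(coords) <- c("x", "y")

    expression_dataset(counts, types, coords = coords)
  })
}

#' Simulate a pathway database aligned to the simulated markers
#'
#' One pathway per simulated cell type containing its markers plus sampled
#' filler genes, one housekeeping pathway, and `n_extra` random pathways —
#' giving enrichment tests a known ground truth.
#'
#' @param cfg the [sim_config()] used for [simulate_dataset()]
#' @param n_extra random pathways (default 5)
#' @param n_filler filler genes added to each marker pathway (default 5)
#' @param seed RNG seed; defaults to a substream offset from `cfg$seed` so
#'   that the database draws are decoupled from panel down-sampling draws
#' @return a [pathway_database()]
#' @export
simulate_pathway_db <- function(cfg = sim_config(), n_extra = 5, n_filler = 5,
                                seed = cfg$seed + 1001L) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(seed, {
    hk <- if (cfg$n_housekeeping) paste0("HK_", seq_len(cfg$n_housekeeping)) else character(0)
    nz <- if (cfg$n_noise) paste0("NZ_", seq_len(cfg$n_noise)) else character(0)
    all_genes <- c(unlist(lapply(seq_len(cfg$n_types), function(t) {
      paste0("M", t, "_", seq_len(cfg$markers_per_type))
    })), hk, nz)

    pws <- list()
    for (t in seq_len(cfg$n_types)) {
      markers <- paste0("M", t, "_", seq_len(cfg$markers_per_type))
      filler <- sample(nz, min(n_filler, length(nz)))
      pws[[paste0("TYPE", t, "_PROGRAM")]] <- c(markers, filler)
    }
    if (length(hk)) pws[["HOUSEKEEPING"]] <- hk
    for (i in seq_len(n_extra)) {
      pws[[paste0("RANDOM_", i)]] <-
        sample(all_genes, sample(5:min(15, length(all_genes)), 1))
    }
    pathway_database(pws, source = "simulated")
  })
}

#' Simulate a ligand/receptor annotation table
#'
#' A random `lr_fraction` of the simulated genes is split evenly between the
#' ligand and receptor categories.
#'
#' @param cfg the [sim_config()] used for [simulate_dataset()]
#' @param lr_fraction fraction of genes annotated, in `[0, 1]` (default 0.2)
#' @param seed RNG seed; defaults to a substream offset from `cfg$seed`,
#'   independent of the database and panel draws
#' @return tibble (`gene`, `category`)
#' @export
simulate_lr_table <- function(cfg = sim_config(), lr_fraction = 0.2,
                              seed = cfg$seed + 2002L) {
  stopifnot(inherits(cfg, "sim_config"), lr_fraction >= 0, lr_fraction <= 1)
  withr::with_seed(seed, {
    hk <- if (cfg$n_housekeeping) paste0("HK_", seq_len(cfg$n_housekeeping)) else character(0)
    nz <- if (cfg$n_noise) paste0("NZ_", seq_len(cfg$n_noise)) else character(0)
    all_genes <- c(unlist(lapply(seq_len(cfg$n_types), function(t) {
      paste0("M", t, "_", seq_len(cfg$markers_per_type))
    })), hk, nz)
    n_lr <- round(lr_fraction * length(all_genes))
    if (n_lr == 0) {
      return(tibble::tibble(gene = character(0), category = character(0)))
    }
    chosen <- sample(all_genes, n_lr)
    half <- ceiling(n_lr / 2)
    tibble::tibble(
      gene = chosen,
      category = c(rep("ligand", half), rep("receptor", n_lr - half))
    )
  })
}

#' Ground-truth panels of a simulated dataset
#'
#' Convenience selectors keyed on the simulator's gene-naming scheme.
#'
#' @param ds a dataset from [simulate_dataset()]
#' @param kind `"marker"`, `"housekeeping"` or `"noise"`
#' @param size optional panel size (default: all genes of that kind)
#' @param seed seed for down-sampling when `size` is given
#' @return a [gene_panel()]
#' @export
simulated_panel <- function(ds, kind = c("marker", "housekeeping", "noise"),
                            size = NULL, seed = 1) {
  kind <- match.arg(kind)
  prefix <- switch(kind, marker = "^M[0-9]+_", housekeeping = "^HK_",
                   noise = "^NZ_")
  genes <- grep(prefix, ds$gene_ids, value = TRUE)
  if (!is.null(size)) {
    if (size > length(genes)) stop("not enough ", kind, " genes")
    genes <- withr::with_seed(seed, sample(genes, size))
  }
  gene_panel(genes, name = kind)
}
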