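#' Genetic-algorithm configuration
#'
#' Defaults follow the published setup: a population of 50 random panels of
#' 200 genes each, refined for up to 5000 iterations. Selection is elitist
#' (the top `elite_fraction` of panels survive unchanged, so the best score
#' never decreases) and variation is mutation-only by default: each offspring
#' replaces `mutation_genes` uniformly chosen genes of an elite parent with
#' genes drawn from the candidate pool. Single-point set-crossover between two
#' elites can be enabled with `crossover_prob`.
#'
#' @param candidate_pool character vector of genes panels are drawn from
#' @param panel_size genes per panel (default 200)
#' @param population number of panels (default 50)
#' @param max_iters iteration budget (default 5000)
#' @param elite_fraction fraction of panels kept unchanged, in (0, 1)
#'   (default 0.2)
#' @param mutation_genes genes replaced per mutation
#'   (default `max(1, round(0.05 * panel_size))`)
#' @param crossover_prob probability an offspring is produced by crossover of
#'   two elites before mutation (default 0)
#' @param patience iterations without improvement `> tol` before stopping
#'   (default 200)
#' @param tol minimal improvement counted as progress (default 1e-6)
#' @param seed RNG seed
#' @return a `ga_config`
#' @export
ga_config <- function(candidate_pool, panel_size = 200, population = 50,
                      max_iters = 5000, elite_fraction = 0.2,
                      mutation_genes = max(1, round(0.05 * panel_size)),
                      crossover_prob = 0, patience = 200, tol = 1e-6,
                      seed = 1) {
  candidate_pool <- unique(as.character(candidate_pool))
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    stop("elite_fraction must be in (0, 1)")
  }
  if (panel_size > length(candidate_pool)) {
    stop("panel_size exceeds the candidate pool size")
  }
  if (mutation_genes < 1) stop("mutation_genes must be >= 1")
  if (crossover_prob < 0 || crossover_prob > 1) stop("crossover_prob in [0, 1]")
  stopifnot(population >= 2, max_iters >= 1, patience >= 1, tol >= 0)
  structure(list(candidate_pool = candidate_pool, panel_size = panel_size,
                 population = population, max_iters = max_iters,
                 elite_fraction = elite_fraction,
                 mutation_genes = mutation_genes,
                 crossover_prob = crossover_prob, patience = patience,
                 tol = tol, seed = seed),
            class = "ga_config")
}

#' Mutate a panel
#'
#' Replaces `m` uniformly chosen panel genes with `m` uniformly chosen genes
#' from `pool` outside the panel; panel size and uniqueness are preserved.
#' When fewer than `m` replacement genes exist, as many as possible are
#' replaced with a warning. Uses the current RNG state (seed externally for
#' determinism).
#'
#' @param panel a [gene_panel()] or character vector
#' @param pool candidate gene pool
#' @param m number of genes to replace
#' @return a mutated [gene_panel()]
#' @export
mutate_panel <- function(panel, pool, m) {
  genes <- if (inherits(panel, "gene_panel")) panel$genes else as.character(panel)
  name <- if (inherits(panel, "gene_panel")) panel$name else "panel"
  if (m < 1 || m > length(genes)) stop("m must be in [1, panel size]")
  outside <- setdiff(pool, genes)
  if (length(outside) == 0) stop("pool \\ panel is empty; nothing to mutate with")
  if (length(outside) < m) {
    warning("pool \\ panel smaller than m; replacing ", length(outside),
            " gene(s)")
    m <- length(outside)
  }
  drop <- sample(length(genes), m)
  add <- sample(outside, m)
  genes[drop] <- add
  gene_panel(genes, name = name)
}

# single-point set-crossover: take a prefix of one parent, fill from the
# other, then from the pool if still short
crossover_panels <- function(a, b, size, pool) {
  cut <- sample(size - 1L, 1L)
  child <- unique(c(a[seq_len(cut)], setdiff(b, a[seq_len(cut)])))
  if (length(child) > size) child <- child[seq_len(size)]
  if (length(child) < size) {
    child <- c(child, sample(setdiff(pool, child), size - length(child)))
  }
  child
}

#' Optimize a gene panel by genetic algorithm
#'
#' Maximizes a panel objective (by default [ga_objective()] on the supplied
#' dataset) over duplicate-free panels of fixed size drawn from the candidate
#' pool. Each iteration scores all panels (memoized on panel content), copies
#' the elite fraction unchanged, and refills the population with mutated
#' (optionally crossed-over) elites. Stops at `max_iters` or once the best
#' score has not improved by more than `tol` for `patience` consecutive
#' iterations. Elitism guarantees a non-decreasing best trajectory; the run is
#' deterministic given the config seed.
#'
#' @param ga a [ga_config()]
#' @param ds dataset used by the default objective (ignored when `objective`
#'   is supplied)
#' @param db,graph optional inputs forwarded to [ga_objective()]
#' @param config a [score_config()] for the default objective
#' @param objective optional function(character gene vector) -> numeric in
#'   `[0, 1]`; any such function may be injected
#' @param memoize cache objective values by panel content (default TRUE;
#'   affects runtime only, never results)
#' @return a `ga_state`: final population and objectives, `best_panel`,
#'   `best_trajectory`, `mean_trajectory`, `iterations_run`, `converged`,
#'   `seed`, `n_evaluations`
#' @export
optimize_panel <- function(ga, ds = NULL, db = NULL, graph = NULL,
                           config = score_config(), objective = NULL,
                           memoize = TRUE) {
  stopifnot(inherits(ga, "ga_config"))
  if (is.null(objective)) {
    if (is.null(ds)) stop("supply a dataset or an objective function")
    if (!is.null(ds$coords) && is.null(graph)) {
      graph <- build_knn_graph(ds$coords, k = config$k_neighbors)
    }
    objective <- function(genes) {
      ga_objective(ds, gene_panel(genes, name = "candidate"), db = db,
                   graph = graph, config = config)
    }
  }

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score_panel <- function(genes) {
    key <- paste(sort(genes), collapse = "\r")
    if (memoize && !is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    val <- objective(genes)
    if (memoize) cache[[key]] <- val
    val
  }

  withr::with_seed(ga$seed, {
    pop <- replicate(ga$population,
                     sample(ga$candidate_pool, ga$panel_size),
                     simplify = FALSE)
    n_elite <- ceiling(ga$elite_fraction * ga$population)
    best_traj <- mean_traj <- numeric(0)
    stall <- 0L
    best_prev <- -Inf
    iter <- 0L
    converged <- FALSE

    while (iter < ga$max_iters) {
      iter <- iter + 1L
      scores <- vapply(pop, score_panel, numeric(1))
      ord <- order(scores, decreasing = TRUE)
      pop <- pop[ord]
      scores <- scores[ord]
      best_traj[iter] <- scores[1]
      mean_traj[iter] <- mean(scores)

      if (scores[1] - best_prev > ga$tol) {
        stall <- 0L
        best_prev <- max(best_prev, scores[1])
      } else {
        stall <- stall + 1L
      }
      if (stall >= ga$patience) { converged <- TRUE; break }
      if (iter == ga$max_iters) break

      offspring <- lapply(seq_len(ga$population - n_elite), function(i) {
        parent <- pop[[sample(n_elite, 1)]]
        if (ga$crossover_prob > 0 && stats::runif(1) < ga$crossover_prob &&
            n_elite >= 2) {
          other <- pop[[sample(n_elite, 1)]]
          parent <- crossover_panels(parent, other, ga$panel_size,
                                     ga$candidate_pool)
        }
        mutate_panel(parent, ga$candidate_pool, ga$mutation_genes)$genes
      })
      pop <- c(pop[seq_len(n_elite)], offspring)
    }

    final_scores <- vapply(pop, score_panel, numeric(1))
    best_idx <- which.max(final_scores)
    structure(list(
      population = pop, objectives = final_scores,
      best_panel = gene_panel(pop[[best_idx]], name = "optimized"),
      best_objective = final_scores[best_idx],
      best_trajectory = best_traj, mean_trajectory = mean_traj,
      iterations_run = iter, converged = converged,
      seed = ga$seed, n_evaluations = n_eval, config = ga
    ), class = "ga_state")
  })
}

#' @export
print.ga_state <- function(x, ...) {
  cat("<ga_state> best objective = ", signif(x$best_objective, 6), " after ",
      x$iterations_run, " iteration(s)",
      if (x$converged) " (converged)", "; ", x$n_evaluations,
      " objective evaluations\n", sep = "")
  invisible(x)
}

#' @describeIn optimize_panel trajectory tibble (`iteration`, `best`, `mean`)
#' @param x a `ga_state`
#' @param ... unused
#' @export
tidy.ga_state <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$best_trajectory),
                 best = x$best_trajectory, mean = x$mean_trajectory)
}

#' @describeIn optimize_panel one-row summary tibble
#' @export
glance.ga_state <- function(x, ...) {
  tibble::tibble(best_objective = x$best_objective,
                 iterations_run = x$iterations_run,
                 converged = x$converged, n_evaluations = x$n_evaluations,
                 seed = x$seed)
}
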