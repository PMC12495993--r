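full_inputs <- function() {
  fx <- sim_fixture()
  ds <- fx$ds
  list(
    fx = fx, ds = ds,
    mk = simulated_panel(ds, "marker"),
    db = simulate_pathway_db(fx$cfg),
    lr = simulate_lr_table(fx$cfg),
    graph = build_knn_graph(ds$coords, k = 6),
    pm = linear_response_model(n_genes(ds), density = 0.1, seed = 99,
                               gene_ids = ds$gene_ids)
  )
}

test_that("category scores recompose exactly from the individual metrics", {
  inp <- full_inputs()
  cfg <- score_config(seed = 4)
  cs <- suppressWarnings(category_scores(inp$ds, inp$mk, db = inp$db,
                                         lr_table = inp$lr, graph = inp$graph,
                                         pmodel = inp$pm, config = cfg))
  expect_setequal(cs$available,
                  c("specificity", "diversity", "biology", "spatial", "forward"))
  expect_true(all(cs$values >= 0 & cs$values <= 1))

  sm <- gene_specificity_matrix(inp$ds, inp$mk, epsilon = cfg$epsilon)
  ent <- panel_entropy_score(sm)
  clf <- classification_performance(inp$ds, inp$mk, n_folds = cfg$n_folds,
                                    seed = cfg$seed)
  v <- variation_recovery_nmi(inp$ds, inp$mk, seed = cfg$seed)
  expect_equal(cs$values[["specificity"]],
               mean(c(clf$balanced_accuracy, 1 - ent$entropy, v)))

  d <- feature_diversity_score(inp$ds, inp$mk, tau = cfg$tau)
  expect_equal(cs$values[["diversity"]], (d$score + 1) / 2)

  enr <- enrich_pathways(inp$mk, inp$db, inp$ds$gene_ids, alpha = cfg$alpha)
  pd <- pathway_diversity_score(enr, jaccard_cut = cfg$jaccard_cut)
  lrs <- ligand_receptor_summary(inp$mk, inp$lr)
  expect_equal(cs$values[["biology"]],
               mean(c(enr$pct_genes_enriched, pd, lrs$lr_proportion)))

  sp <- spatial_metrics(inp$ds, inp$mk, inp$graph)$per_gene
  expect_equal(cs$values[["spatial"]],
               mean((sp$morans_i[!sp$degenerate] + 1) / 2))

  expect_equal(cs$values[["forward"]],
               panel_perturbation_score(inp$pm, inp$mk,
                                        delta = cfg$delta)$panel_score)
})

test_that("optional inputs drop their category from `available`", {
  inp <- full_inputs()
  no_coords <- expression_dataset(inp$ds$counts, inp$ds$cell_types)
  no_coords$lognorm <- inp$ds$lognorm
  cs <- category_scores(no_coords, inp$mk, config = score_config(seed = 4))
  expect_setequal(cs$available, c("specificity", "diversity"))
})

test_that("overall score: endpoints, selective weights, scaling invariance", {
  inp <- full_inputs()
  cs <- suppressWarnings(category_scores(inp$ds, inp$mk, db = inp$db,
                                         lr_table = inp$lr, graph = inp$graph,
                                         pmodel = inp$pm,
                                         config = score_config(seed = 4)))
  # weight concentrated on one category returns exactly that category
  w <- c(specificity = 1, diversity = 0, biology = 0, spatial = 0, forward = 0)
  expect_equal(overall_score(cs, weights = w), cs$values[["specificity"]])

  # random weights match the scalar recomputation; positive rescaling is a no-op
  set.seed(61)
  for (i in 1:100) {
    w <- runif(5)
    names(w) <- c("specificity", "diversity", "biology", "spatial", "forward")
    expected <- sum(w / sum(w) * cs$values[names(w)])
    expect_equal(overall_score(cs, weights = w), expected, tolerance = 1e-12)
    expect_equal(overall_score(cs, weights = w * runif(1, 0.1, 10)),
                 overall_score(cs, weights = w), tolerance = 1e-12)
  }
  expect_error(overall_score(cs, weights = 0 * w), "not all zero")

  # monotone in each category score
  cs2 <- cs
  cs2$values["diversity"] <- cs$values[["diversity"]] + 0.01
  expect_gt(overall_score(cs2), overall_score(cs))
})

test_that("gene importance hits min-max endpoints and handles degenerate panels", {
  inp <- full_inputs()
  cs <- suppressWarnings(category_scores(inp$ds, inp$mk, db = inp$db,
                                         lr_table = inp$lr, graph = inp$graph,
                                         pmodel = inp$pm,
                                         config = score_config(seed = 4)))
  imp <- suppressWarnings(gene_importance_scores(cs))
  expect_setequal(imp$gene, inp$mk$genes)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1, na.rm = TRUE))
  # a gene best-in-panel on every category would score exactly 1; verify the
  # endpoint on the specificity sub-score instead (min-max by construction)
  expect_equal(max(imp$specificity), 1)
  expect_equal(min(imp$specificity), 0)

  # two-gene panel with identical sub-scores collapses to 0.5 with a warning
  x <- cbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  rownames(x) <- paste0("c", 1:4)
  ds2 <- expression_dataset(matrix(1, 4, 2, dimnames = dimnames(x)),
                            c("A", "A", "B", "B"))
  ds2$lognorm <- as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  cs2 <- category_scores(ds2, gene_panel(c("g1", "g2")),
                         config = score_config(seed = 4, n_folds = 2))
  w <- capture_warnings(imp2 <- gene_importance_scores(cs2))
  expect_true(any(grepl("degenerate min-max", w)))
  expect_equal(imp2$diversity, c(0.5, 0.5))
})

test_that("five-gene importance matches a hand-assembled recomputation", {
  inp <- full_inputs()
  five <- gene_panel(c("M1_1", "M2_1", "M3_1", "HK_1", "NZ_1"), name = "five")
  cfg <- score_config(seed = 4)
  cs <- category_scores(inp$ds, five, db = inp$db, lr_table = inp$lr,
                        graph = inp$graph, pmodel = inp$pm, config = cfg)
  imp <- suppressWarnings(gene_importance_scores(cs))

  # spreadsheet-style recomputation of the specificity and spatial sub-scores
  sm <- gene_specificity_matrix(inp$ds, five, epsilon = cfg$epsilon)
  spec_raw <- apply(sm$values, 1, max)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(imp$specificity, unname(mm(spec_raw)[imp$gene]))

  sp <- spatial_metrics(inp$ds, five, inp$graph)$per_gene
  expect_equal(imp$spatial,
               unname(mm(sp$morans_i[match(imp$gene, sp$gene)])))
})

test_that("the optimizer objective recomposes from its five constituents", {
  inp <- full_inputs()
  cfg <- score_config(seed = 4)
  obj <- ga_objective(inp$ds, inp$mk, db = inp$db, graph = inp$graph,
                      config = cfg)
  d <- (feature_diversity_score(inp$ds, inp$mk, tau = cfg$tau)$score + 1) / 2
  pd <- pathway_diversity_score(
    enrich_pathways(inp$mk, inp$db, inp$ds$gene_ids, alpha = cfg$alpha),
    jaccard_cut = cfg$jaccard_cut)
  ent <- 1 - panel_entropy_score(
    gene_specificity_matrix(inp$ds, inp$mk, epsilon = cfg$epsilon))$entropy
  sp <- spatial_metrics(inp$ds, inp$mk, inp$graph)$per_gene
  spat <- mean((sp$morans_i[!sp$degenerate] + 1) / 2)
  v <- variation_recovery_nmi(inp$ds, inp$mk, seed = cfg$seed)
  expect_equal(obj, mean(c(d, pd, ent, spat, v)), tolerance = 1e-12)
  expect_gte(obj, 0); expect_lte(obj, 1)

  # without coordinates the spatial constituent is dropped and renormalized
  no_coords <- expression_dataset(inp$ds$counts, inp$ds$cell_types)
  no_coords$lognorm <- inp$ds$lognorm
  obj4 <- ga_objective(no_coords, inp$mk, db = inp$db, config = cfg)
  expect_equal(obj4, mean(c(d, pd, ent, v)), tolerance = 1e-12)

  # deterministic given dataset, panel, config
  expect_identical(obj, ga_objective(inp$ds, inp$mk, db = inp$db,
                                     graph = inp$graph, config = cfg))
})
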