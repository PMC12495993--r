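test_that("gsc matches closed forms and a per-entry scalar oracle", {
  # p_in = 1, p_out = 0 -> log2(1.01/0.01); equal proportions -> 0
  counts <- rbind(c(1, 1), c(2, 1), c(0, 1), c(0, 1))
  dimnames(counts) <- list(paste0("c", 1:4), c("gA", "gB"))
  ds <- expression_dataset(counts, c("A", "A", "B", "B"))
  sm <- gene_specificity_matrix(ds, gene_panel(c("gA", "gB")), epsilon = 0.01)
  expect_equal(sm$values["gA", "A"], log2(1.01 / 0.01))
  expect_equal(sm$values["gA", "B"], log2(0.01 / 1.01))
  expect_equal(sm$values["gB", "A"], 0)

  # random 30-cell, 4-gene, 3-type dataset vs explicit loops
  set.seed(11)
  counts <- matrix(rpois(120, 1), 30, 4,
                   dimnames = list(paste0("c", 1:30), paste0("g", 1:4)))
  types <- sample(c("A", "B", "C"), 30, replace = TRUE)
  ds <- expression_dataset(counts, types)
  sm <- gene_specificity_matrix(ds, gene_panel(paste0("g", 1:4)))
  for (g in paste0("g", 1:4)) for (t in c("A", "B", "C")) {
    p_in <- mean(counts[types == t, g] > 0)
    p_out <- mean(counts[types != t, g] > 0)
    expect_equal(sm$values[g, t], log2((p_in + 0.01) / (p_out + 0.01)))
  }

  expect_error(gene_specificity_matrix(ds, gene_panel("g1"), epsilon = 0),
               "positive")
  ds1 <- expression_dataset(counts, rep("A", 30))
  expect_error(gene_specificity_matrix(ds1, gene_panel("g1")), "2 cell types")
})

test_that("gsc is antisymmetric under swapping target and complement", {
  fx <- sim_fixture()
  ds <- fx$ds
  two <- expression_dataset(ds$counts, ifelse(ds$cell_types == "T1", "in", "out"))
  sm <- gene_specificity_matrix(two, simulated_panel(ds, "marker"))
  expect_equal(sm$values[, "in"], -sm$values[, "out"], tolerance = 1e-12)
})

test_that("panel entropy follows its formula on degenerate and 2x2 cases", {
  # constant positive matrix: Moran degenerate -> 0, p0 = 0 -> entropy 0.25
  sm <- sm_from_values(matrix(2, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])))
  e <- panel_entropy_score(sm)
  expect_true(e$degenerate)
  expect_equal(e$grid_moran, 0)
  expect_equal(e$entropy, 0.25)

  # 2x2 [[1,-1],[-1,1]]: grid Moran's I from the brute-force double loop
  v <- matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  e <- panel_entropy_score(sm_from_values(v))
  # clustering of 2 items leaves order {1,2}; brute-force over the 4 grid units
  i_oracle <- moran_brute(as.vector(v), rook_grid_W(2, 2))
  expect_equal(e$grid_moran, i_oracle, tolerance = 1e-12)
  p0 <- mean(apply(v, 1, max) <= 0)
  expect_equal(e$entropy, 0.5 * (1 - (i_oracle + 1) / 2) + 0.5 * p0)

  expect_error(panel_entropy_score(sm_from_values(matrix(1, 1, 3))), ">= 2")
})

test_that("block-diagonal gsc has lower entropy than entry-permuted versions", {
  set.seed(5)
  v <- matrix(-1 + rnorm(36, sd = 0.05), 12, 3)
  for (t in 1:3) v[(t - 1) * 4 + 1:4, t] <- 3 + rnorm(4, sd = 0.05)
  dimnames(v) <- list(paste0("g", 1:12), paste0("T", 1:3))
  e_block <- panel_entropy_score(sm_from_values(v))$entropy
  for (rep in 1:20) {
    vp <- matrix(sample(as.vector(v)), 12, 3, dimnames = dimnames(v))
    expect_lt(e_block, panel_entropy_score(sm_from_values(vp))$entropy)
  }
})

test_that("entropy is invariant to identical row+column permutation before clustering", {
  set.seed(9)
  v <- matrix(-1, 3, 3)
  diag(v) <- 3
  v <- v + matrix(rnorm(9, sd = 1e-3), 3, 3)
  dimnames(v) <- list(paste0("g", 1:3), paste0("T", 1:3))
  e0 <- panel_entropy_score(sm_from_values(v))$entropy
  perm <- c(3, 1, 2)
  vp <- v[perm, perm]
  # leaf orientation may flip under permutation; with symmetric blocks the
  # score is recovered up to the jitter scale
  expect_equal(panel_entropy_score(sm_from_values(vp))$entropy, e0,
               tolerance = 1e-3)
})

test_that("NMI matches entropy-formula oracle, igraph cross-check, and endpoints", {
  u <- c(1, 1, 1, 2)
  v <- c(1, 1, 2, 2)   # contingency [[2, 1], [0, 1]]
  # independent oracle: plogp sums over the contingency table
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pu <- c(3, 1) / 4; pv <- c(2, 2) / 4
  pj <- c(2, 0, 1, 1) / 4
  mi <- h(pu) + h(pv) - h(pj)
  expect_equal(nmi(u, v), 2 * mi / (h(pu) + h(pv)), tolerance = 1e-12)
  skip_if_not_installed("igraph")
  expect_equal(nmi(u, v), igraph::compare(u, v, method = "nmi"),
               tolerance = 1e-12)

  expect_equal(nmi(u, u), 1)                       # identity
  expect_equal(nmi(u, rep(1, 4)), 0)               # single cluster
  expect_equal(nmi(u, v), nmi(v, u))               # symmetry
})

test_that("variation recovery separates marker from noise panels and is seeded", {
  fx <- sim_fixture()
  ds <- fx$ds
  mk <- simulated_panel(ds, "marker")
  nz <- simulated_panel(ds, "noise", size = 15, seed = 3)
  n_mk <- variation_recovery_nmi(ds, mk, seed = 1)
  n_nz <- variation_recovery_nmi(ds, nz, seed = 1)
  expect_gt(n_mk, n_nz)
  expect_gt(n_mk, 0.4)
  expect_identical(n_mk, variation_recovery_nmi(ds, mk, seed = 1))
  expect_error(variation_recovery_nmi(ds, mk, k = 1), ">= 2")
})

test_that("balanced accuracy is the unweighted mean of per-class recall", {
  # a constant predictor over two balanced classes scores 0.5
  truth <- factor(rep(c("A", "B"), each = 10))
  pred <- factor(rep("A", 20), levels = c("A", "B"))
  expect_equal(panelcraft:::balanced_accuracy(truth, pred), 0.5)
  # and is insensitive to imbalance, unlike plain accuracy
  truth <- factor(rep(c("A", "B"), c(18, 2)))
  pred <- factor(rep("A", 20), levels = c("A", "B"))
  expect_equal(panelcraft:::balanced_accuracy(truth, pred), 0.5)
})

test_that("marker panels classify cell types well, permuted labels near chance", {
  fx <- sim_fixture()
  ds <- fx$ds
  mk <- simulated_panel(ds, "marker")
  for (s in 1:3) {
    r <- classification_performance(ds, mk, seed = s)
    expect_gte(r$balanced_accuracy, 0.9)
    expect_length(r$fold_scores, 5)
    expect_equal(r$balanced_accuracy, mean(r$per_type_accuracy))
  }
  perm <- withr::with_seed(1,
    expression_dataset(ds$counts, sample(ds$cell_types), coords = ds$coords))
  perm$lognorm <- ds$lognorm
  r0 <- classification_performance(perm, mk, seed = 1)
  expect_lt(abs(r0$balanced_accuracy - 1 / 3), 0.1)

  few <- expression_dataset(ds$counts, replace(ds$cell_types, 1, "rare"))
  few$lognorm <- ds$lognorm
  expect_error(classification_performance(few, mk), "n_folds")
})
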