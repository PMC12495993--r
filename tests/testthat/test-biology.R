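test_that("hypergeometric p-values match combinatorial tail sums", {
  # panel of 10 equal to a pathway of 10 in a universe of 100
  universe <- paste0("u", 1:100)
  panel <- gene_panel(universe[1:10])
  db <- pathway_database(list(pw = universe[1:10]))
  s <- enrich_pathways(panel, db, universe)
  expect_equal(s$per_pathway$p_value, 1 / choose(100, 10), tolerance = 1e-10)

  # zero overlap -> p = 1
  db0 <- pathway_database(list(pw = universe[90:100]))
  s0 <- enrich_pathways(panel, db0, universe)
  expect_equal(s0$per_pathway$p_value, 1)

  # 10 random small cases vs explicit tail sums over the overlap distribution
  set.seed(31)
  for (i in 1:10) {
    N <- sample(50:200, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(5:20, 1); n <- sample(5:20, 1)
    pw <- sample(uni, K)
    pan <- gene_panel(sample(uni, n))
    k <- length(intersect(pw, pan$genes))
    s <- enrich_pathways(pan, pathway_database(list(pw = pw)), uni)
    tail_sum <- sum(vapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }, numeric(1)))
    expect_equal(s$per_pathway$p_value, tail_sum, tolerance = 1e-12)
  }
})

test_that("BH q-values follow the step-up definition", {
  # worked case: p = (0.01, 0.02, 0.03) over 3 pathways -> q all 0.03
  universe <- paste0("u", 1:60)
  # build three pathways whose p-values we then overwrite via p.adjust check:
  # assert directly on the step-up arithmetic used by the implementation
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # and that enrich_pathways reproduces p.adjust on its own p-values
  set.seed(32)
  db <- pathway_database(lapply(stats::setNames(1:6, paste0("pw", 1:6)),
                                function(i) sample(universe, 8)))
  pan <- gene_panel(sample(universe, 12))
  s <- enrich_pathways(pan, db, universe)
  expect_equal(s$per_pathway$q_value, p.adjust(s$per_pathway$p_value, "BH"))
  # step-up monotonicity after the cumulative minimum
  ord <- order(s$per_pathway$p_value)
  expect_true(all(diff(s$per_pathway$q_value[ord]) >= -1e-15))
})

test_that("enrichment summary counts genes in significant pathways", {
  universe <- paste0("u", 1:500)
  panel <- gene_panel(universe[1:10])
  db <- pathway_database(list(hit = universe[1:8], miss = universe[400:420]))
  s <- enrich_pathways(panel, db, universe, alpha = 0.05)
  expect_equal(s$n_sig_pathways, 1)
  expect_equal(s$n_genes_enriched, 8)
  expect_equal(s$pct_genes_enriched, 0.8)
  expect_equal(s$max_q, s$per_pathway$q_value[s$per_pathway$pathway == "hit"])

  expect_error(enrich_pathways(panel, db, character(0)), "empty universe")
  dbo <- pathway_database(list(hit = universe[1:8], out = paste0("x", 1:5)))
  expect_warning(enrich_pathways(panel, dbo, universe), "skipped")
})

test_that("pathway diversity handles identical, disjoint and mixed overlaps", {
  universe <- paste0("u", 1:500)
  panel <- gene_panel(universe[1:10])

  # three identical significant pathways -> keep 1, diversity 1/3
  db <- pathway_database(list(a = universe[1:8], b = universe[1:8],
                              c = universe[1:8]))
  s <- enrich_pathways(panel, db, universe)
  expect_equal(s$n_sig_pathways, 3)
  expect_equal(pathway_diversity_score(s), 1 / 3)

  # three pairwise-disjoint significant pathways -> diversity 1
  db <- pathway_database(list(a = universe[1:3], b = universe[4:6],
                              c = universe[7:9]))
  s <- enrich_pathways(panel, db, universe)
  expect_equal(s$n_sig_pathways, 3)
  expect_equal(pathway_diversity_score(s), 1)

  # degenerate: <= 1 significant pathway -> 1
  db <- pathway_database(list(a = universe[1:8]))
  expect_equal(pathway_diversity_score(enrich_pathways(panel, db, universe)), 1)
})

test_that("pathway diversity equals an exhaustive greedy-trace oracle", {
  universe <- paste0("u", 1:500)
  panel <- gene_panel(universe[1:12])
  db <- pathway_database(list(
    p1 = universe[1:10],            # strongest
    p2 = universe[c(1:9, 20)],      # Jaccard 9/11 with p1 -> pruned
    p3 = universe[c(1:5, 30:34)],   # Jaccard 5/15 with p1 -> kept
    p4 = universe[c(6:12, 40:42)]   # overlaps p1 and p3 moderately
  ))
  s <- enrich_pathways(panel, db, universe)
  expect_equal(s$n_sig_pathways, 4)
  # greedy replay in q order with the same tie-breaks
  pp <- s$per_pathway[order(s$per_pathway$q_value, -s$per_pathway$overlap,
                            s$per_pathway$pathway), ]
  kept <- list()
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (nm in pp$pathway) {
    set <- s$members[[nm]]
    if (all(vapply(kept, function(k) jac(set, k) <= 0.7, logical(1)))) {
      kept[[length(kept) + 1]] <- set
    }
  }
  expect_equal(pathway_diversity_score(s), length(kept) / 4)
})

test_that("ligand/receptor composition counts each gene once", {
  panel <- gene_panel(paste0("g", 1:10))
  lr <- data.frame(gene = c("g1", "g2", "g3", "g3"),
                   category = c("ligand", "ligand", "receptor", "ligand"))
  # g3 appears as both -> both; g1, g2 ligands; one receptor-only none
  s <- ligand_receptor_summary(panel, lr)
  expect_equal(s$n_ligand, 2)
  expect_equal(s$n_receptor, 0)
  expect_equal(s$n_both, 1)
  expect_equal(s$n_other, 7)
  expect_equal(s$lr_proportion, 0.3)
  expect_equal(s$n_ligand + s$n_receptor + s$n_both + s$n_other, length(panel))

  s0 <- ligand_receptor_summary(panel, NULL)
  expect_equal(s0$lr_proportion, 0)
  expect_error(ligand_receptor_summary(panel,
                                       data.frame(gene = "g1", category = "x")),
               "unknown")
})

test_that("adding never-enriched noise genes dilutes enrichment monotonically", {
  fx <- sim_fixture()
  ds <- fx$ds
  db <- simulate_pathway_db(fx$cfg)
  # noise genes absent from every pathway
  in_db <- unique(unlist(db$pathways))
  free <- setdiff(grep("^NZ_", ds$gene_ids, value = TRUE), in_db)
  mk <- simulated_panel(ds, "marker")
  base <- enrich_pathways(mk, db, ds$gene_ids)
  expect_gte(base$n_sig_pathways, 1)
  prev_pct <- base$pct_genes_enriched
  prev_sig <- base$n_sig_pathways
  for (add in seq(5, 25, by = 5)) {
    p <- gene_panel(c(mk$genes, free[seq_len(add)]), name = "diluted")
    s <- enrich_pathways(p, db, ds$gene_ids)
    expect_lte(s$pct_genes_enriched, prev_pct)
    expect_lte(s$n_sig_pathways, prev_sig)
    prev_pct <- s$pct_genes_enriched
  }
})
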