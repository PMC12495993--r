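#' Pathway database
#'
#' A named list of gene sets, the carrier for over-representation analysis.
#'
#' @param pathways named list of character vectors (unique names, non-empty
#'   sets)
#' @param source free-text provenance tag
#' @return a `pathway_database`
#' @export
pathway_database <- function(pathways, source = "custom") {
  if (length(pathways) == 0) stop("empty pathway database")
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)) ||
      any(!nzchar(names(pathways)))) {
    stop("pathway names must be unique and non-empty")
  }
  if (any(lengths(pathways) == 0)) stop("pathway with empty gene set")
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  structure(list(pathways = pathways, source = source),
            class = "pathway_database")
}

#' @export
print.pathway_database <- function(x, ...) {
  cat("<pathway_database> ", length(x$pathways), " pathways (",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: name, description, then member genes.
#'
#' @param path file path
#' @return `read_gmt()`: a [pathway_database()]
#' @export
read_gmt <- function(path) {
  pathway_database(fgsea::gmtPathways(path), source = basename(path))
}

#' @rdname read_gmt
#' @param db a [pathway_database()]
#' @return `write_gmt()`: invisibly, `path`
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$pathways), function(nm) {
    paste(c(nm, db$source, db$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway over-representation of a panel
#'
#' One-sided hypergeometric test per pathway for the overlap between the panel
#' and the pathway, both intersected with the gene universe, followed by
#' Benjamini-Hochberg correction over all tested pathways. A pathway is
#' significant when `q < alpha`. The summary reports the number of significant
#' pathways, how many panel genes fall in at least one significant pathway (and
#' the proportion over panel-in-universe genes), and the maximum q-value among
#' significant pathways.
#'
#' @param panel a [gene_panel()]
#' @param db a [pathway_database()]
#' @param universe character vector of genes forming the test universe
#'   (typically all genes of the filtered reference dataset)
#' @param alpha significance level on q-values (default 0.05)
#' @return an `enrichment_summary`
#' @export
enrich_pathways <- function(panel, db, universe, alpha = 0.05) {
  stopifnot(inherits(panel, "gene_panel"), inherits(db, "pathway_database"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  genes <- intersect(panel$genes, universe)
  if (length(genes) < length(panel$genes)) {
    message("panel '", panel$name, "': ", length(panel$genes) - length(genes),
            " gene(s) outside the universe excluded from enrichment")
  }
  N <- length(universe)
  n <- length(genes)

  members <- lapply(db$pathways, intersect, universe)
  empty <- lengths(members) == 0
  if (any(empty)) {
    warning(sum(empty), " pathway(s) with zero overlap with the universe skipped")
    members <- members[!empty]
  }
  if (length(members) == 0) stop("no pathway overlaps the universe")

  overlap <- vapply(members, function(m) length(intersect(m, genes)), integer(1))
  K <- lengths(members)
  p <- stats::phyper(overlap - 1L, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q < alpha

  per_pathway <- tibble::tibble(
    pathway = names(members), size = unname(K), overlap = unname(overlap),
    p_value = unname(p), q_value = unname(q), significant = unname(sig)
  )
  sig_names <- per_pathway$pathway[sig]
  enriched_genes <- unique(unlist(lapply(members[sig_names], intersect, genes),
                                  use.names = FALSE))

  structure(list(
    per_pathway = per_pathway,
    n_sig_pathways = sum(sig),
    n_genes_enriched = length(enriched_genes),
    pct_genes_enriched = if (n > 0) length(enriched_genes) / n else 0,
    max_q = if (any(sig)) max(q[sig]) else NA_real_,
    alpha = alpha,
    panel_genes = genes, n_panel_total = length(panel$genes),
    universe = universe, members = members,
    panel = panel$name
  ), class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat("<enrichment_summary> '", x$panel, "': ", x$n_sig_pathways,
      " significant pathway(s) at q < ", x$alpha, "; ", x$n_genes_enriched,
      "/", length(x$panel_genes), " genes enriched\n", sep = "")
  invisible(x)
}

#' @describeIn enrich_pathways per-pathway results tibble
#' @param x an `enrichment_summary`
#' @param ... unused
#' @export
tidy.enrichment_summary <- function(x, ...) x$per_pathway

#' @describeIn enrich_pathways one-row summary tibble
#' @export
glance.enrichment_summary <- function(x, ...) {
  tibble::tibble(n_sig_pathways = x$n_sig_pathways,
                 n_genes_enriched = x$n_genes_enriched,
                 pct_genes_enriched = x$pct_genes_enriched,
                 max_q = x$max_q, alpha = x$alpha)
}

#' Pathway diversity score
#'
#' Fraction of significant pathways surviving greedy removal of near-duplicate
#' pathways: pathways are visited by ascending q-value (ties broken by larger
#' overlap, then name) and kept only if their Jaccard similarity (on full
#' member sets intersected with the universe) with every already-kept pathway
#' is at most `jaccard_cut`. With `n` significant and `n'` kept, the score is
#' `n'/n`, defined as 1 when `n <= 1`.
#'
#' @param summary an `enrichment_summary` from [enrich_pathways()]
#' @param jaccard_cut similarity cut-off (default 0.7)
#' @return diversity in `(0, 1]`
#' @export
pathway_diversity_score <- function(summary, jaccard_cut = 0.7) {
  stopifnot(inherits(summary, "enrichment_summary"))
  pp <- summary$per_pathway[summary$per_pathway$significant, , drop = FALSE]
  n <- nrow(pp)
  if (n <= 1) return(1)
  ord <- order(pp$q_value, -pp$overlap, pp$pathway)
  sets <- summary$members[pp$pathway[ord]]
  kept <- list()
  for (s in sets) {
    ok <- all(vapply(kept, function(k) jaccard(s, k) <= jaccard_cut, logical(1)))
    if (ok) kept[[length(kept) + 1L]] <- s
  }
  length(kept) / n
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Ligand/receptor composition of a panel
#'
#' Classifies each panel gene as ligand, receptor, both (listed under both
#' categories) or other, from a flat annotation table. `lr_proportion` is the
#' fraction of panel genes that are ligand, receptor or both.
#'
#' @param panel a [gene_panel()]
#' @param lr_table data frame with columns `gene` and `category`
#'   (values `"ligand"` or `"receptor"`); may be empty
#' @return a `lr_summary` with counts `n_ligand`, `n_receptor`, `n_both`,
#'   `n_other` and `lr_proportion`
#' @export
ligand_receptor_summary <- function(panel, lr_table) {
  stopifnot(inherits(panel, "gene_panel"))
  if (is.null(lr_table) || nrow(lr_table) == 0) {
    lig <- rec <- character(0)
  } else {
    stopifnot(all(c("gene", "category") %in% names(lr_table)))
    bad <- setdiff(unique(lr_table$category), c("ligand", "receptor"))
    if (length(bad)) stop("unknown ligand/receptor category: ", bad[1])
    lig <- lr_table$gene[lr_table$category == "ligand"]
    rec <- lr_table$gene[lr_table$category == "receptor"]
  }
  is_l <- panel$genes %in% lig
  is_r <- panel$genes %in% rec
  n_both <- sum(is_l & is_r)
  n_ligand <- sum(is_l & !is_r)
  n_receptor <- sum(is_r & !is_l)
  n_other <- length(panel) - n_ligand - n_receptor - n_both
  structure(list(n_ligand = n_ligand, n_receptor = n_receptor,
                 n_both = n_both, n_other = n_other,
                 lr_proportion = (n_ligand + n_receptor + n_both) / length(panel),
                 panel = panel$name),
            class = "lr_summary")
}

#' @export
print.lr_summary <- function(x, ...) {
  cat("<lr_summary> '", x$panel, "': ", x$n_ligand, " ligand / ",
      x$n_receptor, " receptor / ", x$n_both, " both / ", x$n_other,
      " other (LR proportion ", signif(x$lr_proportion, 3), ")\n", sep = "")
  invisible(x)
}

#' @describeIn ligand_receptor_summary one-row tibble of counts
#' @param x a `lr_summary`
#' @param ... unused
#' @export
glance.lr_summary <- function(x, ...) {
  tibble::tibble(n_ligand = x$n_ligand, n_receptor = x$n_receptor,
                 n_both = x$n_both, n_other = x$n_other,
                 lr_proportion = x$lr_proportion)
}

#' Read a ligand/receptor annotation table
#' @param path CSV with columns `gene,category`
#' @return a tibble
#' @export
read_lr_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
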