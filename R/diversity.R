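#' Feature diversity score
#'
#' Panel redundancy from pairwise Spearman correlations over cells on the
#' lognorm layer. A gene pair is redundant when `|rho| >= tau`, orthogonal
#' otherwise; the score is the signed proportion
#' `(n_orthogonal - n_redundant) / n_pairs`, in `[-1, 1]`. Positive values
#' reflect greater diversity, negative values redundancy. Being rank-based,
#' the score is invariant to strictly monotone per-gene transforms.
#'
#' @param ds an [expression_dataset()] with a lognorm layer
#' @param panel a [gene_panel()] with >= 2 genes in the dataset
#' @param tau redundancy threshold on `|rho|`, in (0, 1) (default 0.3)
#' @return a `diversity_result` with the score, pair counts, and the condensed
#'   pairwise correlations as a tibble (`gene_a`, `gene_b`, `rho`, `redundant`)
#' @export
feature_diversity_score <- function(ds, panel, tau = 0.3) {
  stopifnot(inherits(ds, "expression_dataset"), tau > 0, tau < 1)
  panel <- intersect_panel(panel, ds)
  if (length(panel) < 2) stop("feature diversity needs >= 2 panel genes in the dataset")

  x <- lognorm_submatrix(ds, panel$genes)
  zero_var <- apply(x, 2, stats::var) == 0
  if (any(zero_var)) {
    warning("zero-variance gene(s): ",
            paste(colnames(x)[zero_var], collapse = ", "),
            "; their pairs are assigned rho = 0")
  }
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[zero_var, ] <- 0
  rho[, zero_var] <- 0

  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  rho_pair <- rho[pairs]
  correlations <- tibble::tibble(
    gene_a = colnames(x)[pairs[, 1]],
    gene_b = colnames(x)[pairs[, 2]],
    rho = rho_pair,
    redundant = abs(rho_pair) >= tau
  )
  n_pairs <- nrow(correlations)
  n_redundant <- sum(correlations$redundant)
  n_orthogonal <- n_pairs - n_redundant

  structure(list(score = (n_orthogonal - n_redundant) / n_pairs,
                 tau = tau, n_pairs = n_pairs, n_redundant = n_redundant,
                 n_orthogonal = n_orthogonal, correlations = correlations),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result> score = ", signif(x$score, 4), " (",
      x$n_orthogonal, " orthogonal / ", x$n_redundant, " redundant of ",
      x$n_pairs, " pairs, tau = ", x$tau, ")\n", sep = "")
  invisible(x)
}

#' @describeIn feature_diversity_score pairwise correlation tibble
#' @param x a `diversity_result`
#' @param ... unused
#' @export
tidy.diversity_result <- function(x, ...) x$correlations

#' @describeIn feature_diversity_score one-row summary tibble
#' @export
glance.diversity_result <- function(x, ...) {
  tibble::tibble(score = x$score, tau = x$tau, n_pairs = x$n_pairs,
                 n_redundant = x$n_redundant, n_orthogonal = x$n_orthogonal)
}

#' Export pairwise correlations as TSV
#' @param dr a `diversity_result`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_diversity_tsv <- function(dr, path) {
  utils::write.table(dr$correlations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
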