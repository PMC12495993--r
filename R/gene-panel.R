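#' Construct a gene panel
#'
#' A named, ordered, duplicate-free list of gene symbols — the unit of
#' characterization and optimization.
#'
#' @param genes character vector of gene symbols, unique and non-empty
#' @param name panel name
#' @return a `gene_panel` object
#' @export
gene_panel <- function(genes, name = "panel") {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("a panel must contain at least one gene")
  if (any(!nzchar(genes)) || anyNA(genes)) stop("empty gene symbol in panel")
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)

#' Read a gene panel from a text file
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path file path
#' @param name panel name (default: file name without extension)
#' @return a [gene_panel()]
#' @export
read_panel <- function(path, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_panel(lines, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a gene panel to a text file
#' @param panel a [gene_panel()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_panel <- function(panel, path) {
  writeLines(panel$genes, path)
  invisible(path)
}

#' Intersect a panel with a dataset's genes
#'
#' Characterization requires panel genes to be measured in the reference
#' dataset; this explicit step drops absent genes and reports them in
#' `attr(, "dropped")`.
#'
#' @param panel a [gene_panel()]
#' @param ds an [expression_dataset()]
#' @param case_insensitive match symbols case-insensitively (dataset casing
#'   wins)
#' @return the intersected `gene_panel`, with dropped symbols attached
#' @export
intersect_panel <- function(panel, ds, case_insensitive = FALSE) {
  stopifnot(inherits(panel, "gene_panel"), inherits(ds, "expression_dataset"))
  if (case_insensitive) {
    idx <- match(toupper(panel$genes), toupper(ds$gene_ids))
    kept <- ds$gene_ids[idx[!is.na(idx)]]
    dropped <- panel$genes[is.na(idx)]
  } else {
    keep <- panel$genes %in% ds$gene_ids
    kept <- panel$genes[keep]
    dropped <- panel$genes[!keep]
  }
  if (length(kept) == 0) {
    stop("no panel gene found in the dataset ('", panel$name, "')")
  }
  if (length(dropped)) {
    message("panel '", panel$name, "': dropped ", length(dropped),
            " gene(s) absent from the dataset")
  }
  out <- gene_panel(kept, name = panel$name)
  attr(out, "dropped") <- dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
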