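#' Gene-set collection (injury modules or pathways)
#'
#' @param sets named list; each element either a character vector of gene
#'   identifiers or a list with elements `genes` and optional `description`.
#' @param kind `"injury_module"` or `"pathway"`.
#' @return object of class `gene_set_collection`.
#' @examples
#' gene_set_collection(list(necrosis = c("Gsta2", "Mt2A"),
#'                          fibrogenesis = c("Col11a1", "Smoc1")))
#' @export
gene_set_collection <- function(sets, kind = c("injury_module", "pathway")) {
  kind <- match.arg(kind)
  if (length(sets) == 0L) {
    return(structure(list(sets = list(), kind = kind),
                     class = "gene_set_collection"))
  }
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_input("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop_input("duplicate gene-set names: ",
               paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  norm <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.character(s)) s <- list(genes = s, description = "")
    genes <- as.character(s$genes)
    if (length(genes) == 0L)
      stop_input("gene set '", nm, "' is empty")
    if (anyDuplicated(genes)) {
      warning("gene set '", nm, "' has duplicate genes; deduplicated",
              call. = FALSE)
      genes <- unique(genes)
    }
    list(name = nm, description = s$description %||% "", genes = genes)
  })
  names(norm) <- names(sets)
  structure(list(sets = norm, kind = kind), class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets\n", x$kind, length(x$sets)))
  if (length(x$sets)) {
    sz <- vapply(x$sets, function(s) length(s$genes), integer(1))
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  structure(list(sets = x$sets[i], kind = x$kind),
            class = "gene_set_collection")
}

set_genes <- function(collection, name) collection$sets[[name]]$genes
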