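#' Directional pathway activation scoring
#'
#' Scores each pathway gene set with the directional AFC statistic and a
#' two-sided permutation null (via the module-scoring engine), and labels its
#' direction: `up` if z exceeds the threshold, `down` if z is below the
#' negated threshold, `neutral` otherwise. Pathways matching no profiled gene
#' are reported neutral with a note. An optional category map groups pathways
#' (e.g. Metabolism; Cell and Immune Signaling; Cell Cycle/Translation/
#' Transcription); grouping is a pure relabeling and never changes z.
#'
#' @param profiles one `fold_change_profile` or a named list of them.
#' @param pathways a [gene_set_collection()] (kind `pathway` expected but not
#'   enforced).
#' @param categories optional data frame with columns `pathway`, `category`;
#'   categories outside `Metabolism`, `Cell and Immune Signaling`,
#'   `Cell Cycle/Translation/Transcription` are folded into `other`.
#' @param n_resamples,seed,mode passed to [module_activation()].
#' @param z_threshold direction call threshold (default 2).
#' @return data frame `category, pathway, condition, n_genes_matched, score,
#'   z, p_empirical, direction, note`, ordered by category then pathway.
#' @export
score_pathways_directional <- function(profiles, pathways, categories = NULL,
                                       n_resamples = 10000, seed = 1,
                                       z_threshold = 2,
                                       mode = c("auto", "monte_carlo",
                                                "exhaustive")) {
  mode <- match.arg(mode)
  if (length(pathways) == 0L) stop_input("'pathways' must be non-empty")
  fit <- module_activation(profiles, pathways, statistic = "afc",
                           n_resamples = n_resamples, seed = seed,
                           activation_threshold = z_threshold, mode = mode)
  res <- fit$results
  direction <- ifelse(is.na(res$z_score), "neutral",
                      ifelse(res$z_score > z_threshold, "up",
                             ifelse(res$z_score < -z_threshold, "down",
                                    "neutral")))
  cat_map <- pathway_categories(names(pathways), categories)
  out <- data.frame(category = unname(cat_map[res$module]),
                    pathway = res$module, condition = res$condition,
                    n_genes_matched = res$n_genes_matched,
                    score = res$score, z = res$z_score,
                    p_empirical = res$p_empirical, direction = direction,
                    note = res$note, stringsAsFactors = FALSE)
  out[order(out$category, out$pathway, out$condition), , drop = FALSE]
}

pathway_vocab <- c("Metabolism", "Cell and Immune Signaling",
                   "Cell Cycle/Translation/Transcription", "other")

pathway_categories <- function(pathway_names, categories) {
  map <- stats::setNames(rep("other", length(pathway_names)), pathway_names)
  if (!is.null(categories)) {
    if (!all(c("pathway", "category") %in% names(categories)))
      stop_input("'categories' needs columns 'pathway' and 'category'")
    cat <- as.character(categories$category)
    cat[!cat %in% pathway_vocab] <- "other"
    known <- categories$pathway %in% pathway_names
    map[categories$pathway[known]] <- cat[known]
  }
  map
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test for observing at least the seen
#' number of gene-list members inside a pathway, given the measured universe.
#' This is the standard enrichment test (the plain hypergeometric, not the
#' EASE-corrected variant some web tools apply).
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param pathway character vector, a subset of `universe`.
#' @param universe character vector of all measured genes.
#' @return list of class `ora_result`: `k_hits`, `list_size`, `pathway_size`,
#'   `universe_size`, `p_value`.
#' @examples
#' ora_test(paste0("g", 1:3), paste0("g", 1:4), paste0("g", 1:10))
#' @export
ora_test <- function(gene_list, pathway, universe) {
  universe <- unique(fold_id(universe))
  gene_list <- unique(fold_id(gene_list))
  pathway <- unique(fold_id(pathway))
  if (length(gene_list) == 0L || length(pathway) == 0L)
    stop_input("gene list and pathway must be non-empty")
  if (!all(gene_list %in% universe))
    stop_input("gene list contains genes outside the universe")
  if (!all(pathway %in% universe))
    stop_input("pathway contains genes outside the universe")
  k <- length(intersect(gene_list, pathway))
  n <- length(gene_list); K <- length(pathway); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k_hits = k, list_size = n, pathway_size = K,
                 universe_size = N, p_value = p),
            class = "ora_result")
}

#' Batch over-representation analysis with FDR control
#'
#' Runs [ora_test()] for every pathway in a collection and adjusts the
#' p-values across the batch with Benjamini-Hochberg.
#'
#' @inheritParams ora_test
#' @param pathways a [gene_set_collection()].
#' @return data frame `pathway, k_hits, pathway_size, list_size,
#'   universe_size, p_value, q_value`, sorted ascending by q then p.
#' @export
ora_batch <- function(gene_list, pathways, universe) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  if (length(pathways) == 0L) stop_input("'pathways' must be non-empty")
  rows <- lapply(names(pathways), function(nm) {
    r <- ora_test(gene_list, set_genes(pathways, nm), universe)
    data.frame(pathway = nm, k_hits = r$k_hits,
               pathway_size = r$pathway_size, list_size = r$list_size,
               universe_size = r$universe_size, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$q_value, out$p_value), , drop = FALSE]
}
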