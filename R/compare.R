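#' Pairwise DEG overlap matrix
#'
#' Counts the genes shared by every pair of DEG sets; the diagonal holds each
#' set's own size. Conditions must carry distinct labels.
#'
#' @param deg_sets list of [call_degs()] results, or a named list of character
#'   vectors of gene identifiers.
#' @return object of class `overlap_matrix`: symmetric integer matrix with
#'   condition labels as dimnames.
#' @export
overlap_matrix <- function(deg_sets) {
  sets <- deg_gene_lists(deg_sets)
  if (length(sets) < 1L) stop_input("at least one DEG set is required")
  if (anyDuplicated(names(sets)))
    stop_input("duplicate condition labels: ",
               paste(unique(names(sets)[duplicated(names(sets))]),
                     collapse = ", "))
  n <- length(sets)
  counts <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      counts[i, j] <- counts[j, i] <-
        length(intersect(sets[[i]], sets[[j]]))
    }
  }
  structure(counts, class = c("overlap_matrix", class(counts)))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("DEG overlap matrix (diagonal = set sizes):\n")
  print(unclass(x))
  invisible(x)
}

deg_gene_lists <- function(deg_sets) {
  if (inherits(deg_sets, "deg_set")) deg_sets <- list(deg_sets)
  sets <- lapply(deg_sets, function(s) {
    if (inherits(s, "deg_set")) unique(fold_id(s$gene_ids))
    else unique(fold_id(as.character(s)))
  })
  labs <- names(deg_sets)
  auto <- vapply(deg_sets, function(s) {
    if (inherits(s, "deg_set")) condition_label(s$condition) else NA_character_
  }, character(1))
  if (is.null(labs)) labs <- auto
  labs[is.na(labs) | labs == ""] <- auto[is.na(labs) | labs == ""]
  if (anyNA(labs) || any(labs == ""))
    stop_input("every DEG set must have a condition label")
  names(sets) <- labs
  sets
}

#' Genes common to all DEG sets
#'
#' Strict intersection over every provided set (the all-combinations common
#' core). An empty intersection is a valid empty result.
#'
#' @inheritParams overlap_matrix
#' @return character vector of gene identifiers (case-folded).
#' @export
common_genes <- function(deg_sets) {
  sets <- deg_gene_lists(deg_sets)
  if (length(sets) < 2L) stop_input("at least two DEG sets are required")
  Reduce(intersect, sets)
}

#' Rank genes by their mean fold change across conditions
#'
#' Averages each gene's signed log2 fold change over the supplied profiles
#' (arithmetic mean) and sorts descending; the head of the table is the top
#' upregulated genes, the tail the top downregulated. Genes missing from any
#' profile are dropped with a warning.
#'
#' @param genes character vector (e.g. the [common_genes()] core).
#' @param profiles list of `fold_change_profile`s contributing fold changes.
#' @param top_k if non-`NULL`, also attach the top/bottom `k` rows as
#'   attributes `top` and `bottom`.
#' @return data frame `gene_id, mean_log2_fc, n_conditions, rank`, sorted by
#'   `mean_log2_fc` descending.
#' @export
rank_by_mean_fc <- function(genes, profiles, top_k = NULL) {
  if (inherits(profiles, "fold_change_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop_input("at least one profile is required")
  genes <- unique(fold_id(genes))
  if (length(genes) == 0L) stop_input("no genes to rank")
  fcs <- lapply(profiles, profile_fc)
  present <- Reduce(intersect, c(list(genes), lapply(fcs, names)))
  dropped <- setdiff(genes, present)
  if (length(dropped))
    warning(length(dropped), " gene(s) missing from at least one profile; dropped",
            call. = FALSE)
  if (length(present) == 0L) stop_input("no gene is present in every profile")
  mat <- vapply(fcs, function(fc) fc[present], numeric(length(present)))
  mat <- matrix(mat, nrow = length(present))
  out <- data.frame(gene_id = present,
                    mean_log2_fc = rowMeans(mat),
                    n_conditions = ncol(mat),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_log2_fc, decreasing = TRUE), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_k)) {
    k <- min(top_k, nrow(out))
    attr(out, "top") <- utils::head(out, k)
    attr(out, "bottom") <- utils::tail(out, k)[order(utils::tail(out$mean_log2_fc, k)), ]
  }
  out
}

#' Pearson correlation and R-squared of two score vectors
#'
#' Used to compare module-score vectors across conditions, platforms or
#' species. R-squared is the squared Pearson correlation (equivalently the
#' R-squared of a simple linear fit); report at two decimals.
#'
#' @param v1,v2 numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return list with `pearson_r` and `r_squared` (full precision).
#' @examples
#' correlate_scores(c(10.45, 9.64, 7.58), c(2.59, 1.20, 0.96))
#' @export
correlate_scores <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2) || length(v1) < 3L)
    stop_input("vectors must have equal length >= 3")
  if (anyNA(v1) || anyNA(v2))
    stop_input("missing values are not allowed in score vectors")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_input("correlation is undefined for a zero-variance vector")
  r <- stats::cor(v1, v2)
  list(pearson_r = r, r_squared = r^2)
}

#' PCA embedding of a feature table
#'
#' Column-centered (not scaled) SVD-based principal component analysis with a
#' deterministic sign convention: each component's largest-magnitude loading
#' is made positive, so embeddings are reproducible across platforms.
#'
#' @param feature_table numeric matrix, items in rows, features in columns.
#' @param n_components number of components to keep (default all).
#' @return object of class `pca_embedding`: `points` (items x components),
#'   `rotation`, `explained_variance_fraction`, `center`.
#' @export
pca_embed <- function(feature_table, n_components = NULL) {
  x <- as.matrix(feature_table)
  if (!is.numeric(x) || nrow(x) < 2L || ncol(x) < 2L)
    stop_input("'feature_table' must be a numeric matrix with >= 2 rows and columns")
  if (anyNA(x)) stop_input("missing values are not allowed")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop_input("feature table is constant; PCA is undefined")
  max_comp <- min(dim(x)) - if (nrow(x) <= ncol(x)) 1L else 0L
  max_comp <- min(max_comp, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (!is_count(n_components) || n_components < 1L || n_components > min(dim(x)))
    stop_input("n_components must be between 1 and min(dim(feature_table))")
  sv <- svd(xc)
  d2 <- sv$d^2
  evf <- d2 / sum(d2)
  k <- min(n_components, length(sv$d))
  rot <- sv$v[, seq_len(k), drop = FALSE]
  # Sign convention: largest-|loading| entry of each component is positive.
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  points <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(points) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(rot) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(points = points, rotation = rot,
                 explained_variance_fraction = evf[seq_len(k)],
                 center = center),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("pca_embedding: %d items, %d components\n",
              nrow(x$points), ncol(x$points)))
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Silhouette-style separation of groups in a PCA embedding
#'
#' Mean silhouette coefficient of the items over the first two principal
#' components (Euclidean distance). A value near 1 means tight, well-separated
#' clusters; values near 0 mean no structure. Items in singleton groups take
#' silhouette 0 by convention and raise a flag.
#'
#' @param embedding a [pca_embed()] result (or any matrix of coordinates).
#' @param grouping factor or character vector, one group label per item;
#'   at least two distinct groups.
#' @return list with `score` (mean silhouette), `silhouettes` (per item),
#'   `singleton_flag` (`TRUE` if any group has a single member).
#' @export
cluster_separation_check <- function(embedding, grouping) {
  pts <- if (inherits(embedding, "pca_embedding")) embedding$points
         else as.matrix(embedding)
  k <- min(2L, ncol(pts))
  pts <- pts[, seq_len(k), drop = FALSE]
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(pts))
    stop_input("'grouping' must assign a label to every item")
  groups <- unique(grouping)
  if (length(groups) < 2L)
    stop_input("silhouette separation needs at least two groups")
  d <- as.matrix(stats::dist(pts))
  n <- nrow(pts)
  sil <- numeric(n)
  singleton <- FALSE
  for (i in seq_len(n)) {
    own <- which(grouping == grouping[i])
    own <- setdiff(own, i)
    if (length(own) == 0L) { # singleton group: s = 0 by convention
      sil[i] <- 0
      singleton <- TRUE
      next
    }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(groups, grouping[i]), function(g) {
      mean(d[i, grouping == g])
    }, numeric(1)))
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(score = mean(sil), silhouettes = sil, singleton_flag = singleton)
}
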