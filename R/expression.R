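#' Expression matrix container
#'
#' Wraps a gene x sample numeric matrix together with the transform state.
#' Values are either raw (non-negative) abundances or log2-transformed
#' expression; downstream fold-change and differential-expression routines
#' require the log2 scale (see [log_transform()]).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param is_log2 logical; `TRUE` if `values` are already log2-transformed.
#' @param pseudocount value added before taking log2 when transforming raw
#'   abundances (default 1).
#' @return an object of class `expression_matrix` with elements `values`,
#'   `is_log2`, `pseudocount`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m)
#' log_transform(em)
#' @export
expression_matrix <- function(values, is_log2 = FALSE, pseudocount = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop_input("duplicate gene identifiers: ",
               paste(unique(rownames(values)[duplicated(rownames(values))]),
                     collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_input("duplicate sample identifiers")
  if (!is_log2 && any(values < 0, na.rm = TRUE))
    stop_input("raw (non-log) expression values must be >= 0")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop_input("'pseudocount' must be a single non-negative number")
  structure(list(values = values, is_log2 = isTRUE(is_log2),
                 pseudocount = pseudocount),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log2) "log2" else "raw"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Log2-transform a raw expression matrix
#'
#' Applies `log2(x + pseudocount)` element-wise. Calling this on a matrix
#' already on the log2 scale is an error rather than a silent no-op, so a
#' double transform can never slip through a pipeline.
#'
#' @param m an [expression_matrix()] with `is_log2 = FALSE`.
#' @return the transformed `expression_matrix` (`is_log2 = TRUE`).
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$is_log2)
    stop_input("matrix is already log2-transformed; refusing to transform twice")
  if (any(m$values < 0, na.rm = TRUE))
    stop_input("negative raw values cannot be log-transformed")
  out <- m
  out$values <- log2(m$values + m$pseudocount)
  out$is_log2 <- TRUE
  out
}

#' Define a control/treated cohort pair for one condition
#'
#' @param condition named character vector or list with entries `platform`,
#'   `dose`, `time` labelling the treatment condition.
#' @param control,treated character vectors of sample identifiers; disjoint,
#'   each with at least two members.
#' @return object of class `cohort_pair`.
#' @export
cohort_pair <- function(condition, control, treated) {
  condition <- as.list(condition)
  need <- c("platform", "dose", "time")
  if (!all(need %in% names(condition)))
    stop_input("'condition' must name platform, dose and time")
  control <- as.character(control); treated <- as.character(treated)
  if (length(control) < 2L || length(treated) < 2L)
    stop_input("each cohort needs at least 2 samples")
  if (length(intersect(control, treated)) > 0L)
    stop_input("control and treated sample sets must be disjoint")
  structure(list(condition = condition[need], control = control,
                 treated = treated),
            class = "cohort_pair")
}

condition_label <- function(condition) {
  paste(unlist(condition[c("platform", "dose", "time")]), collapse = "_")
}

# Pull the two cohort sub-matrices, validating sample membership.
cohort_values <- function(m, pair) {
  stopifnot(inherits(m, "expression_matrix"), inherits(pair, "cohort_pair"))
  if (!m$is_log2)
    stop_input("expression matrix must be log2-transformed (see log_transform)")
  missing <- setdiff(c(pair$control, pair$treated), colnames(m$values))
  if (length(missing))
    stop_input("samples not in matrix: ", paste(missing, collapse = ", "))
  list(control = m$values[, pair$control, drop = FALSE],
       treated = m$values[, pair$treated, drop = FALSE])
}

new_fc_profile <- function(df, condition, n_dropped) {
  structure(df,
            condition = condition,
            genes_tested = nrow(df),
            n_dropped = n_dropped,
            class = c("fold_change_profile", "data.frame"))
}

#' Per-gene log2 fold changes between treated and control cohorts
#'
#' The fold change of a gene is the difference between the mean
#' log2-transformed expression over the treated samples and the mean over the
#' control samples. Genes with fewer than two usable (non-missing) values in
#' either cohort are dropped with a warning.
#'
#' @param m log2-scale [expression_matrix()].
#' @param pair a [cohort_pair()] valid against `m`.
#' @return a `fold_change_profile` data frame with columns `gene_id`,
#'   `log2_fc`; attributes `condition`, `genes_tested`, `n_dropped`.
#' @export
fold_changes <- function(m, pair) {
  cv <- cohort_values(m, pair)
  n_c <- rowSums(!is.na(cv$control))
  n_t <- rowSums(!is.na(cv$treated))
  keep <- n_c >= 2L & n_t >= 2L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(n_dropped, " gene(s) dropped: fewer than 2 usable values in a cohort",
            call. = FALSE)
  if (!any(keep))
    stop_input("no gene has enough usable values in both cohorts")
  fc <- rowMeans(cv$treated[keep, , drop = FALSE], na.rm = TRUE) -
    rowMeans(cv$control[keep, , drop = FALSE], na.rm = TRUE)
  new_fc_profile(
    data.frame(gene_id = rownames(m$values)[keep], log2_fc = unname(fc),
               stringsAsFactors = FALSE),
    condition = pair$condition, n_dropped = n_dropped)
}

# Vectorized Welch statistics over rows of two matrices (NA-tolerant).
welch_rows <- function(xt, xc) {
  n_t <- rowSums(!is.na(xt)); n_c <- rowSums(!is.na(xc))
  m_t <- rowMeans(xt, na.rm = TRUE); m_c <- rowMeans(xc, na.rm = TRUE)
  v_t <- rowSums((xt - m_t)^2, na.rm = TRUE) / (n_t - 1)
  v_c <- rowSums((xc - m_c)^2, na.rm = TRUE) / (n_c - 1)
  se2 <- v_t / n_t + v_c / n_c
  diff <- m_t - m_c
  p <- rep(NA_real_, length(diff))
  degenerate <- se2 == 0
  # Zero variance in both cohorts: equal means carry no evidence (p = 1);
  # unequal means are infinitely significant under the model (p = 0).
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  ok <- !degenerate
  tt <- diff[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 /
    ((v_t[ok] / n_t[ok])^2 / (n_t[ok] - 1) + (v_c[ok] / n_c[ok])^2 / (n_c[ok] - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  list(log2_fc = diff, p_value = p)
}

#' Welch two-sample differential-expression test
#'
#' Per-gene two-sided Welch unequal-variance t-test on log2 expression values,
#' together with the mean-difference log2 fold change. Genes with zero
#' variance in both cohorts and equal means receive p = 1 (no evidence).
#'
#' @inheritParams fold_changes
#' @param q_values logical; if `TRUE` (default) a Benjamini-Hochberg adjusted
#'   `q_value` column is appended via [bh_adjust()].
#' @return a `fold_change_profile` with columns `gene_id`, `log2_fc`,
#'   `p_value` and (optionally) `q_value`.
#' @export
de_test <- function(m, pair, q_values = TRUE) {
  cv <- cohort_values(m, pair)
  n_c <- rowSums(!is.na(cv$control))
  n_t <- rowSums(!is.na(cv$treated))
  keep <- n_c >= 2L & n_t >= 2L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(n_dropped, " gene(s) dropped: fewer than 2 usable values in a cohort",
            call. = FALSE)
  if (!any(keep))
    stop_input("no gene has enough usable values in both cohorts")
  w <- welch_rows(cv$treated[keep, , drop = FALSE],
                  cv$control[keep, , drop = FALSE])
  df <- data.frame(gene_id = rownames(m$values)[keep],
                   log2_fc = unname(w$log2_fc),
                   p_value = unname(w$p_value),
                   stringsAsFactors = FALSE)
  if (isTRUE(q_values)) df$q_value <- bh_adjust(df$p_value)
  new_fc_profile(df, condition = pair$condition, n_dropped = n_dropped)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (q-values).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop_input("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes at an FDR threshold
#'
#' A gene is a DEG when its q-value is at or below the threshold (inclusive).
#'
#' @param profile a `fold_change_profile` carrying a `q_value` column.
#' @param q_threshold FDR cut-off, default 0.1.
#' @return object of class `deg_set`: `condition`, `gene_ids`, `q_threshold`.
#' @export
call_degs <- function(profile, q_threshold = 0.1) {
  stopifnot(inherits(profile, "fold_change_profile"))
  if (is.null(profile$q_value))
    stop_input("profile has no q_value column; run de_test or bh_adjust first")
  structure(list(condition = attr(profile, "condition"),
                 gene_ids = profile$gene_id[profile$q_value <= q_threshold],
                 q_threshold = q_threshold),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set [%s]: %d genes at q <= %g\n",
              condition_label(x$condition), length(x$gene_ids), x$q_threshold))
  invisible(x)
}
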