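#' Match a gene set against a fold-change profile
#'
#' Gene identifiers are compared case-insensitively (after trimming
#' whitespace); the returned `matched` identifiers are spelled as in the
#' profile, ready for indexing into it.
#'
#' @param set character vector of gene identifiers (a module or pathway).
#' @param profile a `fold_change_profile` (see [fold_changes()], [de_test()]).
#' @return list with `matched` (profile gene ids), `n_matched`,
#'   `n_in_set`, `unmatched` (set members absent from the profile).
#' @export
match_genes <- function(set, profile) {
  stopifnot(inherits(profile, "fold_change_profile"))
  set <- as.character(set)
  prof_key <- fold_id(profile$gene_id)
  set_key <- unique(fold_id(set))
  hit <- prof_key %in% set_key
  list(matched = profile$gene_id[hit],
       n_matched = sum(hit),
       n_in_set = length(set_key),
       unmatched = set[!fold_id(set) %in% prof_key])
}

# Fold-change lookup vector keyed by case-folded gene id.
profile_fc <- function(profile) {
  fc <- profile$log2_fc
  names(fc) <- fold_id(profile$gene_id)
  fc
}

stat_fun <- function(statistic) {
  switch(statistic,
         aafc = function(fc) mean(abs(fc)),
         afc  = function(fc) mean(fc),
         stop_input("unknown statistic '", statistic, "'"))
}

#' Aggregated absolute fold-change (AAFC) score
#'
#' Mean of the absolute log2 fold changes over the matched genes of a set:
#' a direction-blind measure of how strongly the set's genes move.
#'
#' @param profile a `fold_change_profile`.
#' @param genes character vector of gene identifiers already matched to the
#'   profile (see [match_genes()]).
#' @return a single non-negative number.
#' @export
aafc_score <- function(profile, genes) {
  set_score(profile, genes, "aafc")
}

#' Aggregate fold-change (AFC) score
#'
#' Mean of the signed log2 fold changes over the matched genes: positive
#' values indicate net upregulation, negative net downregulation. For any
#' input, `abs(afc) <= aafc` (triangle inequality).
#'
#' @inheritParams aafc_score
#' @return a single signed number.
#' @export
afc_score <- function(profile, genes) {
  set_score(profile, genes, "afc")
}

set_score <- function(profile, genes, statistic) {
  stopifnot(inherits(profile, "fold_change_profile"))
  genes <- unique(fold_id(genes))
  if (length(genes) == 0L)
    stop_input("cannot score an empty gene list")
  fc <- profile_fc(profile)
  missing <- setdiff(genes, names(fc))
  if (length(missing))
    stop_input("genes not in profile: ", paste(missing, collapse = ", "))
  stat_fun(statistic)(unname(fc[genes]))
}

#' Permutation null distribution for a set statistic
#'
#' Draws gene subsets of exactly `set_size` without replacement from the
#' profile's measured genes, scores each with the chosen statistic, and
#' returns the null mean, standard deviation (sample sd, denominator n - 1,
#' for Monte-Carlo draws; population sd for exhaustive enumeration) and the
#' score vector. When the number of distinct subsets is at most
#' `exhaustive_limit` (and `mode = "auto"`), all subsets are enumerated
#' instead of sampled, giving the exact null.
#'
#' @param profile a `fold_change_profile`.
#' @param set_size number of genes per null set, `1 <= set_size <=` genes in
#'   the profile.
#' @param statistic `"aafc"` or `"afc"`.
#' @param n_resamples Monte-Carlo draws (default 10000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param mode `"auto"` (exhaustive when cheap, else Monte-Carlo),
#'   `"monte_carlo"`, or `"exhaustive"`.
#' @param exhaustive_limit subset-count ceiling for auto-exhaustive mode.
#' @return list with `null_mean`, `null_sd`, `null_scores`, `mode`, `n`.
#' @export
permutation_null <- function(profile, set_size, statistic = c("aafc", "afc"),
                             n_resamples = 10000, seed = NULL,
                             mode = c("auto", "monte_carlo", "exhaustive"),
                             exhaustive_limit = 200000) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "fold_change_profile"))
  fc <- profile$log2_fc
  m <- length(fc)
  if (!is_count(set_size) || set_size < 1L || set_size > m)
    stop_input("set_size must be between 1 and the number of profiled genes (",
               m, ")")
  if (!is_count(n_resamples) || n_resamples < 100)
    stop_input("n_resamples must be at least 100")
  set_size <- as.integer(set_size)
  vals <- if (statistic == "aafc") abs(fc) else fc

  n_subsets <- choose(m, set_size)
  if (mode == "exhaustive" || (mode == "auto" && n_subsets <= exhaustive_limit)) {
    if (n_subsets > exhaustive_limit)
      stop_input("exhaustive enumeration requested but ", n_subsets,
                 " subsets exceed the limit of ", exhaustive_limit)
    idx <- utils::combn(m, set_size)
    scores <- colMeans(matrix(vals[idx], nrow = set_size))
    used_mode <- "exhaustive"
  } else {
    scores <- with_seed(seed, {
      idx <- vapply(seq_len(n_resamples),
                    function(i) sample.int(m, set_size),
                    integer(set_size))
      colMeans(matrix(vals[idx], nrow = set_size))
    })
    used_mode <- "monte_carlo"
  }
  n_sc <- length(scores)
  mu <- mean(scores)
  # Monte-Carlo draws estimate the null sd (denominator n - 1); exhaustive
  # enumeration IS the null population, so the population sd applies.
  sdv <- if (used_mode == "exhaustive") {
    sqrt(sum((scores - mu)^2) / n_sc)
  } else {
    stats::sd(scores)
  }
  list(null_mean = mu,
       null_sd = sdv,
       null_scores = scores,
       mode = used_mode,
       n = n_sc)
}

#' Score one module against a fold-change profile
#'
#' Computes the module's AAFC or AFC score, the permutation null over random
#' gene sets of the matched size, the z-score
#' `(score - null_mean) / null_sd`, an empirical p-value, and the activation
#' call (`z > activation_threshold`). For AAFC the empirical p is the upper
#' tail; for AFC it is two-sided around the null mean (both directions are
#' biologically meaningful). Monte-Carlo p-values carry the standard
#' `(r + 1) / (N + 1)` correction; exhaustive nulls report the exact tail
#' fraction. A degenerate null (`null_sd == 0`) yields `NA` z and p with a
#' warning, never a division by zero.
#'
#' @param profile a `fold_change_profile`.
#' @param set character vector of gene identifiers (the module).
#' @param statistic `"aafc"` (magnitude) or `"afc"` (directional).
#' @param n_resamples,seed,mode,exhaustive_limit passed to
#'   [permutation_null()].
#' @param activation_threshold z-score above which the module is called
#'   activated (default 2).
#' @param module_name label recorded in the result.
#' @return list of class `module_activation_result` with fields `module`,
#'   `n_genes_in_set`, `n_genes_matched`, `statistic`, `score`, `null_mean`,
#'   `null_sd`, `z_score`, `p_empirical`, `activated`, `null_mode`.
#' @export
score_module <- function(profile, set, statistic = c("aafc", "afc"),
                         n_resamples = 10000, seed = NULL,
                         activation_threshold = 2,
                         mode = c("auto", "monte_carlo", "exhaustive"),
                         exhaustive_limit = 200000,
                         module_name = "module") {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  mm <- match_genes(set, profile)
  if (mm$n_matched == 0L)
    stop_input("module '", module_name, "' matches no profiled gene")
  score <- set_score(profile, mm$matched, statistic)
  nul <- permutation_null(profile, mm$n_matched, statistic,
                          n_resamples = n_resamples, seed = seed,
                          mode = mode, exhaustive_limit = exhaustive_limit)
  if (nul$null_sd > 0) {
    z <- (score - nul$null_mean) / nul$null_sd
    r <- if (statistic == "aafc") {
      sum(nul$null_scores >= score)
    } else {
      sum(abs(nul$null_scores - nul$null_mean) >= abs(score - nul$null_mean))
    }
    p <- if (nul$mode == "exhaustive") r / nul$n else (r + 1) / (nul$n + 1)
    activated <- z > activation_threshold
  } else {
    warning("null distribution for module '", module_name,
            "' is degenerate (sd = 0); z undefined", call. = FALSE)
    z <- NA_real_
    p <- NA_real_
    activated <- FALSE
  }
  structure(list(module = module_name,
                 n_genes_in_set = mm$n_in_set,
                 n_genes_matched = mm$n_matched,
                 statistic = statistic,
                 score = score,
                 null_mean = nul$null_mean,
                 null_sd = nul$null_sd,
                 z_score = z,
                 p_empirical = p,
                 activated = activated,
                 null_mode = nul$mode),
            class = "module_activation_result")
}

#' @export
print.module_activation_result <- function(x, ...) {
  cat(sprintf("%s [%s]: score %.4g, null %.4g +/- %.4g, z %.3f, p %.4g%s\n",
              x$module, toupper(x$statistic), x$score, x$null_mean, x$null_sd,
              if (is.na(x$z_score)) NA else x$z_score, x$p_empirical,
              if (isTRUE(x$activated)) " *activated*" else ""))
  invisible(x)
}

#' Fit module activation scores across conditions
#'
#' The central fitting function: scores every gene-set module of a collection
#' on every fold-change profile with the chosen aggregate fold-change
#' statistic and a seeded permutation null, producing the module x condition
#' z-score table and activation calls. Each (module, condition) cell draws
#' its null from an independent RNG stream derived deterministically from the
#' top-level seed, so results do not depend on evaluation order. Per-cell
#' failures (e.g. a module matching no profiled gene) are recorded as flagged
#' rows, not run failures.
#'
#' @param profiles a single `fold_change_profile` or a named list of them
#'   (names are condition labels; unnamed lists are labelled from each
#'   profile's condition attribute).
#' @param modules a [gene_set_collection()].
#' @param statistic `"aafc"` (magnitude; upper-tail p) or `"afc"`
#'   (directional; two-sided p).
#' @param n_resamples permutation draws per cell (default 10000).
#' @param seed top-level integer seed.
#' @param activation_threshold z-score activation cut-off (default 2).
#' @param mode null evaluation mode, see [permutation_null()].
#' @return object of class `module_activation` with components `results`
#'   (long data frame), `z` (module x condition matrix), and the fit
#'   settings. Methods: `print`, `summary`, `coef` (the z matrix), `plot`,
#'   `as.data.frame`.
#' @examples
#' prof <- structure(
#'   data.frame(gene_id = paste0("g", 1:40),
#'              log2_fc = c(rep(2, 10), rnorm(30, 0, 0.3))),
#'   condition = list(platform = "in_vivo", dose = "high", time = "t1"),
#'   class = c("fold_change_profile", "data.frame"))
#' mods <- gene_set_collection(list(hit = paste0("g", 1:10),
#'                                  null = paste0("g", 21:30)))
#' fit <- module_activation(prof, mods, n_resamples = 200, seed = 1)
#' coef(fit)
#' @export
module_activation <- function(profiles, modules,
                              statistic = c("aafc", "afc"),
                              n_resamples = 10000, seed = 1,
                              activation_threshold = 2,
                              mode = c("auto", "monte_carlo", "exhaustive")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stopifnot(inherits(modules, "gene_set_collection"))
  if (inherits(profiles, "fold_change_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L)
    stop_input("at least one fold-change profile is required")
  labels <- names(profiles)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(profiles, function(p) condition_label(attr(p, "condition")),
                     character(1))
  }
  if (anyDuplicated(labels))
    stop_input("duplicate condition labels: ",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(profiles) <- labels

  rows <- vector("list", length(modules) * length(profiles))
  k <- 0L
  for (cond in labels) {
    for (mod in names(modules)) {
      k <- k + 1L
      cell_seed <- derive_seed(seed, mod, cond)
      rows[[k]] <- tryCatch({
        res <- withCallingHandlers(
          score_module(profiles[[cond]], set_genes(modules, mod),
                       statistic = statistic, n_resamples = n_resamples,
                       seed = cell_seed,
                       activation_threshold = activation_threshold,
                       mode = mode, module_name = mod),
          warning = function(w) invokeRestart("muffleWarning"))
        data.frame(module = mod, condition = cond,
                   n_genes_in_set = res$n_genes_in_set,
                   n_genes_matched = res$n_genes_matched,
                   score = res$score, null_mean = res$null_mean,
                   null_sd = res$null_sd, z_score = res$z_score,
                   p_empirical = res$p_empirical, activated = res$activated,
                   note = if (is.na(res$z_score)) "degenerate null" else "",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(module = mod, condition = cond,
                   n_genes_in_set = length(set_genes(modules, mod)),
                   n_genes_matched = 0L, score = NA_real_,
                   null_mean = NA_real_, null_sd = NA_real_,
                   z_score = NA_real_, p_empirical = NA_real_,
                   activated = FALSE, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), condition = character(),
               n_genes_in_set = integer(), n_genes_matched = integer(),
               score = numeric(), null_mean = numeric(), null_sd = numeric(),
               z_score = numeric(), p_empirical = numeric(),
               activated = logical(), note = character(),
               stringsAsFactors = FALSE)
  z <- matrix(NA_real_, nrow = length(modules), ncol = length(labels),
              dimnames = list(names(modules), labels))
  if (nrow(results) > 0L)
    z[cbind(results$module, results$condition)] <- results$z_score

  structure(list(results = results, z = z, statistic = statistic,
                 n_resamples = n_resamples, seed = seed,
                 activation_threshold = activation_threshold,
                 conditions = labels, modules = names(modules)),
            class = "module_activation")
}

#' Score all modules across conditions
#'
#' Alias for [module_activation()], named for the operation it performs.
#' @inheritParams module_activation
#' @return see [module_activation()].
#' @export
score_all_modules <- module_activation

#' @export
print.module_activation <- function(x, digits = 2, ...) {
  cat(sprintf("module_activation fit: %d modules x %d conditions (%s, N = %d, seed %d)\n",
              length(x$modules), length(x$conditions), toupper(x$statistic),
              x$n_resamples, x$seed))
  cat(sprintf("z-scores (activation threshold %g):\n", x$activation_threshold))
  print(round(x$z, digits))
  invisible(x)
}

#' @export
summary.module_activation <- function(object, ...) {
  act <- with(object$results, tapply(activated, condition, sum))
  structure(list(fit = object,
                 n_activated = act[object$conditions],
                 n_flagged = sum(object$results$note != "")),
            class = "summary.module_activation")
}

#' @export
print.summary.module_activation <- function(x, ...) {
  print(x$fit)
  cat("activated modules per condition:\n")
  print(x$n_activated)
  if (x$n_flagged > 0)
    cat(sprintf("%d flagged cell(s); see as.data.frame(fit)$note\n", x$n_flagged))
  invisible(x)
}

#' @export
coef.module_activation <- function(object, ...) object$z

#' @export
as.data.frame.module_activation <- function(x, ...) x$results

#' @export
plot.module_activation <- function(x, ...) {
  z <- x$z
  op <- graphics::par(mar = c(8, 10, 2, 2))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s activation z-scores", toupper(x$statistic)),
                  ...)
  graphics::axis(1, seq_len(ncol(z)), colnames(z), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(z)), rev(rownames(z)), las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
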