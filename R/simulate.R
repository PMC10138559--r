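#' Simulation design for a two-platform toxicant exposure study
#'
#' Describes the synthetic study layout: an in vivo and an in vitro platform,
#' dose levels with numeric effect multipliers (control = 0), exposure times
#' with their own multipliers, and small per-cohort sample sizes. The defaults
#' emulate a 2 platform x 2 dose x 2 time design with n = 3 animals or
#' cultures per cohort over a ~10^4-gene universe, with per-sample Gaussian
#' noise on the log2 scale.
#'
#' @param n_genes size of the gene universe (default 10000).
#' @param platforms character labels (default `in_vivo`, `in_vitro`).
#' @param doses named numeric vector of effect multipliers; must contain a
#'   `control` entry equal to 0 (default control 0, low 1, high 1.5).
#' @param times named numeric vector of time effect multipliers
#'   (default t1 = 1, t2 = 1.5).
#' @param n_control,n_treated samples per cohort (each >= 2, default 3).
#' @param baseline_log_mean,baseline_log_sd per-gene baseline expression
#'   distribution, log2 units (defaults 6 and 2).
#' @param noise_sd within-cohort per-sample noise, log2 units (default 0.5).
#' @param seed integer seed; fixes baselines, noise and all sampling.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 10000,
                              platforms = c("in_vivo", "in_vitro"),
                              doses = c(control = 0, low = 1, high = 1.5),
                              times = c(t1 = 1, t2 = 1.5),
                              n_control = 3, n_treated = 3,
                              baseline_log_mean = 6, baseline_log_sd = 2,
                              noise_sd = 0.5, seed = 1) {
  if (!is_count(n_genes) || n_genes < 1) stop_input("n_genes must be >= 1")
  if (n_control < 2 || n_treated < 2)
    stop_input("cohort sizes must be >= 2 (means and variances must be estimable)")
  if (is.null(names(doses)) || !"control" %in% names(doses))
    stop_input("'doses' must be a named vector with a 'control' entry")
  if (doses[["control"]] != 0) stop_input("the control dose multiplier must be 0")
  if (any(!is.finite(doses)) || any(doses < 0))
    stop_input("dose multipliers must be finite and non-negative")
  if (is.null(names(times)) || any(!is.finite(times)) || any(times < 0))
    stop_input("time multipliers must be named, finite and non-negative")
  if (noise_sd < 0 || baseline_log_sd < 0)
    stop_input("standard deviations must be non-negative")
  structure(list(n_genes = as.integer(n_genes), platforms = platforms,
                 doses = doses, times = times,
                 n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_design")
}

design_universe <- function(design) {
  sprintf("g%05d", seq_len(design$n_genes))
}

#' Planted module effect
#'
#' A set of genes shifted by a common base log2 effect. A fraction
#' `direction_mix` of the genes (the first ones, deterministically) move in
#' the direction of `effect_log2`; the rest move oppositely. Realized shifts
#' are deterministic per gene, so the simulation truth is exact.
#'
#' @param module_name label for the planted module.
#' @param gene_ids genes to perturb (must be in the simulated universe).
#' @param effect_log2 signed base effect at multiplier 1, log2 units.
#' @param direction_mix fraction of genes shifted with the sign of
#'   `effect_log2` (default 0.8: predominantly upregulation).
#' @return object of class `planted_effect` with a per-gene signed
#'   `gene_effects` vector.
#' @export
planted_effect <- function(module_name, gene_ids, effect_log2,
                           direction_mix = 0.8) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop_input("a planted effect needs >= 1 gene")
  if (anyDuplicated(gene_ids)) stop_input("duplicate genes in planted effect")
  if (!is.finite(effect_log2)) stop_input("effect_log2 must be finite")
  if (direction_mix < 0 || direction_mix > 1)
    stop_input("direction_mix must be in [0, 1]")
  n <- length(gene_ids)
  n_pos <- ceiling(direction_mix * n)
  signs <- rep(c(1, -1), c(n_pos, n - n_pos))
  structure(list(module_name = module_name, gene_ids = gene_ids,
                 effect_log2 = effect_log2, direction_mix = direction_mix,
                 gene_effects = stats::setNames(signs * effect_log2, gene_ids)),
            class = "planted_effect")
}

#' Generate reproducible gene-set modules from a universe
#'
#' Samples `n_modules` named gene sets of the requested sizes from the
#' universe. By default the sets are disjoint (sampled without replacement
#' across modules); with `disjoint = FALSE` each module is drawn
#' independently and overlaps may occur.
#'
#' @param n_modules number of sets.
#' @param sizes integer vector of set sizes, recycled to `n_modules`; each
#'   must be at most the universe size.
#' @param universe character vector of gene identifiers.
#' @param seed integer seed; identical seeds give identical collections.
#' @param disjoint logical, default `TRUE`.
#' @return a [gene_set_collection()] of kind `injury_module` with sets named
#'   `module_01`, `module_02`, ...
#' @export
generate_gene_sets <- function(n_modules, sizes, universe, seed = 1,
                               disjoint = TRUE) {
  if (!is_count(n_modules) || n_modules < 1)
    stop_input("n_modules must be a positive count")
  universe <- as.character(universe)
  sizes <- rep_len(as.integer(sizes), n_modules)
  if (any(sizes < 1)) stop_input("set sizes must be >= 1")
  if (any(sizes > length(universe)))
    stop_input("a requested set size exceeds the universe size (",
               length(universe), ")")
  if (disjoint && sum(sizes) > length(universe))
    stop_input("disjoint sets of total size ", sum(sizes),
               " cannot be drawn from a universe of ", length(universe))
  sets <- with_seed(seed, {
    if (disjoint) {
      picked <- sample(universe, sum(sizes))
      split(picked, rep(seq_len(n_modules), sizes))
    } else {
      lapply(sizes, function(k) sample(universe, k))
    }
  })
  names(sets) <- sprintf("module_%02d", seq_len(n_modules))
  gene_set_collection(sets, kind = "injury_module")
}

#' Simulate a multi-condition toxicogenomic expression experiment
#'
#' For every (platform, time) stratum one control cohort and one treated
#' cohort per non-control dose are generated. Gene `g`'s log2 expression in a
#' sample is `baseline(g) + shift(g, condition) + noise`, where
#' `shift = gene_effect(g) * dose_multiplier * time_multiplier` for planted
#' genes and 0 otherwise, and noise is i.i.d. Gaussian with sd
#' `design$noise_sd`. The expected log2 fold change of a planted gene
#' therefore equals its realized shift exactly. An optional count mode draws
#' negative-binomial counts around the same expected expression and returns
#' `log2(count + 1)`.
#'
#' @param design a [simulation_design()].
#' @param effects list of [planted_effect()] objects (may be empty).
#' @param noise_model `"gaussian"` (default) or `"negbin"`.
#' @param nb_dispersion negative-binomial dispersion (count mode only).
#' @return list of class `synthetic_experiment`:
#'   \describe{
#'     \item{matrix}{one [expression_matrix()] (log2) holding all samples}
#'     \item{sample_sheet}{data frame `sample_id, platform, dose, time, cohort`}
#'     \item{pairs}{named list of [cohort_pair()] per treatment condition}
#'     \item{truth}{`synthetic_truth`: design, effects, the gene x condition
#'       realized shift table, planted/null gene flags, seed}
#'   }
#' @export
simulate_experiment <- function(design, effects = list(),
                                noise_model = c("gaussian", "negbin"),
                                nb_dispersion = 0.05) {
  stopifnot(inherits(design, "simulation_design"))
  noise_model <- match.arg(noise_model)
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  universe <- design_universe(design)
  gene_effects <- stats::setNames(numeric(design$n_genes), universe)
  for (ef in effects) {
    stopifnot(inherits(ef, "planted_effect"))
    unknown <- setdiff(ef$gene_ids, universe)
    if (length(unknown))
      stop_input("planted effect '", ef$module_name,
                 "' references genes outside the universe: ",
                 paste(utils::head(unknown, 5), collapse = ", "))
    gene_effects[ef$gene_ids] <- ef$gene_effects
  }
  planted <- names(gene_effects)[gene_effects != 0]

  treat_doses <- design$doses[names(design$doses) != "control"]
  conditions <- expand.grid(platform = design$platforms,
                            dose = names(treat_doses),
                            time = names(design$times),
                            stringsAsFactors = FALSE)
  cond_labels <- apply(conditions, 1, paste, collapse = "_")

  # Realized per-condition shifts (exact truth).
  shift_tab <- vapply(seq_len(nrow(conditions)), function(i) {
    gene_effects * treat_doses[[conditions$dose[i]]] *
      design$times[[conditions$time[i]]]
  }, numeric(design$n_genes))
  shift_tab <- matrix(shift_tab, nrow = design$n_genes,
                      dimnames = list(universe, NULL))
  colnames(shift_tab) <- cond_labels

  sim <- with_seed(design$seed, {
    baseline <- stats::rnorm(design$n_genes, design$baseline_log_mean,
                             design$baseline_log_sd)
    draw_cohort <- function(n, shift) {
      mu <- baseline + shift
      x <- mu + matrix(stats::rnorm(design$n_genes * n, 0, design$noise_sd),
                       design$n_genes, n)
      if (noise_model == "negbin") {
        counts <- matrix(stats::rnbinom(length(x), mu = pmax(2^x - 1, 0),
                                        size = 1 / nb_dispersion),
                         design$n_genes, n)
        x <- log2(counts + 1)
      }
      x
    }
    cols <- list(); sheet <- list()
    for (pf in design$platforms) {
      for (tm in names(design$times)) {
        ids <- sprintf("%s_control_%s_c%d", pf, tm, seq_len(design$n_control))
        ctrl <- draw_cohort(design$n_control, 0)
        colnames(ctrl) <- ids
        cols[[length(cols) + 1L]] <- ctrl
        sheet[[length(sheet) + 1L]] <- data.frame(
          sample_id = ids, platform = pf, dose = "control", time = tm,
          cohort = "control", stringsAsFactors = FALSE)
        for (ds in names(treat_doses)) {
          lab <- paste(pf, ds, tm, sep = "_")
          ids <- sprintf("%s_t%d", lab, seq_len(design$n_treated))
          trt <- draw_cohort(design$n_treated, shift_tab[, lab])
          colnames(trt) <- ids
          cols[[length(cols) + 1L]] <- trt
          sheet[[length(sheet) + 1L]] <- data.frame(
            sample_id = ids, platform = pf, dose = ds, time = tm,
            cohort = "treated", stringsAsFactors = FALSE)
        }
      }
    }
    list(values = do.call(cbind, cols), sheet = do.call(rbind, sheet))
  })
  rownames(sim$values) <- universe
  em <- expression_matrix(sim$values, is_log2 = TRUE)

  pairs <- stats::setNames(lapply(seq_len(nrow(conditions)), function(i) {
    pf <- conditions$platform[i]; ds <- conditions$dose[i]
    tm <- conditions$time[i]
    ss <- sim$sheet
    cohort_pair(list(platform = pf, dose = ds, time = tm),
                control = ss$sample_id[ss$platform == pf & ss$time == tm &
                                         ss$cohort == "control"],
                treated = ss$sample_id[ss$platform == pf & ss$time == tm &
                                         ss$dose == ds])
  }), cond_labels)

  truth <- structure(list(design = design, effects = effects,
                          realized_effect_table = shift_tab[planted, ,
                                                            drop = FALSE],
                          planted_genes = planted,
                          null_genes = setdiff(universe, planted),
                          seed = design$seed),
                     class = "synthetic_truth")
  structure(list(matrix = em, sample_sheet = sim$sheet, pairs = pairs,
                 truth = truth),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic_experiment: %d genes, %d samples, %d conditions, %d planted genes (seed %d)\n",
              nrow(x$matrix$values), ncol(x$matrix$values), length(x$pairs),
              length(x$truth$planted_genes), x$truth$seed))
  invisible(x)
}
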