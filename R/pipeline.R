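#' Default run configuration
#'
#' The tunable constants of the pipeline: FDR threshold 0.1 for DEG calls,
#' z-score activation threshold 2, 10000 permutation resamples, pseudocount 1
#' for the log2 transform, AAFC as the module statistic.
#'
#' @param ... overrides of the defaults (unknown keys are an error).
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, q_threshold = 0.1, z_threshold = 2,
              n_resamples = 10000L, pseudocount = 1, statistic = "aafc",
              # input paths (NULL => simulate)
              matrix = NULL, samples = NULL, gmt = NULL, categories = NULL,
              # simulation block (used when matrix is NULL)
              n_genes = 2000L, n_modules = 8L, module_size = 50L,
              n_planted_modules = 3L, effect_log2 = 2, direction_mix = 0.8,
              noise_sd = 0.5, n_control = 3L, n_treated = 3L,
              baseline_log_mean = 6, baseline_log_sd = 2,
              dose_multipliers = c(control = 0, low = 1, high = 1.5),
              time_multipliers = c(t1 = 1, t2 = 1.5),
              out = NULL)
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  if (cfg$q_threshold <= 0 || cfg$z_threshold <= 0)
    stop_input("thresholds must be positive")
  if (cfg$n_resamples < 100) stop_input("n_resamples must be >= 100")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat key namespace mirroring [run_config()]; values in the file override
#' the defaults, and `...` overrides the file (CLI over file over defaults).
#'
#' @param path YAML file path.
#' @param ... further overrides.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  for (k in c("dose_multipliers", "time_multipliers"))
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  do.call(run_config, utils::modifyList(y %||% list(), list(...)))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes differential expression, module scoring, directional pathway
#' scoring and cross-condition comparison over every (platform, dose, time)
#' condition in the sample sheet, writing all result tables plus a JSON run
#' manifest to `out`. With no input matrix configured, a synthetic experiment
#' is generated first (planting `n_planted_modules` of the generated modules
#' with `effect_log2`) and its inputs are written alongside the results, so a
#' default run is fully self-contained and reproducible from the manifest.
#'
#' Outputs under `out/`: `expression_matrix.tsv`, `sample_sheet.csv`,
#' `modules.gmt`, `truth.json` (simulated runs); per-condition
#' `profile_<condition>.tsv` and `degs_<condition>.tsv`;
#' `module_zscores.tsv` (modules x conditions), `module_results.tsv`
#' (long form), `pathway_directions.tsv`, `deg_overlap.tsv`,
#' `common_gene_ranking.tsv`, `score_correlations.tsv`, `manifest.json`.
#'
#' @param config a [run_config()], a YAML path, or a plain list of overrides.
#' @param out output directory (created if absent); overrides `config$out`.
#' @return the manifest, invisibly (list with config, checksums, warnings).
#' @export
run_pipeline <- function(config = run_config(), out = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  out <- out %||% config$out
  if (is.null(out)) stop_input("an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  inputs <- character()

  withCallingHandlers({
    if (is.null(config$matrix)) {
      sim <- simulate_default(config)
      em <- sim$matrix; sheet <- sim$sample_sheet; pairs <- sim$pairs
      modules <- sim$modules
      write_expression_tsv(em, file.path(out, "expression_matrix.tsv"))
      write_sample_sheet(sheet, file.path(out, "sample_sheet.csv"))
      write_gmt(modules, file.path(out, "modules.gmt"))
      jsonlite::write_json(
        list(seed = sim$truth$seed,
             planted_genes = sim$truth$planted_genes,
             realized_effect_table = as.data.frame(sim$truth$realized_effect_table)),
        file.path(out, "truth.json"))
      inputs <- file.path(out, c("expression_matrix.tsv", "sample_sheet.csv",
                                 "modules.gmt"))
    } else {
      if (is.null(config$samples) || is.null(config$gmt))
        stop_input("configs with an input matrix also need 'samples' and 'gmt'")
      missing <- Filter(Negate(file.exists),
                        c(config$matrix, config$samples, config$gmt))
      if (length(missing))
        stop_input("missing required input(s): ", paste(missing, collapse = ", "))
      em <- read_expression_tsv(config$matrix, is_log2 = TRUE,
                                pseudocount = config$pseudocount)
      sheet <- read_sample_sheet(config$samples)
      modules <- read_gmt(config$gmt)
      pairs <- pairs_from_sheet(sheet)
      inputs <- c(config$matrix, config$samples, config$gmt)
    }

    # Differential expression per condition.
    profiles <- list(); deg_sets <- list()
    for (lab in names(pairs)) {
      prof <- de_test(em, pairs[[lab]])
      profiles[[lab]] <- prof
      deg_sets[[lab]] <- call_degs(prof, config$q_threshold)
      write_profile_tsv(prof, file.path(out, paste0("profile_", lab, ".tsv")))
      utils::write.table(
        data.frame(gene_id = deg_sets[[lab]]$gene_ids),
        file.path(out, paste0("degs_", lab, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # Module activation scoring.
    fit <- module_activation(profiles, modules, statistic = config$statistic,
                             n_resamples = config$n_resamples,
                             seed = config$seed,
                             activation_threshold = config$z_threshold)
    zt <- data.frame(module = rownames(fit$z), signif(fit$z, 6),
                     check.names = FALSE)
    utils::write.table(zt, file.path(out, "module_zscores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    long <- fit$results
    num <- vapply(long, is.numeric, logical(1))
    long[num] <- lapply(long[num], signif, 6)
    utils::write.table(long, file.path(out, "module_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # Directional pathway scoring (modules reused as sets when no pathway
    # GMT is configured; categories optional).
    categories <- if (!is.null(config$categories))
      utils::read.delim(config$categories, header = FALSE,
                        col.names = c("pathway", "category")) else NULL
    pw <- score_pathways_directional(profiles, modules,
                                     categories = categories,
                                     n_resamples = config$n_resamples,
                                     seed = config$seed,
                                     z_threshold = config$z_threshold)
    numpw <- vapply(pw, is.numeric, logical(1))
    pw[numpw] <- lapply(pw[numpw], signif, 6)
    utils::write.table(pw, file.path(out, "pathway_directions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # Cross-condition comparison.
    om <- overlap_matrix(deg_sets)
    utils::write.table(data.frame(condition = rownames(om), unclass(om),
                                  check.names = FALSE),
                       file.path(out, "deg_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    core <- tryCatch(common_genes(deg_sets), error = function(e) character())
    if (length(core) > 0L) {
      ranking <- rank_by_mean_fc(core, profiles)
      ranking$mean_log2_fc <- signif(ranking$mean_log2_fc, 6)
      utils::write.table(ranking, file.path(out, "common_gene_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cors <- condition_correlations(fit$z)
    utils::write.table(cors, file.path(out, "score_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, warning = log_warning)

  outputs <- setdiff(list.files(out, full.names = TRUE),
                     file.path(out, "manifest.json"))
  manifest <- list(
    tool = "toxmod",
    version = as.character(utils::packageVersion("toxmod")),
    config = unclass(config),
    input_md5 = as.list(md5_of(inputs)),
    output_md5 = as.list(md5_of(outputs)),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Simulate the default synthetic experiment described by a run_config.
simulate_default <- function(config) {
  design <- simulation_design(
    n_genes = config$n_genes,
    doses = config$dose_multipliers, times = config$time_multipliers,
    n_control = config$n_control, n_treated = config$n_treated,
    baseline_log_mean = config$baseline_log_mean,
    baseline_log_sd = config$baseline_log_sd,
    noise_sd = config$noise_sd, seed = config$seed)
  modules <- generate_gene_sets(config$n_modules, config$module_size,
                                design_universe(design),
                                seed = derive_seed(config$seed, "gene_sets"))
  n_plant <- min(config$n_planted_modules, length(modules))
  effects <- lapply(seq_len(n_plant), function(i) {
    planted_effect(names(modules)[i], set_genes(modules, names(modules)[i]),
                   effect_log2 = config$effect_log2,
                   direction_mix = config$direction_mix)
  })
  sim <- simulate_experiment(design, effects)
  sim$modules <- modules
  sim
}

# Build cohort pairs from a sample sheet: each treated (platform, dose, time)
# cohort is paired with the control cohort of the same platform and time.
pairs_from_sheet <- function(sheet) {
  trt <- unique(sheet[sheet$cohort == "treated",
                      c("platform", "dose", "time")])
  if (nrow(trt) == 0L) stop_input("sample sheet contains no treated cohort")
  pairs <- list()
  for (i in seq_len(nrow(trt))) {
    pf <- trt$platform[i]; ds <- trt$dose[i]; tm <- trt$time[i]
    ctrl <- sheet$sample_id[sheet$platform == pf & sheet$time == tm &
                              sheet$cohort == "control"]
    tre <- sheet$sample_id[sheet$platform == pf & sheet$time == tm &
                             sheet$dose == ds & sheet$cohort == "treated"]
    pairs[[paste(pf, ds, tm, sep = "_")]] <-
      cohort_pair(list(platform = pf, dose = ds, time = tm), ctrl, tre)
  }
  pairs
}

# All pairwise correlations between condition z-score columns.
condition_correlations <- function(z) {
  conds <- colnames(z)
  if (length(conds) < 2L || nrow(z) < 3L)
    return(data.frame(condition_a = character(), condition_b = character(),
                      pearson_r = numeric(), r_squared = numeric()))
  combos <- utils::combn(conds, 2)
  rows <- apply(combos, 2, function(cc) {
    ok <- stats::complete.cases(z[, cc])
    if (sum(ok) < 3L || stats::sd(z[ok, cc[1]]) == 0 ||
        stats::sd(z[ok, cc[2]]) == 0)
      return(data.frame(condition_a = cc[1], condition_b = cc[2],
                        pearson_r = NA_real_, r_squared = NA_real_))
    cs <- correlate_scores(z[ok, cc[1]], z[ok, cc[2]])
    data.frame(condition_a = cc[1], condition_b = cc[2],
               pearson_r = signif(cs$pearson_r, 6),
               r_squared = signif(cs$r_squared, 6))
  })
  do.call(rbind, rows)
}
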