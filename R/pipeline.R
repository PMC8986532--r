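# End-to-end orchestration: ingest -> pacemaker/clock -> GAMM selection ->
# seasonal inference -> sitewise scan, with every artifact written to a run
# directory together with the configuration and seeds that produced it.

#' Run configuration for the full pipeline
#'
#' @param sample_table Path to a sample table CSV, or a ready data.frame.
#' @param beta_matrix Path to a beta matrix, a [beta_matrix()], or `NULL`.
#'   Without methylation data the pacemaker/clock stages are skipped and
#'   downstream stages use the table's `epigenetic_state` / `clock_age`
#'   columns.
#' @param dialect,doy_origin Passed to [read_sample_table()] for paths.
#' @param corr_threshold Site-selection cutoff for the pacemaker.
#' @param alpha Elastic-net mixing weight.
#' @param k Spline basis dimension.
#' @param n_reps Replicates for each simulation stage.
#' @param alpha_level Significance level.
#' @param run_simulations,run_sitewise Stage switches.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sample_table, beta_matrix = NULL,
                       dialect = "generic", doy_origin = "may1",
                       corr_threshold = 0.7, alpha = 0.5, k = 10L,
                       n_reps = 1000L, alpha_level = 0.05,
                       run_simulations = TRUE, run_sitewise = TRUE,
                       seed = 1L) {
  structure(list(sample_table = sample_table, beta_matrix = beta_matrix,
                 dialect = dialect, doy_origin = doy_origin,
                 corr_threshold = corr_threshold, alpha = alpha,
                 k = as.integer(k), n_reps = as.integer(n_reps),
                 alpha_level = alpha_level,
                 run_simulations = run_simulations,
                 run_sitewise = run_sitewise, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest; pacemaker cross-validated states and clock
#' grouped-holdout ages (when methylation data are supplied); eight-model
#' GAMM selection on the epigenetic states; seasonal power / null /
#' permutation simulations; consecutive-season rate contrast with a
#' Kruskal-Wallis test; sitewise EWAS + GAM scan with multiplicity
#' summaries. Each stage's artifact is written to `out_dir` as JSON/CSV
#' with the config hash and seeds embedded in `report.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A list of stage results (also collated into
#'   `<out_dir>/report.json`).
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  table <- if (is.character(config$sample_table))
    read_sample_table(config$sample_table, config$dialect, config$doy_origin)
  else validate_sample_table(config$sample_table)
  beta <- config$beta_matrix
  if (is.character(beta)) beta <- read_beta_matrix(beta)

  res <- list(config = unclass(config[!vapply(config, is.object, TRUE)]))
  res$n_samples <- nrow(table)
  res$n_individuals <- length(unique(table$animal_id))
  res$max_age <- max(table$age)

  if (!is.null(beta)) {
    beta <- beta[, table$sample_id, drop = FALSE]
    class(beta) <- c("beta_matrix", "matrix", "array")
    cv <- cross_validate_epm(beta, table$age, threshold = config$corr_threshold,
                             seed = config$seed)
    table$epigenetic_state <- cv$states
    res$epm <- list(site_counts = cv$site_counts,
                    metrics = accuracy_metrics(cv$states, table$age))
    ho <- grouped_holdout_predictions(beta, table$age, seed = config$seed,
                                      alpha = config$alpha)
    table$clock_age <- ho$predicted
    res$clock <- list(n_folds = ho$n_folds, n_sites_used = length(ho$sites_used),
                      metrics = accuracy_metrics(ho$predicted, table$age))
  }
  if (is.null(table$epigenetic_state))
    stop("no epigenetic_state available: supply methylation data or a table with states")

  sel <- select_model(table$epigenetic_state, table,
                      candidate_fixed_effects(k = config$k))
  res$model_selection <- list(table = sel$table, best = sel$best)
  final <- sel$fits[["spl_age_cyc_doy"]]
  res$state_gamm <- list(intercept = final$intercept,
                         var_individual = final$var_individual,
                         var_residual = final$var_residual,
                         adj_r2 = final$adj_r2,
                         age = smooth_term_test(final, "age"),
                         season = smooth_term_test(final, "doy"))
  if (!is.null(table$clock_age)) {
    fit_ec <- fit_gamm(table$clock_age, table,
                       list(age_spline("age", config$k), doy_spline("doy", config$k)))
    res$clock_gamm <- list(intercept = fit_ec$intercept,
                           season = smooth_term_test(fit_ec, "doy"))
  }

  if (all(c("season", "abs_day") %in% names(table))) {
    rates <- consecutive_year_rates(table)
    kw <- if (nrow(rates) >= 2)
      kruskal_wallis(rates$active_rate, rates$hibernation_rate) else NULL
    res$rates <- list(n_individuals = nrow(rates), rates = rates,
                      kruskal_wallis = kw)
  }

  if (config$run_simulations && all(c("abs_day", "birth_abs") %in% names(table))) {
    res$power <- unclass(run_power_simulation(
      table, trait_config(), n_reps = config$n_reps,
      alpha = config$alpha_level, seed = config$seed + 1L, k = config$k))
    res$null <- unclass(run_null_simulation(
      table, trait_config(), n_reps = config$n_reps,
      alpha = config$alpha_level, seed = config$seed + 2L, k = config$k))
    res$permutation <- unclass(run_permutation_null(
      table$epigenetic_state, table, n_reps = config$n_reps,
      alpha = config$alpha_level, seed = config$seed + 3L, k = config$k))
  }

  if (config$run_sitewise && !is.null(beta)) {
    ew <- ewas_age(beta, table)
    gs <- gam_scan(beta, table, k = config$k)
    thr <- 1e-5
    res$sitewise <- list(
      ewas = multiplicity_thresholds(ew$p),
      gam_age = multiplicity_thresholds(gs$age_p),
      overlap = overlap_summary(ew$site_id[!is.na(ew$p) & ew$p < thr],
                                gs$site_id[!is.na(gs$age_p) & gs$age_p < thr],
                                gs$site_id[!is.na(gs$season_p) & gs$season_p < thr]))
    if (!is.null(out_dir)) {
      utils::write.csv(ew, file.path(out_dir, "ewas_age.csv"), row.names = FALSE)
      utils::write.csv(gs, file.path(out_dir, "gam_scan.csv"), row.names = FALSE)
    }
  }

  if (!is.null(out_dir)) {
    write_sample_table(table, file.path(out_dir, "sample_table.csv"))
    json <- res
    json$model_selection$table <- as.list(res$model_selection$table)
    json$rates$rates <- as.list(res$rates$rates)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  res
}
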