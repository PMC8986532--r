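# Tests of the hibernation-ageing hypothesis: simulation-based power and
# type-I error for the seasonal (cyclic spline) term, a permutation null
# over day-of-year labels, empirically adjusted critical values, and the
# active-versus-hibernation ageing-rate contrast for animals sampled in
# consecutive active seasons.

# seasonal-term p-value from the carried-forward model:
# spline age + cyclic doy + animal random intercept
.season_p <- function(y, data, k = 10L) {
  fit <- fit_gamm(y, data, list(age_spline("age", k), doy_spline("doy", k)),
                  random_intercept = "animal_id", method = "ML")
  list(p = smooth_term_test(fit, "doy")$p, converged = fit$converged)
}

.sim_result <- function(p_values, alpha, n_failed, seed) {
  structure(list(n_reps = length(p_values), p_values = p_values,
                 rejection_rate = mean(p_values < alpha),
                 adjusted_critical_value = unname(stats::quantile(p_values, 0.05, type = 7)),
                 alpha = alpha, n_failed = n_failed, seed = seed),
            class = "simulation_result")
}

#' Power simulation for the seasonal term
#'
#' Per replicate, simulates the seasonal trait (accrual only on active
#' days) on the fixed sampling design, fits the carried-forward GAMM
#' (cubic age spline + cyclic day-of-year spline + animal random
#' intercept), and records the seasonal-term p-value. The rejection
#' proportion at `alpha` estimates power under the design's active-season-
#' only sampling.
#'
#' @param design Sampling design (from [generate_design()] or field data
#'   with `abs_day`/`birth_abs` columns).
#' @param trait_cfg A [trait_config()]; its seed is re-derived per
#'   replicate from `seed`.
#' @param n_reps Replicates (default 1000).
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed.
#' @param k Spline basis dimension.
#' @return A `simulation_result`: `p_values`, `rejection_rate`,
#'   `adjusted_critical_value` (0.05 quantile of the p distribution),
#'   `n_failed` (non-convergent replicates, excluded).
#' @export
run_power_simulation <- function(design, trait_cfg = trait_config(),
                                 n_reps = 1000L, alpha = 0.05, seed = 1L,
                                 k = 10L) {
  .run_trait_simulation(design, trait_cfg, seasonal = TRUE, n_reps = n_reps,
                        alpha = alpha, seed = seed, k = k)
}

#' Null (type-I error) simulation for the seasonal term
#'
#' As [run_power_simulation()] but the simulated trait increases linearly
#' with age independently of season, so rejections are false positives:
#' the rejection proportion estimates the type-I error and the 0.05
#' quantile of the null p distribution is the adjusted critical value that
#' restores a 5% error rate.
#'
#' @inheritParams run_power_simulation
#' @return A `simulation_result`.
#' @export
run_null_simulation <- function(design, trait_cfg = trait_config(),
                                n_reps = 1000L, alpha = 0.05, seed = 1L,
                                k = 10L) {
  .run_trait_simulation(design, trait_cfg, seasonal = FALSE, n_reps = n_reps,
                        alpha = alpha, seed = seed, k = k)
}

.run_trait_simulation <- function(design, trait_cfg, seasonal, n_reps, alpha,
                                  seed, k) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  p <- rep(NA_real_, n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- trait_cfg
    cfg$seed <- rep_seeds[r]
    y <- simulate_trait(design, cfg, seasonal = seasonal)
    res <- tryCatch(.season_p(y, design, k), error = function(e) NULL)
    if (is.null(res) || !res$converged) failed <- failed + 1L
    else p[r] <- res$p
  }
  .sim_result(p[!is.na(p)], alpha, failed, seed)
}

#' Permutation null for the seasonal term
#'
#' Per replicate, shuffles the day-of-year labels across samples (leaving
#' everything else fixed), refits the carried-forward GAMM on the observed
#' response, and records the seasonal-term p-value. The rejection
#' proportion estimates the type-I error under the observed response and
#' design; the 0.05 quantile gives the adjusted significance threshold.
#'
#' @param y Observed epigenetic states, aligned with `data`.
#' @param data Sample table.
#' @inheritParams run_power_simulation
#' @return A `simulation_result`.
#' @export
run_permutation_null <- function(y, data, n_reps = 1000L, alpha = 0.05,
                                 seed = 1L, k = 10L) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  stopifnot(length(y) == nrow(data))
  set.seed(seed)
  p <- rep(NA_real_, n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    d <- data
    d$doy <- sample(d$doy)
    res <- tryCatch(.season_p(y, d, k), error = function(e) NULL)
    if (is.null(res) || !res$converged) failed <- failed + 1L
    else p[r] <- res$p
  }
  .sim_result(p[!is.na(p)], alpha, failed, seed)
}

#' Active- and hibernation-season epigenetic ageing rates
#'
#' Restricts the table to animals sampled in consecutive active seasons
#' with at least 2 samples in one season and at least 1 in the other. For
#' each such animal, the active rate is the state difference between the
#' latest and earliest sample within the season holding >= 2 samples,
#' divided by the days between them; the hibernation rate is the state
#' difference between the first sample after the intervening hibernation
#' and the last sample before it, divided by the days between the two
#' collections.
#'
#' Seasons are indexed so that the late-April tail (study doy >= 353)
#' belongs to the following summer's active season; the table must carry
#' `season` and `abs_day` columns (as produced by [generate_design()]).
#'
#' @param table Sample table with `epigenetic_state`, `season`, `abs_day`.
#' @return A data.frame with one row per eligible animal: `animal_id`,
#'   `active_rate`, `hibernation_rate` (state units per day),
#'   `active_season` (the season supplying the active interval).
#' @export
consecutive_year_rates <- function(table) {
  need <- c("animal_id", "epigenetic_state", "season", "abs_day")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyNA(table$epigenetic_state)) stop("epigenetic_state has missing values")
  out <- list()
  for (id in unique(table$animal_id)) {
    x <- table[table$animal_id == id, ]
    x <- x[order(x$abs_day), ]
    tb <- table(x$season)
    seasons <- as.integer(names(tb))
    pair <- NULL
    for (s in seasons) {
      if (!((s + 1L) %in% seasons)) next
      n1 <- tb[[as.character(s)]]; n2 <- tb[[as.character(s + 1L)]]
      if (max(n1, n2) >= 2L && min(n1, n2) >= 1L) { pair <- c(s, s + 1L); break }
    }
    if (is.null(pair)) next
    active_season <- if (tb[[as.character(pair[1])]] >= 2L) pair[1] else pair[2]
    a <- x[x$season == active_season, ]
    span <- a$abs_day[nrow(a)] - a$abs_day[1]
    if (span == 0) { warning("zero-day active span for ", id, "; skipped"); next }
    active_rate <- (a$epigenetic_state[nrow(a)] - a$epigenetic_state[1]) / span
    before <- x[x$season == pair[1], ]; after <- x[x$season == pair[2], ]
    h_span <- after$abs_day[1] - before$abs_day[nrow(before)]
    if (h_span == 0) { warning("zero-day hibernation span for ", id, "; skipped"); next }
    hib_rate <- (after$epigenetic_state[1] - before$epigenetic_state[nrow(before)]) / h_span
    out[[id]] <- data.frame(animal_id = id, active_rate = active_rate,
                            hibernation_rate = hib_rate,
                            active_season = active_season,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(animal_id = character(0), active_rate = numeric(0),
                      hibernation_rate = numeric(0), active_season = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis rank-sum test for two groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution
#' (df = 1 for two groups). When every value across both groups is
#' identical the statistic is defined as 0 (no rank separation).
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (length(unique(c(group_a, group_b))) == 1L)
    return(list(H = 0, df = 1L, p = 1))
  kt <- stats::kruskal.test(list(group_a, group_b))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}
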