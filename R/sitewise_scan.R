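# Per-CpG association scans: mixed-model EWAS of chronological age,
# per-site GAMs with an age spline and a cyclic seasonal spline,
# multiplicity thresholds, and overlap summaries.

#' Mixed-model EWAS of chronological age
#'
#' Per site, fits a linear mixed model of methylation on chronological age
#' with an animal-level random intercept (or plain least squares when
#' `random_intercept = FALSE`). The slope sign gives the direction of the
#' age association (hyper- vs hypomethylation). P-values use a normal
#' approximation to the slope's t statistic by default; with
#' `df_method = "satterthwaite"` (requires lmerTest) a Satterthwaite
#' correction is applied.
#'
#' @param beta A [beta_matrix()].
#' @param table Sample table aligned with the matrix columns.
#' @param random_intercept Include the animal random intercept (default
#'   `TRUE`).
#' @param df_method `"normal"` or `"satterthwaite"`.
#' @return A data.frame with one row per site: `site_id`, `slope`, `se`,
#'   `p`, `direction` (`"hyper"`/`"hypo"`). Sites that are constant or fail
#'   to converge carry `NA` values and are never silently dropped.
#' @export
ewas_age <- function(beta, table, random_intercept = TRUE,
                     df_method = c("normal", "satterthwaite")) {
  df_method <- match.arg(df_method)
  stopifnot(ncol(beta) == nrow(table))
  if (df_method == "satterthwaite" && !requireNamespace("lmerTest", quietly = TRUE))
    stop("df_method = 'satterthwaite' requires the lmerTest package")
  d <- data.frame(age = table$age, animal = factor(table$animal_id))
  out <- data.frame(site_id = rownames(beta), slope = NA_real_, se = NA_real_,
                    p = NA_real_, direction = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(beta))) {
    y <- unclass(beta)[i, ]
    if (stats::sd(y) == 0) next
    res <- tryCatch({
      if (random_intercept) {
        if (df_method == "satterthwaite") {
          m <- lmerTest::lmer(y ~ age + (1 | animal), data = d,
                              control = lme4::lmerControl(check.conv.singular = "ignore",
                                                          check.conv.grad = "ignore",
                                                          check.conv.hess = "ignore"))
          co <- stats::coef(summary(m))["age", ]
          c(co[["Estimate"]], co[["Std. Error"]], co[["Pr(>|t|)"]])
        } else {
          m <- lme4::lmer(y ~ age + (1 | animal), data = d,
                          control = lme4::lmerControl(check.conv.singular = "ignore",
                                                          check.conv.grad = "ignore",
                                                          check.conv.hess = "ignore"))
          co <- stats::coef(summary(m))["age", ]
          t <- co[["t value"]]
          c(co[["Estimate"]], co[["Std. Error"]], 2 * stats::pnorm(-abs(t)))
        }
      } else {
        m <- stats::lm(y ~ age, data = d)
        co <- stats::coef(summary(m))["age", ]
        c(co[["Estimate"]], co[["Std. Error"]], co[["Pr(>|t|)"]])
      }
    }, error = function(e) NULL)
    if (is.null(res)) next
    out$slope[i] <- res[1]; out$se[i] <- res[2]; out$p[i] <- res[3]
    out$direction[i] <- if (res[1] >= 0) "hyper" else "hypo"
  }
  out
}

#' Per-site GAM scan for age and season effects
#'
#' Per site, fits a GAM of methylation on a cubic spline of chronological
#' age plus a cyclic cubic spline of day of year (no random intercept by
#' default: single-site models are treated as GAMs, switchable) and
#' reports the smooth-term tests.
#'
#' @param beta A [beta_matrix()].
#' @param table Sample table with `age`, `doy` (and `animal_id` when
#'   `random_intercept = TRUE`).
#' @param k Spline basis dimension (default 10).
#' @param random_intercept Include the animal random intercept (default
#'   `FALSE`).
#' @param method Smoothing-parameter criterion (default `"REML"`, the
#'   stable choice for single-model smoothness estimation).
#' @return A data.frame per site: `site_id`, `age_edf`, `age_p`,
#'   `season_edf`, `season_p`. Failed sites carry `NA`.
#' @export
gam_scan <- function(beta, table, k = 10L, random_intercept = FALSE,
                     method = "REML") {
  stopifnot(ncol(beta) == nrow(table))
  out <- data.frame(site_id = rownames(beta), age_edf = NA_real_,
                    age_p = NA_real_, season_edf = NA_real_,
                    season_p = NA_real_, stringsAsFactors = FALSE)
  fixed <- list(age_spline("age", k), doy_spline("doy", k))
  re <- if (random_intercept) "animal_id" else NULL
  for (i in seq_len(nrow(beta))) {
    y <- unclass(beta)[i, ]
    if (stats::sd(y) == 0) next
    fit <- tryCatch(fit_gamm(y, table, fixed, random_intercept = re,
                             method = method),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    a <- smooth_term_test(fit, "age"); s <- smooth_term_test(fit, "doy")
    out$age_edf[i] <- a$edf; out$age_p[i] <- a$p
    out$season_edf[i] <- s$edf; out$season_p[i] <- s$p
  }
  out
}

#' Multiplicity thresholds and hit counts
#'
#' Counts significant sites at a fixed threshold of 1e-5, at the
#' Bonferroni threshold `alpha / n_sites`, and under the Benjamini-
#' Hochberg step-up rule at FDR `alpha`.
#'
#' @param p_values Numeric p-values (NA allowed; NAs never count as hits).
#' @param n_sites Number of tests for the Bonferroni denominator (defaults
#'   to `length(p_values)`).
#' @param alpha Family-wise / FDR level (default 0.05).
#' @return List with `fixed_1e5` (count at p < 1e-5),
#'   `bonferroni_threshold`, `bonferroni_count`, `bh_count`.
#' @export
multiplicity_thresholds <- function(p_values, n_sites = length(p_values),
                                    alpha = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values outside [0,1]")
  bonf <- alpha / n_sites
  list(fixed_1e5 = sum(p_values[ok] < 1e-5),
       bonferroni_threshold = bonf,
       bonferroni_count = sum(p_values[ok] < bonf),
       bh_count = sum(stats::p.adjust(p_values[ok], "BH") < alpha))
}

#' Venn overlap of significant site sets
#'
#' @param ewas_hits,gam_age_hits,gam_season_hits Character vectors of site
#'   ids.
#' @return List of the seven region counts (`ewas_only`, `gam_age_only`,
#'   `gam_season_only`, `ewas_gam_age`, `ewas_gam_season`,
#'   `gam_age_gam_season`, `all_three`) plus the pairwise totals
#'   `ewas_and_gam_age`, `ewas_and_gam_season`, `gam_age_and_gam_season`
#'   and `union_size`.
#' @export
overlap_summary <- function(ewas_hits, gam_age_hits, gam_season_hits) {
  A <- unique(as.character(ewas_hits))
  B <- unique(as.character(gam_age_hits))
  C <- unique(as.character(gam_season_hits))
  abc <- intersect(intersect(A, B), C)
  ab <- intersect(A, B); ac <- intersect(A, C); bc <- intersect(B, C)
  list(ewas_only = length(setdiff(A, union(B, C))),
       gam_age_only = length(setdiff(B, union(A, C))),
       gam_season_only = length(setdiff(C, union(A, B))),
       ewas_gam_age = length(setdiff(ab, C)),
       ewas_gam_season = length(setdiff(ac, B)),
       gam_age_gam_season = length(setdiff(bc, A)),
       all_three = length(abc),
       ewas_and_gam_age = length(ab),
       ewas_and_gam_season = length(ac),
       gam_age_and_gam_season = length(bc),
       union_size = length(union(union(A, B), C)))
}
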