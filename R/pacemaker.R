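# Epigenetic pacemaker (EPM): models each CpG site's methylation as a
# linear function of a per-sample latent epigenetic state,
#   beta_ij = rate_i * s_j + offset_i + e_ij,
# and estimates (rate, offset, s) by conditional expectation maximization
# (alternating least squares) minimizing the total residual sum of squares.
# States are identified only up to an affine transformation; initializing
# them at chronological ages anchors the gauge in pseudo-year units.

#' Select age-correlated CpG sites
#'
#' Returns the sites whose absolute Pearson correlation between methylation
#' and chronological age exceeds `threshold`. Sites with zero variance
#' (correlation undefined) are excluded with a warning when they occur.
#'
#' @param beta A [beta_matrix()] (sites x samples).
#' @param ages Chronological ages aligned with the matrix columns.
#' @param threshold Absolute correlation cutoff (default 0.7).
#' @return Character vector of selected site ids.
#' @export
select_age_sites <- function(beta, ages, threshold = 0.7) {
  stopifnot(ncol(beta) == length(ages), ncol(beta) >= 3)
  sds <- apply(beta, 1, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("all sites constant; no site selectable")
    return(character(0))
  }
  r <- as.numeric(stats::cor(t(unclass(beta)[keep, , drop = FALSE]), ages))
  rownames(beta)[keep][abs(r) > threshold & !is.na(r)]
}

#' Fit the epigenetic pacemaker
#'
#' Alternates (a) per-site ordinary least squares of methylation on the
#' current states with (b) the closed-form per-sample state update
#' `s_j = sum_i rate_i (beta_ij - offset_i) / sum_i rate_i^2`, starting from
#' states equal to chronological ages, until the relative change in residual
#' sum of squares falls below `tol`.
#'
#' @param beta A [beta_matrix()] restricted to the modelling sites.
#' @param ages Chronological ages (initial states), aligned with columns.
#' @param tol Relative RSS change at convergence (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return An object of class `epm_model`: list with `site_ids`, `rate`,
#'   `offset`, `states`, `rss`, `rss_trace`, `n_iter`, `converged`.
#' @export
fit_epm <- function(beta, ages, tol = 1e-6, max_iter = 1000L) {
  B <- unclass(beta)
  stopifnot(nrow(B) >= 1, ncol(B) >= 3, ncol(B) == length(ages))
  s <- as.numeric(ages)
  rss_trace <- numeric(0)
  rss_prev <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # (a) per-site OLS of beta on states
    sc <- s - mean(s)
    denom <- sum(sc^2)
    if (denom == 0) stop("degenerate states: no variance")
    rate <- as.numeric(B %*% sc) / denom
    offset <- rowMeans(B) - rate * mean(s)
    # (b) closed-form state update
    r2 <- sum(rate^2)
    if (r2 == 0) stop("degenerate model: all site rates zero")
    s <- as.numeric(crossprod(B - offset, rate)) / r2
    fitted <- outer(rate, s) + offset
    rss <- sum((B - fitted)^2)
    rss_trace <- c(rss_trace, rss)
    if (is.finite(rss_prev) && (rss_prev - rss) <= tol * max(rss_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    rss_prev <- rss
  }
  structure(list(site_ids = rownames(B), rate = rate, offset = offset,
                 states = s, rss = rss, rss_trace = rss_trace,
                 n_iter = iter, converged = converged),
            class = "epm_model")
}

#' Predict epigenetic states for new samples
#'
#' Applies the closed-form state update with the model's site parameters
#' held fixed.
#'
#' @param model An `epm_model`.
#' @param beta_new A [beta_matrix()] covering the model's sites.
#' @return Numeric state per new sample.
#' @export
predict_states <- function(model, beta_new) {
  missing <- setdiff(model$site_ids, rownames(beta_new))
  if (length(missing))
    stop("beta matrix lacks model site(s): ", paste(missing, collapse = ", "))
  B <- unclass(beta_new)[model$site_ids, , drop = FALSE]
  as.numeric(crossprod(B - model$offset, model$rate)) / sum(model$rate^2)
}

#' Cross-validated epigenetic states
#'
#' Each sample's state is predicted by a pacemaker trained without it.
#' Site selection is, by default, repeated inside every training fold so
#' that held-out states carry no selection leakage; set
#' `reselect_sites = FALSE` to select once on the full data instead.
#'
#' @param beta Full [beta_matrix()].
#' @param ages Chronological ages aligned with columns.
#' @param k Number of folds (default 10).
#' @param threshold Site-selection correlation cutoff.
#' @param reselect_sites Re-select sites per fold (default `TRUE`).
#' @param seed Seed for the fold assignment.
#' @param tol,max_iter Passed to [fit_epm()].
#' @return List with `states` (out-of-fold state per sample), `folds`
#'   (fold id per sample), and `site_counts` (selected sites per fold).
#' @export
cross_validate_epm <- function(beta, ages, k = 10L, threshold = 0.7,
                               reselect_sites = TRUE, seed = 1L,
                               tol = 1e-6, max_iter = 1000L) {
  n <- ncol(beta)
  if (k > n) stop("k must not exceed the number of samples")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  if (!reselect_sites) global_sites <- select_age_sites(beta, ages, threshold)
  states <- rep(NA_real_, n)
  site_counts <- integer(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sites <- if (reselect_sites)
      select_age_sites(beta_matrix(unclass(beta)[, tr, drop = FALSE]),
                       ages[tr], threshold)
    else global_sites
    if (length(sites) < 1) stop("no site selected in fold ", f)
    site_counts[f] <- length(sites)
    m <- fit_epm(unclass(beta)[sites, tr, drop = FALSE] |>
                   beta_matrix(site_ids = sites, sample_ids = colnames(beta)[tr]),
                 ages[tr], tol = tol, max_iter = max_iter)
    states[!tr] <- predict_states(
      m, beta_matrix(unclass(beta)[sites, !tr, drop = FALSE],
                     site_ids = sites, sample_ids = colnames(beta)[!tr]))
  }
  list(states = states, folds = folds, site_counts = site_counts)
}

#' Serialize a pacemaker model to JSON
#'
#' @param model An `epm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epm_model <- function(model, path) {
  jsonlite::write_json(
    list(site_ids = model$site_ids, rate = model$rate, offset = model$offset,
         states = model$states, rss = model$rss, n_iter = model$n_iter,
         converged = model$converged),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
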