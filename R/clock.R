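# Elastic-net epigenetic clock: penalized linear regression of
# chronological age on CpG methylation, with grouped out-of-sample
# prediction and accuracy metrics.

#' Fit an elastic-net epigenetic clock
#'
#' Regresses chronological age on methylation levels with elastic-net
#' penalization (ridge and lasso weighted by `alpha`; `alpha = 0.5` weights
#' them equally). The penalty strength is chosen at the minimum mean
#' cross-validated squared error over a 10-fold split; irrelevant sites are
#' shrunk to exactly zero.
#'
#' @param beta A [beta_matrix()] (sites x samples).
#' @param ages Chronological ages aligned with columns.
#' @param alpha Elastic-net mixing weight in [0,1] (default 0.5).
#' @param cv_folds Folds for the lambda search (default 10).
#' @param standardize Standardize predictors before penalization (default
#'   `TRUE`).
#' @param seed Seed for the internal fold assignment.
#' @return An object of class `clock_model`: list with `site_ids`, `coef`
#'   (per-site, zeros kept), `intercept`, `alpha`, `lambda`, `standardize`,
#'   `seed`, and the underlying `glmnet` fit.
#' @export
fit_clock <- function(beta, ages, alpha = 0.5, cv_folds = 10L,
                      standardize = TRUE, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, ncol(beta) == length(ages))
  if (stats::sd(ages) == 0) stop("constant response: ages have no variance")
  if (length(ages) < cv_folds) stop("need at least cv_folds samples")
  x <- t(unclass(beta))
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), length(ages)))
  cv <- glmnet::cv.glmnet(x, ages, alpha = alpha, foldid = foldid,
                          standardize = standardize)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  structure(list(site_ids = rownames(beta), coef = co[-1], intercept = co[1],
                 alpha = alpha, lambda = cv$lambda.min,
                 standardize = standardize, seed = seed, cv_fit = cv),
            class = "clock_model")
}

#' Predict ages with a fitted clock
#'
#' @param object A `clock_model`.
#' @param beta A [beta_matrix()] covering the model's sites.
#' @param ... Unused.
#' @return Numeric predicted age per sample.
#' @export
predict.clock_model <- function(object, beta, ...) {
  missing <- setdiff(object$site_ids, rownames(beta))
  if (length(missing))
    stop("beta matrix lacks clock site(s): ", paste(missing, collapse = ", "))
  x <- t(unclass(beta)[object$site_ids, , drop = FALSE])
  as.numeric(x %*% object$coef + object$intercept)
}

#' Grouped holdout predictions
#'
#' Splits the samples into `ceiling(n / group_size)` groups (contiguous
#' blocks after a seeded shuffle), fits one clock per group on all other
#' samples, and predicts each group's ages out of sample, so every
#' prediction comes from a model that never saw that sample.
#'
#' @param beta A [beta_matrix()].
#' @param ages Chronological ages.
#' @param group_size Approximate samples per holdout group (default 14).
#' @param seed Seed controlling the shuffle and the per-fold clock fits.
#' @param ... Passed to [fit_clock()].
#' @return List with `predicted` (per-sample out-of-sample age), `fold`
#'   (group id per sample), `n_folds`, and `sites_used` (union of site ids
#'   with nonzero coefficient in any fold model).
#' @export
grouped_holdout_predictions <- function(beta, ages, group_size = 14L,
                                        seed = 1L, ...) {
  n <- length(ages)
  stopifnot(group_size >= 1, group_size < n)
  n_folds <- as.integer(ceiling(n / group_size))
  # contiguous blocks after a seeded shuffle
  set.seed(seed)
  fold <- integer(n)
  perm <- sample.int(n)
  fold[perm] <- as.integer(ceiling(seq_len(n) / group_size))
  predicted <- rep(NA_real_, n)
  sites_used <- character(0)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    m <- fit_clock(beta_matrix(unclass(beta)[, tr, drop = FALSE],
                               site_ids = rownames(beta),
                               sample_ids = colnames(beta)[tr]),
                   ages[tr], seed = seed + f, ...)
    predicted[!tr] <- predict(
      m, beta_matrix(unclass(beta)[, !tr, drop = FALSE],
                     site_ids = rownames(beta),
                     sample_ids = colnames(beta)[!tr]))
    sites_used <- union(sites_used, m$site_ids[m$coef != 0])
  }
  list(predicted = predicted, fold = fold, n_folds = n_folds,
       sites_used = sites_used)
}

#' Accuracy metrics for age prediction
#'
#' Pearson correlation, median absolute error, and median relative absolute
#' error (|error| / observed age, over samples with observed age > 0).
#'
#' @param predicted,observed Numeric vectors of equal length (>= 2).
#' @return List with `pearson_r`, `median_abs_error`,
#'   `median_rel_abs_error`.
#' @export
accuracy_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  stopifnot(length(predicted) >= 2)
  err <- abs(predicted - observed)
  pos <- observed > 0
  list(pearson_r = as.numeric(stats::cor(predicted, observed)),
       median_abs_error = stats::median(err),
       median_rel_abs_error = if (any(pos)) stats::median(err[pos] / observed[pos]) else NA_real_)
}

#' Serialize a clock model to JSON
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  jsonlite::write_json(
    list(site_ids = model$site_ids, coef = model$coef,
         intercept = model$intercept, alpha = model$alpha,
         lambda = model$lambda, standardize = model$standardize,
         seed = model$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
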