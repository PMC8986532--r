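# Penalized-spline generalized additive mixed models for circannual data:
# cubic regression splines for age, cyclic cubic splines (period 365) for
# day of year, tensor-product interactions, and an animal-level random
# intercept. Built on mgcv; models compared by AIC are fitted by ML since
# the candidates differ in their fixed effects.

#' Specify a model term
#'
#' @param variable Column name in the model data.
#' @param basis One of `"linear"`, `"cubic_spline"`,
#'   `"cyclic_cubic_spline"`.
#' @param k Basis dimension for spline bases (default 10).
#' @param period Cycle length for the cyclic basis (default 365).
#' @return A list of class `smooth_spec`.
#' @export
smooth_spec <- function(variable,
                        basis = c("cubic_spline", "cyclic_cubic_spline", "linear"),
                        k = 10L, period = 365) {
  basis <- match.arg(basis)
  if (basis != "linear" && k < 3) stop("spline bases need k >= 3")
  structure(list(variable = variable, basis = basis, k = as.integer(k),
                 period = if (basis == "cyclic_cubic_spline") period else NULL),
            class = "smooth_spec")
}

#' @rdname smooth_spec
#' @export
lin_term <- function(variable) smooth_spec(variable, "linear")

#' @rdname smooth_spec
#' @export
age_spline <- function(variable = "age", k = 10L) smooth_spec(variable, "cubic_spline", k)

#' @rdname smooth_spec
#' @export
doy_spline <- function(variable = "doy", k = 10L, period = 365)
  smooth_spec(variable, "cyclic_cubic_spline", k, period)

#' Interaction of two model terms
#'
#' For two linear terms this is the usual product interaction (with main
#' effects); for two spline terms it is a tensor-product interaction
#' (`ti`): the row-wise product basis with the marginal main effects
#' removed, added alongside the marginal smooths, carrying one penalty per
#' margin.
#'
#' @param a,b `smooth_spec` terms.
#' @return A list of class `interaction_spec`.
#' @export
interaction_term <- function(a, b) {
  stopifnot(inherits(a, "smooth_spec"), inherits(b, "smooth_spec"))
  structure(list(a = a, b = b), class = "interaction_spec")
}

.basis_code <- c(cubic_spline = "cr", cyclic_cubic_spline = "cc")

# returns list(terms = character, knots = named list)
.spec_to_mgcv <- function(spec) {
  if (inherits(spec, "interaction_spec")) {
    a <- spec$a; b <- spec$b
    if (a$basis == "linear" && b$basis == "linear")
      return(list(terms = c(a$variable, b$variable,
                            paste0(a$variable, ":", b$variable)),
                  knots = list()))
    if (a$basis == "linear" || b$basis == "linear")
      stop("mixed linear/spline interactions are not supported")
    ma <- .spec_to_mgcv(a); mb <- .spec_to_mgcv(b)
    # cyclic margins keep their full k so the supplied knots (shared with
    # the marginal smooth) match; non-cyclic margins are trimmed to keep
    # the interaction's coefficient count modest
    k_a <- if (a$basis == "cyclic_cubic_spline") a$k else min(a$k, 5L)
    k_b <- if (b$basis == "cyclic_cubic_spline") b$k else min(b$k, 5L)
    ti <- sprintf("ti(%s, %s, bs = c(\"%s\", \"%s\"), k = c(%d, %d))",
                  a$variable, b$variable,
                  .basis_code[[a$basis]], .basis_code[[b$basis]],
                  k_a, k_b)
    return(list(terms = c(ma$terms, mb$terms, ti),
                knots = c(ma$knots, mb$knots)))
  }
  stopifnot(inherits(spec, "smooth_spec"))
  if (spec$basis == "linear")
    return(list(terms = spec$variable, knots = list()))
  code <- .basis_code[[spec$basis]]
  term <- sprintf("s(%s, bs = \"%s\", k = %d)", spec$variable, code, spec$k)
  knots <- list()
  if (spec$basis == "cyclic_cubic_spline")
    knots[[spec$variable]] <- seq(1, 1 + spec$period, length.out = spec$k)
  list(terms = term, knots = knots)
}

#' Construct a penalized cubic regression spline basis
#'
#' Knots at data quantiles; the penalty is the integrated squared second
#' derivative, symmetric positive semidefinite with a two-dimensional null
#' space (constant and linear functions).
#'
#' @param x Covariate values (at least `k` distinct).
#' @param k Basis dimension.
#' @return List with `X` (design columns), `S` (penalty matrix), `knots`,
#'   and `smooth` (the underlying mgcv smooth object, usable with
#'   `mgcv::PredictMat`).
#' @export
cubic_spline_basis <- function(x, k = 10L) {
  if (length(unique(x)) < k) stop("need at least k distinct covariate values")
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k),
                        data = data.frame(x = x), absorb.cons = FALSE)[[1]]
  list(X = sm$X, S = sm$S[[1]], knots = sm$xp, smooth = sm)
}

#' Construct a cyclic cubic spline basis
#'
#' Value, first and second derivatives match at the period boundary; the
#' penalty null space is one-dimensional (constants only).
#'
#' @param x Covariate values in `[1, period]`.
#' @param k Basis dimension.
#' @param period Cycle length (default 365).
#' @return As [cubic_spline_basis()].
#' @export
cyclic_spline_basis <- function(x, k = 10L, period = 365) {
  if (any(x < 1 | x > period)) stop("x outside [1, period]")
  knots <- seq(1, 1 + period, length.out = k)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cc", k = k),
                        data = data.frame(x = x),
                        knots = list(x = knots), absorb.cons = FALSE)[[1]]
  list(X = sm$X, S = sm$S[[1]], knots = sm$xp, smooth = sm)
}

#' Fit a generalized additive mixed model
#'
#' Gaussian response with identity link; smooths are centered (sum-to-zero
#' over the data) so the intercept is identifiable, and the animal-level
#' random intercept is represented as a ridge-penalized factor smooth.
#' Smoothing parameters and variance components are estimated by ML
#' (default, required for AIC comparison of fixed-effect structures) or
#' REML.
#'
#' @param y Response vector.
#' @param data Sample table providing the covariates.
#' @param fixed A list of `smooth_spec` / `interaction_spec` terms.
#' @param random_intercept Column name of the grouping factor, or `NULL`
#'   for no random effect.
#' @param method `"ML"` or `"REML"`.
#' @return An object of class `gamm_fit`: list with the mgcv `fit`,
#'   `intercept`, `coefficients`, `smoothing_params`, `var_individual`,
#'   `var_residual`, `edf` (per smooth), `aic`, `adj_r2`, `term_tests`
#'   (per-smooth edf/Ref.df/F/p), `converged`, `formula`.
#' @export
fit_gamm <- function(y, data, fixed, random_intercept = "animal_id",
                     method = c("ML", "REML")) {
  method <- match.arg(method)
  if (inherits(fixed, c("smooth_spec", "interaction_spec"))) fixed <- list(fixed)
  parts <- lapply(fixed, .spec_to_mgcv)
  terms <- unlist(lapply(parts, `[[`, "terms"))
  knots <- do.call(c, lapply(parts, `[[`, "knots"))
  df <- as.data.frame(data)
  df$.y <- y
  re_term <- NULL
  if (!is.null(random_intercept)) {
    df[[random_intercept]] <- factor(df[[random_intercept]])
    re_term <- sprintf("s(%s, bs = \"re\")", random_intercept)
  }
  rhs <- paste(c(terms, re_term), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- mgcv::gam(form, data = df, method = method,
                   knots = if (length(knots)) knots else NULL)
  sm <- summary(fit)
  st <- sm$s.table
  re_label <- if (!is.null(re_term)) sprintf("s(%s)", random_intercept) else NULL
  var_individual <- NA_real_
  if (!is.null(re_label) && re_label %in% rownames(st)) {
    # for a ridge-penalized random intercept, sigma_b^2 = sig2 / sp
    sp_re <- fit$sp[grep(re_label, names(fit$sp), fixed = TRUE)]
    var_individual <- if (length(sp_re)) unname(fit$sig2 / sp_re[1]) else NA_real_
  }
  smooth_rows <- setdiff(rownames(st), re_label)
  structure(list(fit = fit,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 coefficients = stats::coef(fit),
                 smoothing_params = fit$sp,
                 var_individual = var_individual,
                 var_residual = fit$sig2,
                 edf = if (length(smooth_rows)) st[smooth_rows, "edf"] else numeric(0),
                 aic = stats::AIC(fit),
                 adj_r2 = sm$r.sq,
                 term_tests = st,
                 converged = isTRUE(fit$converged),
                 formula = deparse(form)),
            class = "gamm_fit")
}

#' Wald-type test of a smooth term
#'
#' Reports the effective degrees of freedom, reference degrees of freedom,
#' F statistic and p-value of one smooth term from a fitted model.
#'
#' @param fit A `gamm_fit`.
#' @param term Smooth label, e.g. `"s(doy)"`, or the bare variable name.
#' @return List with `edf`, `ref_df`, `F`, `p`.
#' @export
smooth_term_test <- function(fit, term) {
  st <- fit$term_tests
  lab <- if (term %in% rownames(st)) term else {
    hit <- grep(paste0("\\(", term, "[,)]"), rownames(st), value = TRUE)
    if (length(hit) != 1) stop("unknown or ambiguous term: ", term)
    hit
  }
  row <- st[lab, ]
  list(edf = unname(row["edf"]), ref_df = unname(row["Ref.df"]),
       F = unname(row["F"]), p = unname(row["p-value"]))
}

#' The eight candidate fixed-effect structures
#'
#' Chronological age and day of year entered as: (1) both linear; (2)
#' linear with their product interaction; (3) spline age + linear doy; (4)
#' linear age + spline doy; (5) linear age + cyclic doy; (6) spline age +
#' spline doy; (7) spline age + cyclic doy; (8) spline age + cyclic doy +
#' their tensor-product interaction.
#'
#' @param age_var,doy_var Column names.
#' @param k Spline basis dimension.
#' @return Named list of fixed-effect term lists for [fit_gamm()].
#' @export
candidate_fixed_effects <- function(age_var = "age", doy_var = "doy", k = 10L) {
  la <- lin_term(age_var); ld <- lin_term(doy_var)
  sa <- age_spline(age_var, k); sd_ <- smooth_spec(doy_var, "cubic_spline", k)
  cd <- doy_spline(doy_var, k)
  list(lin_age_lin_doy = list(la, ld),
       lin_age_x_lin_doy = list(interaction_term(la, ld)),
       spl_age_lin_doy = list(sa, ld),
       lin_age_spl_doy = list(la, sd_),
       lin_age_cyc_doy = list(la, cd),
       spl_age_spl_doy = list(sa, sd_),
       spl_age_cyc_doy = list(sa, cd),
       spl_age_x_cyc_doy = list(interaction_term(sa, cd)))
}

#' AIC model selection over candidate fixed-effect structures
#'
#' Fits every candidate by ML with the shared random intercept and ranks
#' them by AIC. A winner is declared "best" only when its AIC lead over the
#' runner-up exceeds 2; non-convergent candidates are ranked but excluded
#' from the declaration.
#'
#' @param y Response vector.
#' @param data Sample table.
#' @param candidates Named list of fixed-effect structures (default
#'   [candidate_fixed_effects()]).
#' @param random_intercept Grouping column, or `NULL`.
#' @param method Estimation method (ML recommended for this comparison).
#' @return List with `table` (data.frame: model, aic, delta_aic, edf sum,
#'   converged, ranked by AIC), `fits` (named list of `gamm_fit`), `best`
#'   (name or `NA` when the top model's lead is <= 2).
#' @export
select_model <- function(y, data, candidates = candidate_fixed_effects(),
                         random_intercept = "animal_id",
                         method = "ML") {
  fits <- lapply(candidates, function(fx)
    fit_gamm(y, data, fx, random_intercept = random_intercept, method = method))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  ord <- order(aic)
  tab <- data.frame(model = names(candidates)[ord], aic = aic[ord],
                    delta_aic = aic[ord] - min(aic),
                    converged = conv[ord], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  best <- NA_character_
  if (nrow(tab) >= 2 && tab$converged[1] && (tab$aic[2] - tab$aic[1]) > 2)
    best <- tab$model[1]
  if (nrow(tab) == 1 && tab$converged[1]) best <- tab$model[1]
  list(table = tab, fits = fits, best = best)
}
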