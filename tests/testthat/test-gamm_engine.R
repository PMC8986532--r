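test_that("cubic spline penalty has nullity two and vanishes on linear fits", {
  set.seed(1)
  x <- sort(runif(60, 0, 12))
  bs <- cubic_spline_basis(x, k = 10)
  ev <- eigen(bs$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  expect_identical(sum(ev < max(ev) * 1e-10), 2L)  # constant + linear
  # coefficients reproducing a straight line incur zero penalty
  co <- qr.solve(bs$X, 2 + 3 * x)
  expect_lt(as.numeric(t(co) %*% bs$S %*% co), 1e-8)
})

test_that("the cubic regression basis interpolates like a natural cubic spline", {
  x <- seq(0, 10, length.out = 11)
  set.seed(2)
  y <- sin(x) + rnorm(11, 0, 0.1)
  bs <- cubic_spline_basis(x, k = 11)  # knots coincide with the data here
  co <- qr.solve(bs$X, y)
  xf <- seq(0.2, 9.8, by = 0.1)
  pred <- mgcv::PredictMat(bs$smooth, data.frame(x = xf)) %*% co
  ref <- spline(x, y, xout = xf, method = "natural")$y
  expect_equal(as.numeric(pred), ref, tolerance = 1e-8)
})

test_that("cyclic spline value and derivatives match at the period boundary", {
  x <- c(1:112, 362:365)  # data confined to the active window
  bs <- cyclic_spline_basis(x, k = 10, period = 365)
  set.seed(3)
  co <- rnorm(ncol(bs$X))
  eps <- 1e-5
  f <- function(z) as.numeric(mgcv::PredictMat(bs$smooth, data.frame(x = z)) %*% co)
  expect_equal(f(1), f(366), tolerance = 1e-8)
  d1 <- (f(1 + eps) - f(1)) / eps
  d2 <- (f(366) - f(366 - eps)) / eps
  expect_equal(d1, d2, tolerance = 1e-3)
  dd1 <- (f(1 + 2 * eps) - 2 * f(1 + eps) + f(1)) / eps^2
  dd2 <- (f(366) - 2 * f(366 - eps) + f(366 - 2 * eps)) / eps^2
  expect_equal(dd1, dd2, tolerance = 1e-2)
  expect_error(cyclic_spline_basis(c(0.5, 10), k = 10), "outside")
})

test_that("a cyclic smooth fits a period-365 sinusoid to within 1% of amplitude", {
  set.seed(4)
  doy <- sample(1:365, 200, replace = TRUE)
  y <- sin(2 * pi * doy / 365)
  fit <- mgcv::gam(y ~ s(doy, bs = "cc", k = 10),
                   knots = list(doy = seq(1, 366, length.out = 10)))
  grid <- data.frame(doy = 1:365)
  err <- predict(fit, grid) - sin(2 * pi * (1:365) / 365)
  expect_lt(max(abs(err)), 0.01)
})

test_that("fitted smooth contributions are centered over the data", {
  st <- generate_study_table(seed = 21)
  fit <- fit_gamm(st$epigenetic_state, st, list(age_spline(), doy_spline()))
  pt <- predict(fit$fit, type = "terms")
  for (term in c("s(age)", "s(doy)"))
    expect_lt(abs(sum(pt[, term])), 1e-6 * nrow(st) * sd(st$epigenetic_state))
})

test_that("a purely linear age effect yields edf near one and no seasonal signal", {
  d <- generate_design(design_config(n_individuals = 100, n_samples_total = 300,
                                     n_consecutive = 11, seed = 23))
  set.seed(24)
  y <- 0.8 * d$age + rnorm(nrow(d), 0, 0.5)
  fit <- fit_gamm(y, d, list(age_spline(), doy_spline()), random_intercept = NULL,
                  method = "REML")
  expect_lte(smooth_term_test(fit, "age")$edf, 1.2)
  expect_gt(smooth_term_test(fit, "doy")$p, 0.001)
})

test_that("the tensor interaction shrinks to nothing under additive truth", {
  d <- generate_design(design_config(seed = 25))
  set.seed(26)
  y <- 0.6 * d$age + 0.5 * sin(2 * pi * d$doy / 365) + rnorm(nrow(d), 0, 0.3)
  fit <- fit_gamm(y, d, list(interaction_term(age_spline(), doy_spline())),
                  random_intercept = NULL)
  ti_label <- grep("^ti\\(", rownames(fit$term_tests), value = TRUE)
  expect_identical(length(ti_label), 1L)
  # interaction edf stays near the bottom of its 24-dimensional range
  expect_lt(fit$term_tests[ti_label, "edf"], 4)
  expect_lt(fit$term_tests[ti_label, "edf"] / fit$term_tests[ti_label, "Ref.df"], 0.15)
})

test_that("edf respects its bounds and extreme smoothing collapses to the nullspace", {
  st <- generate_study_table(seed = 26)
  fit <- fit_gamm(st$epigenetic_state, st, list(age_spline(), doy_spline()))
  expect_true(all(fit$edf >= 0 & fit$edf <= c(9, 8) + 1e-6))
  df <- as.data.frame(st)
  df$.y <- st$epigenetic_state
  heavy <- mgcv::gam(.y ~ s(age, bs = "cr", k = 10), data = df, sp = 1e9)
  expect_equal(sum(heavy$edf[-1]), 1, tolerance = 0.01)  # linear remnant
})

test_that("model selection ranks deterministically and recovers generating structure", {
  st <- generate_study_table(seed = 27)
  s1 <- select_model(st$epigenetic_state, st)
  s2 <- select_model(st$epigenetic_state, st)
  expect_identical(s1$table, s2$table)
  # across seeds the winner carries a spline age term always and the cyclic
  # seasonal spline in the majority of datasets (seasonal power is < 1)
  tops <- vapply(c(27, 33, 41), function(s) {
    tab <- generate_study_table(seed = s)
    select_model(tab$epigenetic_state, tab)$table$model[1]
  }, character(1))
  expect_true(all(grepl("spl_age", tops)))
  expect_gte(sum(grepl("cyc_doy", tops)), 2L)
  # a non-seasonal linear trait does not prefer cyclic candidates by > 2 AIC
  d <- generate_design(design_config(seed = 28))
  y <- simulate_trait(d, trait_config(seed = 29), seasonal = FALSE)
  s3 <- select_model(y, d)
  aics <- s3$table$aic[match(c("lin_age_lin_doy", "lin_age_cyc_doy"), s3$table$model)]
  expect_gt(aics[2] - aics[1], -2)
})

test_that("smooth term tests are extreme for deterministic signals and report the Table shape", {
  d <- generate_design(design_config(seed = 30))
  y <- 0.5 * d$age + sin(2 * pi * d$doy / 365)  # no noise at all
  fit <- fit_gamm(y, d, list(age_spline(), doy_spline()), random_intercept = NULL)
  tt <- smooth_term_test(fit, "doy")
  expect_lt(tt$p, 1e-10)
  expect_true(all(c("edf", "ref_df", "F", "p") %in% names(tt)))
  expect_error(smooth_term_test(fit, "nonexistent"), "unknown")
})
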