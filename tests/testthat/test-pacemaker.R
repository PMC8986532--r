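test_that("an exact single-site linear system is solved in one round", {
  ages <- c(1, 3, 5, 8, 10)
  beta <- beta_matrix(matrix(0.1 * ages, 1, 5,
                             dimnames = list("cg1", paste0("s", 1:5))))
  m <- fit_epm(beta, ages)
  expect_equal(unname(m$rate), 0.1, tolerance = 1e-12)
  expect_equal(unname(m$offset), 0, tolerance = 1e-12)
  expect_equal(m$states, ages, tolerance = 1e-10)
  expect_lt(m$rss, 1e-20)
  expect_true(m$converged)
})

test_that("RSS decreases monotonically and matches a direct numerical minimizer", {
  toy <- epm_toy(n_sites = 3, ages = c(1, 2, 3, 5, 6, 8, 10, 12))
  set.seed(3)
  noisy <- beta_matrix(pmin(pmax(unclass(toy$beta) + rnorm(24, 0, 0.02), 0), 1),
                       rownames(toy$beta), colnames(toy$beta))
  m <- fit_epm(noisy, toy$ages)
  expect_true(all(diff(m$rss_trace) <= 1e-12))
  # age-anchored initial model: per-site OLS on chronological ages
  rss0 <- sum(vapply(seq_len(3), function(i) {
    sum(resid(lm(unclass(noisy)[i, ] ~ toy$ages))^2)
  }, numeric(1)))
  expect_lte(m$rss, rss0 + 1e-12)
  # independent oracle: general-purpose optimizer over (rates, offsets, states)
  obj <- function(par) {
    r <- par[1:3]; o <- par[4:6]; s <- par[7:14]
    sum((unclass(noisy) - (outer(r, s) + o))^2)
  }
  opt <- optim(c(m$rate, m$offset, m$states), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(m$rss, opt$value, tolerance = 1e-6)
})

test_that("duplicating a site leaves the estimated states unchanged", {
  toy <- epm_toy(n_sites = 1, ages = c(1, 2, 4, 6, 9, 11))
  set.seed(8)
  y <- pmin(pmax(unclass(toy$beta)[1, ] + rnorm(6, 0, 0.01), 0), 1)
  single <- beta_matrix(matrix(y, 1, 6, dimnames = list("cgA", colnames(toy$beta))))
  double <- beta_matrix(rbind(y, y), c("cgA", "cgB"), colnames(toy$beta))
  m1 <- fit_epm(single, toy$ages)
  m2 <- fit_epm(double, toy$ages)
  expect_equal(m1$states, m2$states, tolerance = 1e-8)
})

test_that("state prediction inverts the site relations and is idempotent", {
  toy <- epm_toy(n_sites = 4)
  m <- fit_epm(toy$beta, toy$ages)
  expect_equal(predict_states(m, toy$beta), m$states, tolerance = 1e-10)
  # a sample constructed at state 5 exactly
  new_beta <- beta_matrix(matrix(m$rate * 5 + m$offset, ncol = 1,
                                 dimnames = list(m$site_ids, "new")))
  expect_equal(predict_states(m, new_beta), 5, tolerance = 1e-10)
  expect_error(predict_states(m, toy$beta[1:2, , drop = FALSE]), "lacks")
})

test_that("recovered states match generating states after affine alignment", {
  d <- generate_design(design_config(n_individuals = 50, n_samples_total = 150,
                                     n_consecutive = 5, seed = 31))
  states <- simulate_trait(d, trait_config(seed = 32), seasonal = FALSE)
  b <- simulate_beta_matrix(d, states, site_config(n_sites = 300, n_age_sites = 300,
                                                   noise_sd = 0.02, seed = 33))
  m <- fit_epm(b, d$age)
  expect_gte(cor(m$states, states), 0.99)
  aligned <- affine_align(m$states, states)
  expect_lt(sd(aligned - states) / sd(states), 0.15)
})

test_that("cross-validation predicts each sample out of fold, deterministically", {
  d <- small_design(seed = 41L, n = 12L, total = 24L, n_consec = 0L)
  states <- simulate_trait(d, trait_config(seed = 42), seasonal = FALSE)
  b <- simulate_beta_matrix(d, states, site_config(n_sites = 60, n_age_sites = 40,
                                                   noise_sd = 0.01, seed = 43))
  cv1 <- cross_validate_epm(b, d$age, k = 10, seed = 9)
  cv2 <- cross_validate_epm(b, d$age, k = 10, seed = 9)
  expect_identical(cv1, cv2)
  expect_true(all(table(cv1$folds) >= 2))
  # leave-one-out: every fold trains on n - 1 samples
  loo <- cross_validate_epm(b, d$age, k = nrow(d), seed = 10)
  expect_identical(sort(unique(loo$folds)), seq_len(nrow(d)))
  # noiseless recovery out of fold
  b0 <- simulate_beta_matrix(d, states, site_config(n_sites = 40, n_age_sites = 40,
                                                    noise_sd = 0, seed = 44))
  cv0 <- cross_validate_epm(b0, d$age, k = 6, seed = 11)
  expect_gte(cor(cv0$states, states), 0.999)
  expect_error(cross_validate_epm(b, d$age, k = nrow(d) + 1), "exceed")
})

test_that("logarithmic generating states produce a concave state-age curve", {
  d <- generate_design(design_config(n_individuals = 40, n_samples_total = 100,
                                     n_consecutive = 4, seed = 51))
  states <- 4 * log1p(d$age)  # decelerating epigenetic ageing
  b <- simulate_beta_matrix(d, states, site_config(n_sites = 150, n_age_sites = 150,
                                                   noise_sd = 0.01, seed = 52))
  m <- fit_epm(b, d$age)
  sm <- mgcv::gam(s ~ s(age, bs = "cr", k = 6), method = "REML",
                  data = data.frame(s = m$states, age = d$age))
  grid <- data.frame(age = seq(1, 10.5, length.out = 40))  # interior of the range
  pred <- predict(sm, grid)
  # curvature is non-positive up to smoothing wiggle well below the true
  # log-curve's curvature scale
  expect_true(all(diff(diff(pred)) <= 2.5e-4 * diff(range(pred))))
})
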