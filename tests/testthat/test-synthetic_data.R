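test_that("the default design reproduces the study's sampling structure", {
  d <- generate_design(design_config(seed = 3L))
  expect_identical(nrow(d), 149L)
  expect_identical(length(unique(d$animal_id)), 73L)
  expect_true(all(d$doy %in% c(362:365, 1:112)))
  counts <- table(d$animal_id)
  expect_true(all(counts >= 1 & counts <= 8))
  expect_lt(abs(max(d$age) - 12.04), 0.005)
  expect_lt(abs(min(d$age) - 0.01), 0.005)
  # per-animal samples ordered in time and consistent with one birth date
  for (x in split(d, d$animal_id)) {
    expect_true(all(diff(x$abs_day) > 0))
    expect_identical(length(unique(x$birth_abs)), 1L)
    expect_equal(x$age, (x$abs_day - x$birth_abs) / 365)
  }
})

test_that("exactly the configured animals are eligible for the consecutive-season filter", {
  d <- generate_design(design_config(seed = 9L))
  d$epigenetic_state <- 1  # states irrelevant for eligibility
  expect_identical(nrow(consecutive_year_rates(d)), 11L)
  d2 <- small_design(seed = 2L, n_consec = 0L)
  d2$epigenetic_state <- 1
  expect_identical(nrow(consecutive_year_rates(d2)), 0L)
})

test_that("degenerate configs work and generation is deterministic", {
  one <- generate_design(design_config(n_individuals = 1, n_samples_total = NULL,
                                       samples_per_individual = c(1, 1),
                                       n_consecutive = 0, seed = 5))
  expect_identical(nrow(one), 1L)
  expect_identical(generate_design(design_config(seed = 8)),
                   generate_design(design_config(seed = 8)))
  expect_error(design_config(sampling_window = integer(0)), "empty")
})

test_that("trait simulation matches closed forms at zero variance", {
  d <- small_design()
  cfg <- trait_config(var_individual = 0, var_residual = 0)
  flat <- simulate_trait(d, cfg, seasonal = FALSE)
  # 0.004 per day of age: two samples 100 days apart differ by exactly 0.4
  x <- split(d, d$animal_id)[[which.max(table(d$animal_id))]]
  gap_days <- diff(x$abs_day)
  expect_equal(diff(flat[match(x$sample_id, d$sample_id)]), 0.004 * gap_days)
  # a full year of the flat trait accrues 0.004 * 365 = 1.46
  expect_equal(0.004 * 365, 1.46)
  # two samples inside one winter: zero accrual between them
  winter <- data.frame(sample_id = c("w1", "w2"), animal_id = "W",
                       age = c(200, 260) / 365, doy = c(200L, 260L),
                       year = 0L, season = 0L, abs_day = c(200L, 260L),
                       birth_doy = 60L, birth_abs = 60L)
  wtrait <- simulate_trait(winter, cfg, seasonal = TRUE)
  expect_equal(diff(wtrait), 0)
})

test_that("seasonal trait is constant across winter and increasing across active days", {
  d <- small_design(seed = 11L)
  cfg <- trait_config(var_individual = 0, var_residual = 0)
  seas <- simulate_trait(d, cfg, seasonal = TRUE)
  for (x in split(cbind(d, trait = seas), d$animal_id)) {
    if (nrow(x) < 2) next
    for (j in 2:nrow(x)) {
      same_season <- x$season[j] == x$season[j - 1]
      dtrait <- x$trait[j] - x$trait[j - 1]
      if (same_season) {
        expect_gt(dtrait, 0)  # active days in between
      } else {
        # spans a hibernation: accrual only from the flanking active tails
        active_span <- cfg$active_daily_rate *
          (x$abs_day[j] - x$abs_day[j - 1] - (352 - 139 + 1))
        expect_lte(dtrait, active_span + 1e-9)
        expect_gte(dtrait, 0)
      }
    }
  }
})

test_that("the derived seasonal rate equalizes annual accrual with the flat trait", {
  cfg <- trait_config()
  expect_equal(cfg$active_daily_rate * 151, 0.004 * 365)
  cfg2 <- trait_config(active_daily_rate = 0.0164)
  expect_equal(cfg2$active_daily_rate, 0.0164)
})

test_that("beta simulation evaluates site relations exactly without noise", {
  d <- small_design()
  states <- seq(0, 10, length.out = nrow(d))
  states[1] <- 2
  cfg <- site_config(n_sites = 1, n_age_sites = 1, rate_range = c(0.05, 0.05),
                     offset_range = c(0.1, 0.1), noise_sd = 0, mixed_signs = FALSE)
  b <- simulate_beta_matrix(d, states, cfg)
  expect_equal(unname(unclass(b)[1, ]), 0.05 * states + 0.1)
  expect_equal(unname(unclass(b)[1, 1]), 0.2)  # rate 0.05, offset 0.1, state 2
  # noiseless age sites correlate perfectly with states
  cfg2 <- site_config(n_sites = 6, n_age_sites = 6, noise_sd = 0, seed = 4)
  b2 <- simulate_beta_matrix(d, states, cfg2)
  r <- apply(unclass(b2), 1, function(y) cor(y, states))
  expect_equal(unname(abs(r)), rep(1, 6), tolerance = 1e-12)
})

test_that("site selection equals an independent correlation recount under noise", {
  d <- small_design(seed = 13L)
  states <- simulate_trait(d, trait_config(seed = 20L), seasonal = FALSE)
  cfg <- site_config(n_sites = 50, n_age_sites = 30, noise_sd = 0.04, seed = 21)
  b <- simulate_beta_matrix(d, states, cfg)
  sel <- select_age_sites(b, d$age, threshold = 0.7)
  recount <- character(0)  # brute-force, site by site
  for (i in seq_len(nrow(b))) {
    y <- unclass(b)[i, ]
    if (sd(y) > 0 && abs(cor(y, d$age)) > 0.7)
      recount <- c(recount, rownames(b)[i])
  }
  expect_setequal(sel, recount)
})

test_that("outputs are reproducible bit for bit from config and seed", {
  d <- small_design(seed = 17L)
  t1 <- simulate_trait(d, trait_config(seed = 5), seasonal = TRUE)
  t2 <- simulate_trait(d, trait_config(seed = 5), seasonal = TRUE)
  expect_identical(t1, t2)
  b1 <- simulate_beta_matrix(d, t1, site_config(n_sites = 20, n_age_sites = 10, seed = 6))
  b2 <- simulate_beta_matrix(d, t1, site_config(n_sites = 20, n_age_sites = 10, seed = 6))
  expect_identical(b1, b2)
  expect_identical(generate_study_table(seed = 4), generate_study_table(seed = 4))
})
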