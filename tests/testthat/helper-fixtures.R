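# shared fixtures, all built in code

# a small longitudinal design: fast to simulate and fit
small_design <- function(seed = 42L, n = 20L, total = 48L, n_consec = 3L) {
  generate_design(design_config(n_individuals = n, n_samples_total = total,
                                n_consecutive = n_consec, seed = seed))
}

# noiseless pacemaker-model data: states linear in age, exact site relations
epm_toy <- function(n_sites = 5L, ages = c(1, 2, 4, 7, 9, 12), seed = 7L) {
  set.seed(seed)
  rate <- runif(n_sites, 0.005, 0.02) * sample(c(-1, 1), n_sites, TRUE)
  offset <- runif(n_sites, 0.3, 0.6)
  beta <- outer(rate, ages) + offset
  list(beta = beta_matrix(beta, sprintf("cg%02d", seq_len(n_sites)),
                          sprintf("s%02d", seq_along(ages))),
       ages = ages, rate = rate, offset = offset)
}

# least-squares affine alignment of x onto y, returns aligned x
affine_align <- function(x, y) {
  co <- stats::coef(stats::lm(y ~ x))
  co[1] + co[2] * x
}
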