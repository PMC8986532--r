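# Synthetic data with the statistical structure the analysis assumes:
# a longitudinal sampling design restricted to the active season, latent
# epigenetic states that accrue only outside hibernation, and per-site
# linear methylation--state relations with noise.
#
# Conventions: study day 1 = 1 May. Hibernation (winter) occupies study days
# 139-352 (16 Sep - 17 Apr); the active season spans the wrap, days 353-365
# followed by 1-138 of the next study year (151 days). Field sampling is
# narrower still: days 362-365 and 1-112 (27 Apr - 20 Aug). On an absolute
# day axis (day = year*365 + doy) the sampling window of one season is a
# contiguous 116-day block, which the generator exploits.

.WINTER <- c(139L, 352L)
.ACTIVE_DAYS_PER_YEAR <- 365L - (.WINTER[2] - .WINTER[1] + 1L)  # 151

#' Configuration for a synthetic sampling design
#'
#' Defaults emulate the structure of the field study: 73 females, 149
#' samples total with 1-8 per individual, ages spanning 0.01-12.04 years,
#' collection restricted to study days 362-365 and 1-112, and 11 individuals
#' sampled in consecutive active seasons with at least 2 samples in one
#' season and 1 in the other (the subset used for the ageing-rate contrast).
#'
#' @param n_individuals Number of animals.
#' @param n_samples_total Total samples; `NULL` draws per-animal counts
#'   uniformly from `samples_per_individual` instead.
#' @param samples_per_individual Length-2 integer range of samples per animal.
#' @param age_range Length-2 range (years) spanned by ages at sampling; both
#'   endpoints are realized (to day resolution) by the design.
#' @param age_scale Mean of the (truncated) exponential distribution from
#'   which interior ages at last sampling are drawn. The default `Inf`
#'   spreads ages uniformly, matching a deliberately age-stratified sample
#'   selection; a finite scale gives the right-skewed structure of an
#'   unselected wild population.
#' @param sampling_window Integer study days on which samples may fall.
#' @param trap_interval Length-2 range of days between successive captures
#'   of the same animal within a season: trapping runs in biweekly
#'   sessions and a recapture typically happens one to a few sessions
#'   after the previous one.
#' @param natal_window Length-2 range of study days for burrow emergence.
#' @param n_consecutive Number of animals sampled in consecutive seasons
#'   (clamped to what the per-animal counts allow).
#' @param seed Integer seed.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_individuals = 73L,
                          n_samples_total = 149L,
                          samples_per_individual = c(1L, 8L),
                          age_range = c(0.01, 12.04),
                          age_scale = Inf,
                          sampling_window = c(362:365, 1:112),
                          trap_interval = c(10L, 60L),
                          natal_window = c(30L, 90L),
                          n_consecutive = 11L,
                          seed = 1L) {
  stopifnot(n_individuals >= 1, length(samples_per_individual) == 2,
            samples_per_individual[1] >= 1,
            samples_per_individual[2] >= samples_per_individual[1],
            length(age_range) == 2, age_range[1] >= 0,
            age_range[2] >= age_range[1])
  sampling_window <- sort(unique(as.integer(sampling_window)))
  if (length(sampling_window) == 0L) stop("empty sampling window")
  if (any(sampling_window < 1L | sampling_window > 365L))
    stop("sampling window must lie in 1..365")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_samples_total = if (is.null(n_samples_total)) NULL else as.integer(n_samples_total),
                 samples_per_individual = as.integer(samples_per_individual),
                 age_range = as.numeric(age_range),
                 age_scale = age_scale,
                 sampling_window = sampling_window,
                 trap_interval = as.integer(trap_interval),
                 natal_window = as.integer(natal_window),
                 n_consecutive = as.integer(n_consecutive),
                 seed = as.integer(seed)),
            class = "design_config")
}

# season index of a sample: the April tail (doy >= 353) belongs to the
# following summer's active season
.season_index <- function(year, doy) year + as.integer(doy >= 353L)

# absolute day from (year, doy); day 1 of year 0 is absolute day 1
.abs_day <- function(year, doy) year * 365L + doy

# contiguous absolute-day block of the sampling window for season S,
# given the window is {362..365, 1..112}
.season_block <- function(S, window) {
  tail_days <- window[window >= 353L]
  head_days <- window[window < 353L]
  c(if (length(tail_days)) .abs_day(S - 1L, tail_days),
    if (length(head_days)) .abs_day(S, head_days))
}

#' Generate a synthetic sampling design
#'
#' Produces one row per blood sample with animal identity, exact age in
#' years (absolute day span / 365), study day-of-year, study year, season
#' index, and absolute day. Ages at the last sample per animal are
#' stratified over `age_range` so both endpoints are covered; consecutive-
#' season animals receive at least 2 samples in one season and at least 1
#' in the adjacent season, all other animals are sampled within a single
#' season (and so are excluded by the consecutive-year filter).
#'
#' @param cfg A [design_config()].
#' @return A sample table (`data.frame`) with columns `sample_id`,
#'   `animal_id`, `age`, `doy`, `year`, `season`, `abs_day`, `birth_doy`,
#'   `birth_abs`.
#' @export
generate_design <- function(cfg = design_config()) {
  stopifnot(inherits(cfg, "design_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  lo <- cfg$samples_per_individual[1]; hi <- cfg$samples_per_individual[2]

  # per-animal sample counts
  n_consec <- cfg$n_consecutive
  if (hi < 3L) n_consec <- 0L
  n_consec <- min(n_consec, n)
  if (is.null(cfg$n_samples_total)) {
    counts <- sample(lo:hi, n, replace = TRUE)
    if (n_consec > 0L) counts[seq_len(n_consec)] <- pmax(counts[seq_len(n_consec)], 3L)
  } else {
    total <- cfg$n_samples_total
    min_needed <- n * lo + n_consec * max(0L, 3L - lo)
    if (total < min_needed || total > n * hi)
      stop("n_samples_total incompatible with per-individual range")
    counts <- rep(lo, n)
    if (n_consec > 0L) counts[seq_len(n_consec)] <- pmax(lo, 3L)
    # keep one animal at a single sample to host the youngest age
    protected <- which(counts == lo)[1]
    while (sum(counts) < total) {
      open <- setdiff(which(counts < hi), protected)
      if (!length(open)) open <- which(counts < hi)
      i <- if (length(open) == 1L) open else sample(open, 1L)
      counts[i] <- counts[i] + 1L
    }
  }
  consec <- if (n_consec > 0L) seq_len(n_consec) else integer(0)

  # stratified ages at last sample (right-skewed interior, endpoints
  # realized); youngest goes to a single-sample animal, consecutive-season
  # animals need enough lifespan to span two seasons
  targets <- if (n == 1L) mean(cfg$age_range) else {
    u <- (seq_len(n) - 0.5) / n
    lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
    q <- if (is.finite(cfg$age_scale)) {
      m <- cfg$age_scale
      lo - m * log(1 - u * (1 - exp(-(hi - lo) / m)))  # truncated exponential
    } else lo + u * (hi - lo)
    q[1] <- lo; q[n] <- hi
    q
  }
  assign_target <- rep(NA_real_, n)
  t_young <- targets[1]; t_rest <- targets[-1]
  old_enough <- t_rest >= 1.5
  if (length(consec)) {
    if (sum(old_enough) < length(consec))
      stop("age range too narrow for consecutive-season animals")
    pick <- sample(which(old_enough), length(consec))
    assign_target[consec] <- t_rest[pick]
    t_rest <- t_rest[-pick]
  }
  singles <- setdiff(which(counts == min(counts)), consec)
  young_host <- if (length(singles)) singles[1] else setdiff(seq_len(n), consec)[1]
  assign_target[young_host] <- t_young
  open <- which(is.na(assign_target))
  assign_target[open] <- t_rest[sample(length(t_rest))]

  birth_doy <- sample(cfg$natal_window[1]:cfg$natal_window[2], n, replace = TRUE)
  window <- cfg$sampling_window

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    b_abs <- .abs_day(0L, birth_doy[i])
    # land the last sample on a window day near the target age
    off0 <- as.integer(round(assign_target[i] * 365))
    shift_ok <- function(s) {
      d <- ((b_abs + off0 + s - 1L) %% 365L) + 1L
      d %in% window
    }
    s_seq <- c(0L, as.integer(rbind(-(1:182), 1:182)))
    ok <- s_seq[vapply(s_seq, shift_ok, logical(1))]
    stopifnot(length(ok) > 0)
    s <- ok[1]
    # avoid overshooting the configured maximum age
    if ((off0 + s) / 365 > cfg$age_range[2] + 1e-9) {
      neg <- ok[ok < s]
      if (length(neg)) s <- neg[1]
    }
    last_abs <- b_abs + off0 + s
    last_year <- (last_abs - 1L) %/% 365L
    last_doy <- ((last_abs - 1L) %% 365L) + 1L
    S <- .season_index(last_year, last_doy)
    valid_S <- .season_block(S, window)
    valid_S <- valid_S[valid_S > b_abs]
    idx_last <- match(last_abs, valid_S)

    c_i <- counts[i]
    # earlier same-season captures step back by the trap interval
    # (biweekly field protocol), compressed when the season block, the
    # animal's birth or the minimum sampling age leaves too little room
    min_off <- as.integer(ceiling(cfg$age_range[1] * 365))
    step_back <- function(anchor, k, floor_abs) {
      floor_abs <- max(floor_abs, b_abs + min_off - 1L)
      if (k == 0L) return(integer(0))
      gaps <- sample(cfg$trap_interval[1]:cfg$trap_interval[2], k, replace = TRUE)
      days <- anchor - cumsum(gaps)
      if (any(days <= floor_abs)) {
        pool <- seq.int(floor_abs + 1L, anchor - 1L)
        if (length(pool) < k) stop("sampling window too small for requested samples")
        days <- sort(sample_int(pool, k))
      }
      sort(days)
    }
    if (i %in% consec) {
      # split samples across seasons S-1 and S; >=1 in each (>=2 in one
      # holds automatically since c_i >= 3)
      valid_prev <- .season_block(S - 1L, window)
      valid_prev <- valid_prev[valid_prev > b_abs]
      k_lo <- max(1L, c_i - length(valid_prev))
      k_hi <- min(c_i - 1L, length(valid_S))
      if (k_lo > k_hi) stop("animal too young to span consecutive seasons")
      k_late <- if (k_lo == k_hi) k_lo else sample(k_lo:k_hi, 1L)
      if (idx_last < k_late) {  # push the last sample later to make room
        last_abs <- valid_S[k_late]
        idx_last <- k_late
      }
      floor_late <- valid_S[1] - 1L
      late_extra <- step_back(last_abs, k_late - 1L, floor_late)
      k_early <- c_i - k_late
      anchor_early <- sample_int(valid_prev[valid_prev >= stats::quantile(valid_prev, 0.5)], 1L)
      early <- c(step_back(anchor_early, k_early - 1L,
                           max(valid_prev[1] - 1L, b_abs)), anchor_early)
      days <- c(early, late_extra, last_abs)
    } else {
      if (length(valid_S) < c_i)
        stop("sampling window too small for requested samples")
      if (idx_last < c_i) {  # push the last sample later to make room
        last_abs <- valid_S[c_i]
        idx_last <- c_i
      }
      days <- c(step_back(last_abs, c_i - 1L, valid_S[1] - 1L), last_abs)
    }
    yr <- (days - 1L) %/% 365L
    dy <- ((days - 1L) %% 365L) + 1L
    rows[[i]] <- data.frame(
      sample_id = sprintf("A%02d_s%d", i, seq_len(c_i)),
      animal_id = sprintf("A%02d", i),
      age = (days - b_abs) / 365,
      doy = dy, year = yr, season = .season_index(yr, dy),
      abs_day = days, birth_doy = birth_doy[i], birth_abs = b_abs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_sample_table(out)
}

#' Configuration for simulated longitudinal traits
#'
#' Two trait families: a non-seasonal trait increasing linearly with age at
#' `daily_rate_flat` per day, and a seasonal trait that accrues
#' `active_daily_rate` per active-season day and stalls during winter
#' (study days 139-352). The default active rate, `daily_rate_flat * 365 /
#' 151`, equalizes the two traits' annual increase over the 151-day active
#' window; `active_daily_rate` can be set explicitly instead (e.g. 0.0164).
#' Animal-level intercepts and sample-level residuals are Gaussian with the
#' configured variances.
#'
#' @param daily_rate_flat Non-seasonal increase per day of age.
#' @param active_daily_rate Seasonal increase per active day; `NULL` derives
#'   the rate-equalizing default.
#' @param winter_days Inclusive study-day interval with zero accrual.
#' @param var_individual Among-animal intercept variance.
#' @param var_residual Residual (within-sample) variance.
#' @param baseline Trait value at birth, before random effects.
#' @param seed Integer seed.
#' @return A list of class `trait_config`.
#' @export
trait_config <- function(daily_rate_flat = 0.004,
                         active_daily_rate = NULL,
                         winter_days = c(139L, 352L),
                         var_individual = 0.329,
                         var_residual = 0.294,
                         baseline = 0,
                         seed = 1L) {
  stopifnot(var_individual >= 0, var_residual >= 0,
            length(winter_days) == 2, winter_days[1] >= 1, winter_days[2] <= 365,
            winter_days[1] <= winter_days[2])
  n_active <- 365L - (winter_days[2] - winter_days[1] + 1L)
  if (is.null(active_daily_rate))
    active_daily_rate <- daily_rate_flat * 365 / n_active
  structure(list(daily_rate_flat = daily_rate_flat,
                 active_daily_rate = active_daily_rate,
                 winter_days = as.integer(winter_days),
                 var_individual = var_individual,
                 var_residual = var_residual,
                 baseline = baseline, seed = as.integer(seed)),
            class = "trait_config")
}

# active days accrued in absolute-day interval (0, t]
.active_days_to <- function(t, winter_days) {
  flag <- as.numeric(!(seq_len(365L) >= winter_days[1] & seq_len(365L) <= winter_days[2]))
  cum <- cumsum(flag)
  per_year <- cum[365L]
  full <- t %/% 365L
  rem <- t %% 365L
  full * per_year + ifelse(rem == 0L, 0, cum[pmax(rem, 1L)] * (rem > 0L))
}

#' Simulate a longitudinal trait on a sampling design
#'
#' @param design A sample table from [generate_design()] (needs `abs_day`
#'   and `birth_abs` when `seasonal = TRUE`).
#' @param cfg A [trait_config()].
#' @param seasonal If `TRUE`, accrual occurs only outside `winter_days`,
#'   integrated along each animal's life from birth; if `FALSE`, accrual is
#'   `daily_rate_flat` per day of age.
#' @return Numeric vector of trait values, one per design row.
#' @export
simulate_trait <- function(design, cfg = trait_config(), seasonal = FALSE) {
  stopifnot(inherits(cfg, "trait_config"), nrow(design) > 0)
  set.seed(cfg$seed)
  animals <- unique(design$animal_id)
  b <- stats::rnorm(length(animals), 0, sqrt(cfg$var_individual))
  names(b) <- animals
  e <- stats::rnorm(nrow(design), 0, sqrt(cfg$var_residual))
  if (seasonal) {
    if (!all(c("abs_day", "birth_abs") %in% names(design)))
      stop("seasonal trait needs abs_day and birth_abs columns")
    act <- .active_days_to(design$abs_day, cfg$winter_days) -
      .active_days_to(design$birth_abs, cfg$winter_days)
    mu <- cfg$baseline + cfg$active_daily_rate * act
  } else {
    mu <- cfg$baseline + cfg$daily_rate_flat * (design$age * 365)
  }
  as.numeric(mu + b[design$animal_id] + e)
}

#' Configuration for a synthetic beta matrix
#'
#' @param n_sites Total CpG sites.
#' @param n_age_sites Sites whose methylation is linear in the latent state.
#' @param rate_range Magnitude range of per-site rates (beta units per state
#'   unit).
#' @param offset_range Range of per-site offsets (methylation at state 0).
#' @param noise_sd Gaussian noise standard deviation (beta units).
#' @param mixed_signs If `TRUE` (default), rate signs are random.
#' @param seed Integer seed.
#' @return A list of class `site_config`.
#' @export
site_config <- function(n_sites = 400L, n_age_sites = 309L,
                        rate_range = c(0.01, 0.04),
                        offset_range = c(0.05, 0.95),
                        noise_sd = 0.03, mixed_signs = TRUE, seed = 1L) {
  stopifnot(n_age_sites <= n_sites, noise_sd >= 0,
            rate_range[1] <= rate_range[2])
  structure(list(n_sites = as.integer(n_sites),
                 n_age_sites = as.integer(n_age_sites),
                 rate_range = rate_range, offset_range = offset_range,
                 noise_sd = noise_sd, mixed_signs = mixed_signs,
                 seed = as.integer(seed)),
            class = "site_config")
}

#' Simulate a methylation beta matrix from latent states
#'
#' Age-informative sites follow `beta = rate * state + offset + noise`,
#' clipped to [0,1]; the remaining sites are state-independent noise around
#' their offsets. Offsets of age sites are drawn so that the noiseless
#' values stay inside [0.02, 0.98] over the observed state range, keeping
#' clipping rare.
#'
#' @param design Sample table (supplies sample ids).
#' @param states Numeric latent state per design row.
#' @param cfg A [site_config()].
#' @return A [beta_matrix()] with attributes `age_sites` (ids), `rates`,
#'   `offsets` (generating parameters, for recovery tests).
#' @export
simulate_beta_matrix <- function(design, states, cfg = site_config()) {
  stopifnot(inherits(cfg, "site_config"), nrow(design) == length(states))
  set.seed(cfg$seed)
  p <- cfg$n_sites; pa <- cfg$n_age_sites; n <- length(states)
  rate <- stats::runif(pa, cfg$rate_range[1], cfg$rate_range[2])
  if (cfg$mixed_signs) rate <- rate * sample(c(-1, 1), pa, replace = TRUE)
  s_lo <- min(states); s_hi <- max(states)
  off_lo <- pmax(cfg$offset_range[1], 0.02 - rate * ifelse(rate > 0, s_lo, s_hi))
  off_hi <- pmin(cfg$offset_range[2], 0.98 - rate * ifelse(rate > 0, s_hi, s_lo))
  off_hi <- pmax(off_hi, off_lo)  # degenerate ranges collapse to a point
  offset <- stats::runif(pa, off_lo, off_hi)
  site_ids <- sprintf("cg%05d", seq_len(p))
  beta <- matrix(NA_real_, p, n)
  if (pa > 0)
    beta[seq_len(pa), ] <- outer(rate, states) + offset +
      stats::rnorm(pa * n, 0, cfg$noise_sd)
  if (p > pa) {
    off2 <- stats::runif(p - pa, cfg$offset_range[1], cfg$offset_range[2])
    beta[(pa + 1L):p, ] <- off2 + stats::rnorm((p - pa) * n, 0, cfg$noise_sd)
  }
  beta <- pmin(pmax(beta, 0), 1)
  out <- beta_matrix(beta, site_ids = site_ids, sample_ids = design$sample_id)
  attr(out, "age_sites") <- site_ids[seq_len(pa)]
  attr(out, "rates") <- rate
  attr(out, "offsets") <- offset
  out
}

#' Generate a synthetic stand-in for the study's per-sample table
#'
#' Builds the default sampling design and attaches a latent epigenetic
#' state with the features the analysis is designed to detect: accrual
#' only during the active season (stalling across hibernation), a concave
#' age profile (faster state change before sexual maturity at ~2 years,
#' decelerating afterwards), and among-animal and residual variances as
#' reported for the fitted state model. A clock-style age estimate
#' tracking chronological age is attached as well. This is a synthetic
#' emulation of the study table's structure, not the deposited data.
#'
#' The mean state at `u` active-years of life follows the concave curve
#' `adult_rate * u + boost * (1 - exp(-u / tau))` (early slope
#' `adult_rate + boost/tau`, late slope `adult_rate`), affine-aligned onto
#' the chronological-age axis: pacemaker states are identified only up to
#' an affine transformation and the age-initialized fit anchors them to
#' the age scale, so the emulated state column lives in that gauge too.
#'
#' The deviation around that mean has three parts whose variances sum to
#' the reported model variances: a per-animal intercept (variance
#' `var_individual`), a slowly varying within-animal trajectory process
#' (exponential autocorrelation with time scale `traj_time` days), and a
#' small independent measurement error (`meas_sd`) reflecting that latent
#' states estimated from hundreds of CpG sites carry little sampling
#' noise. A fast iid residual of the full reported magnitude would make
#' short-interval ageing rates pure noise, contradicting the rate
#' contrasts this table is meant to emulate.
#'
#' @param seed Integer seed.
#' @param adult_rate Late-life state accrual per active-year.
#' @param boost Total extra state accrued through the juvenile phase.
#' @param tau Time scale (active-years) of the juvenile phase.
#' @param var_individual Among-animal intercept variance.
#' @param var_residual Total within-animal variance (trajectory +
#'   measurement).
#' @param meas_sd Measurement-error standard deviation.
#' @param traj_time Autocorrelation time (days) of the trajectory process.
#' @param clock_sd Residual s.d. of the clock-style age column.
#' @return A sample table with `epigenetic_state` and `clock_age` columns.
#' @export
generate_study_table <- function(seed = 1L, adult_rate = 0.55, boost = 4.5,
                                 tau = 1, var_individual = 0.329,
                                 var_residual = 0.294, meas_sd = 0.1,
                                 traj_time = 730, clock_sd = 0.5) {
  stopifnot(meas_sd^2 <= var_residual)
  design <- generate_design(design_config(seed = seed))
  u <- (.active_days_to(design$abs_day, .WINTER) -
          .active_days_to(design$birth_abs, .WINTER)) / .ACTIVE_DAYS_PER_YEAR
  g <- adult_rate * u + boost * (1 - exp(-u / tau))
  co <- stats::coef(stats::lm(design$age ~ g))  # the pacemaker's age gauge
  mu <- co[1] + co[2] * g
  set.seed(seed + 1L)
  animals <- unique(design$animal_id)
  b <- stats::rnorm(length(animals), 0, sqrt(var_individual))
  names(b) <- animals
  v_traj <- var_residual - meas_sd^2
  traj <- numeric(nrow(design))
  for (id in animals) {
    j <- which(design$animal_id == id)
    D <- abs(outer(design$abs_day[j], design$abs_day[j], "-"))
    Sg <- v_traj * exp(-D / traj_time)
    traj[j] <- drop(crossprod(chol(Sg), stats::rnorm(length(j))))
  }
  design$epigenetic_state <- mu + b[design$animal_id] + traj +
    stats::rnorm(nrow(design), 0, meas_sd)
  design$clock_age <- design$age + stats::rnorm(nrow(design), 0, clock_sd)
  design
}
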