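## Synthetic-cohort generator. Compositions are logistic normal on the
## simplex (multivariate normal on the ilr scale, mapped back and closed to
## 1440 min) -- the distribution under which the downstream ilr regression
## model is correctly specified. Covariate marginals and default effect
## sizes emulate a two-site Australian cohort of healthy 60-70 year olds.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  expr
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default mean 24-h time-use composition (minutes/day)
#'
#' Sleep 503, SB 668, LPA 178, MVPA 89 min/day, closed to 1440 — the
#' arithmetic sample means of a healthy, highly active older-adult cohort.
#'
#' @return Named composition vector summing to 1440.
#' @export
default_mean_composition <- function() {
  closure(c(sleep = 503, sb = 668, lpa = 178, mvpa = 89))
}

#' Default ilr-scale covariance of the generator
#'
#' Diagonal covariance on the pivot-coordinate scale, derived by the delta
#' method from minute-scale coefficients of variation typical of wrist
#' accelerometry in this age group (sleep 503±57, SB 668±90, LPA 178±50,
#' MVPA 89±47 min/day).
#'
#' @return 3x3 diagonal matrix.
#' @export
default_ilr_covariance <- function() diag(c(0.041, 0.072, 0.179))

#' Default covariate distribution parameters
#'
#' Marginals for the simulated participant table: truncated-normal age
#' within the 60-70 eligibility window (65.5 ± 3.0), 68% female, two study
#' sites (Adelaide 207/384), education 16.5 ± 3.2 years, smoking category
#' probabilities (current/previous/never), PSQI sleep-quality item
#' probabilities for ratings 0-3, gamma-distributed TV minutes, and
#' recreational-PA category probabilities with within-category minute
#' distributions.
#'
#' @return Named list of parameters consumed by [generate_covariates()].
#' @export
covariate_defaults <- function() {
  list(
    age_mean = 65.5, age_sd = 3.0, age_bounds = c(60, 70),
    p_female = 263 / 384,
    p_adelaide = 207 / 384,
    edu_mean = 16.5, edu_sd = 3.2, edu_bounds = c(6, 30),
    smoking_probs = c(current = 143, previous = 7, never = 234) / 384,
    sleep_rating_probs = c(0.27, 0.54, 0.17, 0.02),
    tv_mean = 130, tv_sd = 80,
    recpa_probs = c(none = 207 / 384, upto30 = 1 - 207 / 384 - 0.267,
                    over30 = 0.267),
    recpa_upto30_mean = 19, recpa_upto30_sd = 8,
    recpa_over30_mean = 80, recpa_over30_sd = 53
  )
}

check_probs <- function(p, what) {
  if (any(p < 0) || any(p > 1)) stop(what, " probabilities must lie in [0, 1]")
  invisible(p)
}

#' Generate logistic-normal time-use compositions
#'
#' Draws multivariate-normal ilr vectors centred at the ilr image of
#' `mean_composition`, maps them back through the inverse ilr and closes to
#' 1440 min. With a zero covariance every draw equals the closed mean.
#'
#' @param n Number of participants.
#' @param mean_composition Strictly positive 4-part composition (minutes).
#' @param ilr_covariance 3x3 symmetric positive-semidefinite matrix on the
#'   ilr scale.
#' @param seed Integer RNG seed (optional; draws are deterministic given
#'   the seed).
#' @return n x 4 matrix of compositions, rows summing to 1440.
#' @export
generate_compositions <- function(n, mean_composition = default_mean_composition(),
                                  ilr_covariance = default_ilr_covariance(),
                                  seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (any(mean_composition <= 0)) stop("mean composition parts must be > 0")
  ilr_covariance <- as.matrix(ilr_covariance)
  if (!isTRUE(all.equal(ilr_covariance, t(ilr_covariance))) ||
      any(eigen(ilr_covariance, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("ilr covariance must be symmetric positive semidefinite")
  mu <- ilr_transform(closure(mean_composition))
  z <- with_seed(seed, MASS::mvrnorm(n, mu = mu, Sigma = ilr_covariance, tol = 1e-6))
  if (n == 1) z <- matrix(z, nrow = 1)
  ilr_inverse(z)
}

#' Generate a synthetic participant covariate table
#'
#' @param n Number of participants.
#' @param spec Parameter list, see [covariate_defaults()].
#' @param seed Integer RNG seed.
#' @return data.frame: `participant_id`, `age`, `sex` (female/male), `site`
#'   (Adelaide/Newcastle), `education` (years), `smoking`
#'   (current/previous/never), `sleep_rating` (0-3, PSQI quality item),
#'   `tv_minutes`, `recpa_minutes`.
#' @export
generate_covariates <- function(n, spec = covariate_defaults(), seed = NULL) {
  check_probs(c(spec$p_female, spec$p_adelaide, spec$smoking_probs,
                spec$sleep_rating_probs, spec$recpa_probs), "covariate")
  if (abs(sum(spec$smoking_probs) - 1) > 1e-8 ||
      abs(sum(spec$sleep_rating_probs) - 1) > 1e-8 ||
      abs(sum(spec$recpa_probs) - 1) > 1e-8)
    stop("category probabilities must sum to 1")
  with_seed(seed, {
    age <- rtrunc_norm(n, spec$age_mean, spec$age_sd,
                       spec$age_bounds[1], spec$age_bounds[2])
    sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
    site <- ifelse(stats::runif(n) < spec$p_adelaide, "Adelaide", "Newcastle")
    education <- rtrunc_norm(n, spec$edu_mean, spec$edu_sd,
                             spec$edu_bounds[1], spec$edu_bounds[2])
    smoking <- sample(names(spec$smoking_probs), n, replace = TRUE,
                      prob = spec$smoking_probs)
    sleep_rating <- sample(0:3, n, replace = TRUE,
                           prob = spec$sleep_rating_probs)
    tv_shape <- (spec$tv_mean / spec$tv_sd)^2
    tv_minutes <- stats::rgamma(n, shape = tv_shape,
                                rate = tv_shape / spec$tv_mean)
    recpa_cat <- sample(names(spec$recpa_probs), n, replace = TRUE,
                        prob = spec$recpa_probs)
    recpa_minutes <- numeric(n)
    k <- recpa_cat == "upto30"
    recpa_minutes[k] <- rtrunc_norm(sum(k), spec$recpa_upto30_mean,
                                    spec$recpa_upto30_sd, 1e-3, 30)
    k <- recpa_cat == "over30"
    ga <- (spec$recpa_over30_mean - 30) / spec$recpa_over30_sd
    recpa_minutes[k] <- 30 + stats::rgamma(sum(k), shape = ga^2,
                                           rate = ga^2 / (spec$recpa_over30_mean - 30))
    data.frame(participant_id = sprintf("P%04d", seq_len(n)),
               age = age, sex = sex, site = site, education = education,
               smoking = smoking, sleep_rating = as.integer(sleep_rating),
               tv_minutes = tv_minutes, recpa_minutes = recpa_minutes)
  })
}

## Indicator design for outcome generation: named columns the effect
## vectors can address directly.
covariate_indicators <- function(data) {
  cbind(age = data$age,
        education = data$education,
        female = as.numeric(data$sex == "female"),
        newcastle = as.numeric(data$site == "Newcastle"),
        smoking_current = as.numeric(data$smoking == "current"),
        smoking_previous = as.numeric(data$smoking == "previous"),
        sleep_bad = as.numeric(data$sleep_rating >= 2),
        recpa_none = as.numeric(data$recpa_minutes == 0),
        recpa_upto30 = as.numeric(data$recpa_minutes > 0 &
                                    data$recpa_minutes <= 30))
}

#' Generate outcomes as linear functions of ilr coordinates and covariates
#'
#' `y = intercept + beta_composition' z + beta_covariates' c
#'  (+ interaction terms) + N(0, noise_sd^2)`, where `z` are the pivot
#' coordinates under the default partition.
#'
#' @param data data.frame containing ilr columns `z1`,`z2`,`z3` and the
#'   covariate columns of [generate_covariates()].
#' @param beta_composition Numeric length 3, coefficients on (z1, z2, z3).
#' @param beta_covariates Named numeric over indicator columns: any of
#'   `age`, `education`, `female`, `newcastle`, `smoking_current`,
#'   `smoking_previous`, `sleep_bad`, `recpa_none`, `recpa_upto30`.
#' @param beta_interaction Optional named list; each element is a numeric
#'   length-3 vector of coefficients on `z * indicator`, named by the
#'   moderator indicator (e.g. `list(sleep_bad = c(0.4, 0, 0))`).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param intercept Intercept.
#' @param seed Integer RNG seed.
#' @return Numeric outcome vector.
#' @export
generate_outcomes <- function(data, beta_composition = c(0, 0, 0),
                              beta_covariates = NULL, beta_interaction = NULL,
                              noise_sd = 1, intercept = 0, seed = NULL) {
  if (length(beta_composition) != 3)
    stop("beta_composition must have length 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  z <- as.matrix(data[, c("z1", "z2", "z3")])
  y <- intercept + drop(z %*% beta_composition)
  ind <- covariate_indicators(data)
  if (!is.null(beta_covariates)) {
    bad <- setdiff(names(beta_covariates), colnames(ind))
    if (length(bad)) stop("unknown covariate effect(s): ",
                          paste(bad, collapse = ", "))
    y <- y + drop(ind[, names(beta_covariates), drop = FALSE] %*% beta_covariates)
  }
  if (!is.null(beta_interaction)) {
    bad <- setdiff(names(beta_interaction), colnames(ind))
    if (length(bad)) stop("unknown interaction moderator(s): ",
                          paste(bad, collapse = ", "))
    for (m in names(beta_interaction)) {
      b <- beta_interaction[[m]]
      if (length(b) != 3) stop("interaction coefficients must have length 3")
      y <- y + ind[, m] * drop(z %*% b)
    }
  }
  y + with_seed(seed, stats::rnorm(nrow(data), 0, noise_sd))
}

## clr coefficients from four pivot (behaviour-vs-remaining) betas:
## beta_pivot_j = sqrt(D/(D-1)) * clr_j, D = 4.
pivot_betas_to_ilr <- function(pivot_betas) {
  clr <- sqrt(3 / 4) * pivot_betas
  clr <- clr - mean(clr)   # project onto the sum-zero clr space
  drop(clr %*% ilr_basis(tu_parts()))
}

#' Default outcome-generating model for each cognitive outcome
#'
#' Five outcomes on their reporting scales: `global_cognition` (ACE-III
#' total, mean 95.1 ± 3.6) and four composite z-scores (`ltm`, `stm`,
#' `exec`, `speed`). Processing speed carries the only non-null
#' composition effect, specified through behaviour-vs-remaining pivot
#' coefficients (sleep 0.28, SB −0.33, LPA −0.16, MVPA 0.20); covariate
#' effects (site on global cognition and the memory composites, age and
#' sex on executive function, age on speed, education on global cognition,
#' no-recreational-PA on long-term memory) match the cross-sectional
#' pattern the generator emulates. All interaction effects are null by
#' default.
#'
#' @return Named list of per-outcome parameter lists (fields
#'   `beta_composition`, `beta_covariates`, `beta_interaction`,
#'   `noise_sd`, `intercept`).
#' @export
default_outcome_specs <- function() {
  speed_b <- pivot_betas_to_ilr(c(sleep = 0.28, sb = -0.33,
                                  lpa = -0.16, mvpa = 0.20))
  list(
    global_cognition = list(beta_composition = c(0, 0, 0),
                            beta_covariates = c(newcastle = -1.43, education = 0.22),
                            beta_interaction = NULL, noise_sd = 3.3,
                            intercept = 95.1 - 0.22 * 16.5 + 1.43 * 177 / 384),
    ltm = list(beta_composition = c(0, 0, 0),
               beta_covariates = c(newcastle = 0.25, recpa_none = -0.38),
               beta_interaction = NULL, noise_sd = 1, intercept = 0),
    stm = list(beta_composition = c(0, 0, 0),
               beta_covariates = c(newcastle = 0.17),
               beta_interaction = NULL, noise_sd = 1, intercept = 0),
    exec = list(beta_composition = c(0, 0, 0),
                beta_covariates = c(age = -0.05, female = -0.23),
                beta_interaction = NULL, noise_sd = 1, intercept = 0.05 * 65.5),
    speed = list(beta_composition = speed_b,
                 beta_covariates = c(age = -0.04),
                 beta_interaction = NULL, noise_sd = 1, intercept = 0.04 * 65.5)
  )
}

#' Cohort configuration
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#'
#' @param n Participant count (default 426, the enrolled roster size from
#'   which eligibility filtering proceeds).
#' @param seed Integer RNG seed for the whole cohort.
#' @param mean_composition,ilr_covariance Composition model, see
#'   [generate_compositions()].
#' @param covariate_spec See [covariate_defaults()].
#' @param outcome_specs See [default_outcome_specs()].
#' @param n_invalid_accel,n_missing_covariate Numbers of (disjoint)
#'   participants flagged as failing the accelerometry valid-week rule or
#'   given one missing covariate, for eligibility-filter testing.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n = 426, seed = 1,
                          mean_composition = default_mean_composition(),
                          ilr_covariance = default_ilr_covariance(),
                          covariate_spec = covariate_defaults(),
                          outcome_specs = default_outcome_specs(),
                          n_invalid_accel = 21, n_missing_covariate = 21) {
  if (n < 1) stop("n must be >= 1")
  if (n_invalid_accel + n_missing_covariate > n)
    stop("more exclusions than participants")
  structure(list(n = n, seed = as.integer(seed),
                 mean_composition = mean_composition,
                 ilr_covariance = ilr_covariance,
                 covariate_spec = covariate_spec,
                 outcome_specs = outcome_specs,
                 n_invalid_accel = n_invalid_accel,
                 n_missing_covariate = n_missing_covariate),
            class = "cohort_config")
}

#' Generate a full synthetic cohort
#'
#' Compositions, ilr coordinates, covariates, outcomes and eligibility
#' flags, deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return data.frame with minutes columns (`sleep`,`sb`,`lpa`,`mvpa`),
#'   ilr columns `z1..z3`, covariates, one outcome column per entry of
#'   `outcome_specs`, and `accel_valid` (logical). The config is attached
#'   as attribute `provenance`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  ## one RNG stream for every component, so no two draws can share a seed
  data <- with_seed(config$seed, {
    comps <- generate_compositions(config$n, config$mean_composition,
                                   config$ilr_covariance)
    cov <- generate_covariates(config$n, config$covariate_spec)
    data <- cbind(cov, as.data.frame(comps),
                  as.data.frame(ilr_transform(comps)))
    for (i in seq_along(config$outcome_specs)) {
      o <- config$outcome_specs[[i]]
      data[[names(config$outcome_specs)[i]]] <- generate_outcomes(
        data, o$beta_composition, o$beta_covariates, o$beta_interaction,
        o$noise_sd, o$intercept)
    }
    data$accel_valid <- TRUE
    n_excl <- config$n_invalid_accel + config$n_missing_covariate
    if (n_excl > 0) {
      idx <- sample.int(config$n, n_excl)
      if (config$n_invalid_accel > 0)
        data$accel_valid[idx[seq_len(config$n_invalid_accel)]] <- FALSE
      if (config$n_missing_covariate > 0)
        data$education[idx[config$n_invalid_accel +
                             seq_len(config$n_missing_covariate)]] <- NA
    }
    data
  })
  attr(data, "provenance") <- config
  data
}

#' Generate a synthetic epoch series realising per-day minute targets
#'
#' Builds a participant-week of 1-min epochs whose values fall in the
#' correct cut-point band for their class, with the sleep block recorded as
#' a diary interval and non-wear realised as a contiguous run of >= 60
#' epochs at <= 25 g-min, so the accelerometry chain recovers the target
#' minutes exactly.
#'
#' @param daily_targets data.frame with one row per day: `day_type`
#'   (weekday/weekend) and minute targets `sleep`, `sb`, `lpa`, `mvpa`,
#'   `nonwear` summing to 1440. A non-wear target in (0, 60) cannot be
#'   realised as a detectable run and is rejected.
#' @param participant_id Identifier attached to the series.
#' @param seed Integer RNG seed for the within-band epoch values.
#' @param mvpa_cap Upper bound of the MVPA band draw (g-min).
#' @return List of class `epoch_series`: `participant_id` and `days`, each
#'   day a list with `day_type`, `epochs` (length 1440) and
#'   `sleep_intervals` (`[start, end)` matrix).
#' @export
generate_epoch_series <- function(daily_targets, participant_id = "P0001",
                                  seed = NULL, mvpa_cap = 500) {
  need <- c("day_type", "sleep", "sb", "lpa", "mvpa", "nonwear")
  miss <- setdiff(need, names(daily_targets))
  if (length(miss)) stop("daily_targets missing: ", paste(miss, collapse = ", "))
  tot <- rowSums(daily_targets[, c("sleep", "sb", "lpa", "mvpa", "nonwear")])
  if (any(tot != EPOCHS_PER_DAY))
    stop("each day's targets must sum to ", EPOCHS_PER_DAY)
  if (any(daily_targets$nonwear > 0 & daily_targets$nonwear < 60))
    stop("non-wear targets in (0, 60) min cannot be realised as a detectable run")
  r <- accel_rules()
  with_seed(seed, {
    days <- lapply(seq_len(nrow(daily_targets)), function(i) {
      d <- daily_targets[i, ]
      band <- function(n, lo, hi) if (n > 0) lo + stats::runif(n) * (hi - lo) else numeric(0)
      ## blocks in order: sleep (diary), non-wear, SB, LPA, MVPA. Sleep
      ## epochs are quiet but worn (above the non-wear threshold), so a
      ## diary sleep block never extends a detectable non-wear run.
      epochs <- c(band(d$sleep, r$nonwear_threshold, r$sb_max),
                  band(d$nonwear, 0, r$nonwear_threshold),
                  band(d$sb, r$nonwear_threshold, r$sb_max),
                  band(d$lpa, r$sb_max, r$lpa_max),
                  band(d$mvpa, r$lpa_max, mvpa_cap))
      sl <- if (d$sleep > 0) cbind(start = 0L, end = as.integer(d$sleep))
            else cbind(start = integer(0), end = integer(0))
      list(day_type = as.character(d$day_type), epochs = epochs,
           sleep_intervals = sl)
    })
    structure(list(participant_id = participant_id, days = days),
              class = "epoch_series")
  })
}

#' Flatten an epoch series to the long epoch-table schema
#'
#' @param series An `epoch_series` from [generate_epoch_series()].
#' @return data.frame in the schema expected by [process_epochs()].
#' @export
epoch_series_to_df <- function(series) {
  do.call(rbind, lapply(seq_along(series$days), function(i) {
    d <- series$days[[i]]
    sleep_flag <- interval_mask(check_intervals(d$sleep_intervals, "sleep"))
    data.frame(participant_id = series$participant_id, day_index = i,
               day_type = d$day_type, epoch_index = 0:(EPOCHS_PER_DAY - 1L),
               value = d$epochs, in_sleep_interval = as.integer(sleep_flag))
  }))
}
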