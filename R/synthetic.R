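#' Configuration for the synthetic monitoring-data generator
#'
#' Bundles every knob of the generator into a validated list. Defaults
#' emulate the study system the package targets: six caribou populations
#' monitored for a decade, 6-22 collared females per population-year
#' (default 15), 50-252 females classified per aerial survey (default 150),
#' and vital rates generated from logit-linear models in total disturbance
#' `D` and productivity `P` whose coefficients are the published
#' mixed-model estimates (survival: 1.67, -0.77 on D, 1.22 on P;
#' recruitment: -0.15, -5.05 on lagged D, 2.41 on P squared).
#'
#' @param n_populations number of populations (>= 0).
#' @param years number of biological years simulated.
#' @param collared_per_pop_year target number of simultaneously collared
#'   females per population-year.
#' @param females_per_survey number of true adult females classified per
#'   aerial survey.
#' @param true_beta_survival length-3 numeric, logit-scale truth for annual
#'   survival: intercept, coefficient on `D`, coefficient on `P`.
#' @param true_beta_recruitment length-3 numeric, logit-scale truth for the
#'   calf/female probability: intercept, coefficient on lagged `D`,
#'   coefficient on `P^2`.
#' @param sigma_pop standard deviation of the population random intercept
#'   (logit scale, >= 0).
#' @param censor_prob per animal-year probability of right-censoring
#'   (collar loss, non-predation mortality).
#' @param frac_unclassified probability that a surveyed adult's sex is not
#'   determined.
#' @param female_frac_true true fraction of adults that are female; default
#'   is the sexed-survey fraction 453/699.
#' @param start_year first biological year (labelled by the calendar year
#'   containing its 1 April start).
#' @param d_start_range,d_step_range ranges for the initial disturbance
#'   proportion and its non-negative annual increment; trajectories are
#'   capped at 0.78 so generated `D` stays inside the observed 0.22-0.78.
#' @param p_range range of the productivity proportion `P` (observed
#'   0.04-0.85).
#' @param stagger_frac fraction of newly collared animals entering mid-year
#'   rather than on 1 April.
#' @param stagger_max_day latest entry day (days after 1 April) for
#'   staggered entries.
#' @param shared_random_effects if `TRUE` the same population intercept
#'   drives survival and recruitment; default `FALSE` (the two rates are
#'   modelled separately downstream).
#' @param n_pixels number of stand pixels for [generate_stand_pixels()].
#' @param pixel_noise_sd named numeric: Gaussian noise SD for pixel
#'   `height` (metres) and `proportion` attributes.
#' @param seed integer seed; every generator call is deterministic given
#'   the config.
#' @return an object of class `generator_config`.
#' @seealso [generate_ranges()], [generate_collar_histories()],
#'   [generate_surveys()], [generate_stand_pixels()]
#' @export
generator_config <- function(n_populations = 6,
                             years = 10,
                             collared_per_pop_year = 15,
                             females_per_survey = 150,
                             true_beta_survival = c(1.67, -0.77, 1.22),
                             true_beta_recruitment = c(-0.15, -5.05, 2.41),
                             sigma_pop = 0.2,
                             censor_prob = 0.1,
                             frac_unclassified = 0.05,
                             female_frac_true = 453 / 699,
                             start_year = 2005,
                             d_start_range = c(0.22, 0.60),
                             d_step_range = c(0, 0.02),
                             p_range = c(0.04, 0.85),
                             stagger_frac = 0.3,
                             stagger_max_day = 180,
                             shared_random_effects = FALSE,
                             n_pixels = 2000,
                             pixel_noise_sd = c(height = 0.8, proportion = 0.03),
                             seed = 1L) {
  stopifnot(
    is_count(n_populations, min = 0L),
    is_count(years), is_count(collared_per_pop_year),
    is_count(females_per_survey), is_count(n_pixels),
    length(true_beta_survival) == 3, length(true_beta_recruitment) == 3,
    is.finite(sigma_pop), sigma_pop >= 0,
    is_prob(censor_prob), is_prob(frac_unclassified),
    length(female_frac_true) == 1, female_frac_true > 0, female_frac_true < 1,
    is_prob(stagger_frac),
    length(d_start_range) == 2, length(d_step_range) == 2,
    length(p_range) == 2, all(d_step_range >= 0),
    all(pixel_noise_sd >= 0), length(seed) == 1, is.finite(seed)
  )
  structure(as.list(environment()), class = "generator_config")
}

#' Read a generator configuration from a JSON or YAML document
#'
#' The document holds any subset of [generator_config()]'s arguments by
#' name; omitted fields keep their defaults. YAML requires the `yaml`
#' package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(generator_config)))
  if (length(unknown)) {
    stop("unknown generator_config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(generator_config, vals)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic monitoring-data generator configuration\n")
  cat(sprintf("  %d population(s) x %d biological year(s), seed %d\n",
              x$n_populations, x$years, as.integer(x$seed)))
  cat(sprintf("  collars/pop-year: %d; females/survey: %d\n",
              x$collared_per_pop_year, x$females_per_survey))
  cat(sprintf("  survival truth    (logit): %s\n",
              paste(format(x$true_beta_survival), collapse = ", ")))
  cat(sprintf("  recruitment truth (logit): %s\n",
              paste(format(x$true_beta_recruitment), collapse = ", ")))
  cat(sprintf("  sigma_pop = %.3g, censor_prob = %.3g\n",
              x$sigma_pop, x$censor_prob))
  invisible(x)
}

april1 <- function(year) as.Date(sprintf("%d-04-01", year))

## population random intercepts, deterministic per config and rate
pop_intercepts <- function(config, rate) {
  offset <- if (config$shared_random_effects || rate == "survival") 7L else 8L
  set.seed(stage_seed(config$seed, offset))
  stats::rnorm(config$n_populations, 0, config$sigma_pop)
}

#' Generate population range tables (productivity and disturbance)
#'
#' One record per population per year. Productivity `P` is constant within
#' a population and drawn uniformly over `config$p_range`; the total
#' disturbance proportion `D` follows a non-decreasing trajectory
#' (disturbance accumulates faster than fires and cutblocks age out of the
#' 40-50 year disturbance window over a one-decade horizon), starting in
#' `d_start_range` and capped at 0.78.
#'
#' @param config a [generator_config()].
#' @return data frame with columns `population`, `year`, `P`, `D`.
#' @export
generate_ranges <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_populations == 0) {
    return(data.frame(population = character(), year = integer(),
                      P = numeric(), D = numeric()))
  }
  set.seed(stage_seed(config$seed, 1L))
  pops <- sprintf("pop%02d", seq_len(config$n_populations))
  years <- config$start_year + seq_len(config$years) - 1L
  out <- lapply(seq_along(pops), function(i) {
    P <- runif(1, config$p_range[1], config$p_range[2])
    d0 <- runif(1, config$d_start_range[1], config$d_start_range[2])
    steps <- runif(config$years - 1, config$d_step_range[1], config$d_step_range[2])
    D <- pmin(cumsum(c(d0, steps)), 0.78)
    data.frame(population = pops[i], year = years, P = P, D = D)
  })
  do.call(rbind, out)
}

#' Generate collar telemetry histories
#'
#' Simulates a roster of GPS-collared adult females per population. Each
#' animal-year survives with probability
#' `plogis(b0 + bD * D_t + bP * P + u_pop)`, `u_pop ~ N(0, sigma_pop^2)`.
#' Within a year the death waiting time is exponential from the entry date
#' (constant hazard), so the staggered-entry Kaplan-Meier estimator is
#' consistent for the annual probability. Censoring (collar removal,
#' non-predation mortality) strikes independently with `censor_prob` at a
#' uniform date and competes with death: the earlier event wins. Animals
#' lost to death or censoring are replaced the next 1 April (new recruits
#' may enter mid-year); survivors carry over, so raw histories span years
#' and must pass through [split_biological_years()].
#'
#' @param ranges output of [generate_ranges()].
#' @param config the same [generator_config()].
#' @return data frame with columns `animal_id`, `population`, `entry_date`,
#'   `exit_date`, `fate` (`"dead"` or `"censored"`).
#' @export
generate_collar_histories <- function(ranges, config) {
  stopifnot(inherits(config, "generator_config"), nrow(ranges) > 0)
  u <- pop_intercepts(config, "survival")
  set.seed(stage_seed(config$seed, 2L))
  b <- config$true_beta_survival
  pops <- unique(ranges$population)
  years <- sort(unique(ranges$year))
  res <- vector("list", length(pops))
  for (ip in seq_along(pops)) {
    pop <- pops[ip]
    rg <- ranges[ranges$population == pop, ]
    k <- config$collared_per_pop_year
    counter <- 0L
    ## ongoing animals: id and overall entry date
    ids <- character(0); entry_dates <- as.Date(character(0))
    closed <- list()
    for (iy in seq_along(years)) {
      yr <- years[iy]
      ystart <- april1(yr)
      D <- rg$D[rg$year == yr]
      p_surv <- plogis(b[1] + b[2] * D + b[3] * rg$P[1] + u[ip])
      n_new <- k - length(ids)
      if (n_new > 0) {
        new_ids <- sprintf("%s_a%04d", pop, counter + seq_len(n_new))
        counter <- counter + n_new
        stag <- runif(n_new) < config$stagger_frac
        e_day <- ifelse(stag, floor(runif(n_new, 0, config$stagger_max_day + 1)), 0)
        ids <- c(ids, new_ids)
        entry_dates <- c(entry_dates, ystart + e_day)
      }
      n <- length(ids)
      e <- as.numeric(entry_dates - ystart)    # 0 for carry-overs
      e[e < 0] <- 0
      hz <- -log(p_surv) / 365                 # per-day hazard
      t_death <- if (hz > 0) e + rexp(n, hz) else rep(Inf, n)
      cens_hit <- runif(n) < config$censor_prob
      t_cens <- ifelse(cens_hit, runif(n, e, 365), Inf)
      dies <- t_death <= 365 & t_death <= t_cens
      cens <- !dies & t_cens <= 365
      gone <- dies | cens
      if (any(gone)) {
        exit_day <- pmin(ifelse(dies, t_death, t_cens), 364)
        exit_date <- ystart + floor(exit_day[gone])
        closed[[length(closed) + 1L]] <- data.frame(
          animal_id = ids[gone], population = pop,
          entry_date = entry_dates[gone],
          exit_date = pmax(exit_date, entry_dates[gone]),
          fate = ifelse(dies[gone], "dead", "censored")
        )
      }
      ids <- ids[!gone]; entry_dates <- entry_dates[!gone]
    }
    if (length(ids)) {                          # alive at end of horizon
      closed[[length(closed) + 1L]] <- data.frame(
        animal_id = ids, population = pop, entry_date = entry_dates,
        exit_date = april1(years[length(years)] + 1L) - 1L,
        fate = "censored"
      )
    }
    res[[ip]] <- do.call(rbind, closed)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$population, out$animal_id), , drop = FALSE]
}

#' Generate aerial classification surveys
#'
#' One survey per population per year from the second simulated year on
#' (the calf cohort reflects conditions of the preceding year, so the
#' generating linear predictor uses the previous year's disturbance).
#' Calves are `Binomial(n_females, plogis(b0 + bD * D_{t-1} + bP2 * P^2 +
#' u_pop))`; adult males follow from `female_frac_true`; each adult is
#' independently recorded as unclassified with `frac_unclassified`.
#'
#' @inheritParams generate_collar_histories
#' @return data frame with columns `population`, `year`, `n_calves`,
#'   `n_adult_females`, `n_adult_males`, `n_adult_unclassified`.
#' @export
generate_surveys <- function(ranges, config) {
  stopifnot(inherits(config, "generator_config"), nrow(ranges) > 0)
  u <- pop_intercepts(config, "recruitment")
  set.seed(stage_seed(config$seed, 3L))
  b <- config$true_beta_recruitment
  pops <- unique(ranges$population)
  years <- sort(unique(ranges$year))
  rows <- list()
  for (ip in seq_along(pops)) {
    rg <- ranges[ranges$population == pops[ip], ]
    for (yr in years[-1]) {
      D_lag <- rg$D[rg$year == yr - 1L]
      p_calf <- plogis(b[1] + b[2] * D_lag + b[3] * rg$P[1]^2 + u[ip])
      n_f <- config$females_per_survey
      n_m <- round(n_f * (1 - config$female_frac_true) / config$female_frac_true)
      calves <- rbinom(1, n_f, p_calf)
      u_f <- rbinom(1, n_f, config$frac_unclassified)
      u_m <- rbinom(1, n_m, config$frac_unclassified)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pops[ip], year = yr, n_calves = calves,
        n_adult_females = n_f - u_f, n_adult_males = n_m - u_m,
        n_adult_unclassified = u_f + u_m
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate forest stand pixels
#'
#' Emulates 250-m inventory pixels sampled across a boreal landscape:
#' stand age uniform on 0-120 years; height and canopy cover follow
#' saturating growth curves whose asymptote and rate increase with
#' productivity `P`; the deciduous fraction is unimodal in age with its
#' peak at 20 years post-disturbance and a level increasing with `P`.
#' Canopy cover is recorded over the whole pixel (multiplied by the treed
#' fraction) and the deciduous fraction over the vegetated fraction, so the
#' cover corrections of [correct_canopy_cover()] and [correct_deciduous()]
#' are exercised; about 2% of pixels are treeless and must be dropped.
#'
#' @param config a [generator_config()]; `n_pixels` and `pixel_noise_sd`
#'   control size and noise.
#' @return data frame with columns `age`, `height`, `canopy_cover_raw`,
#'   `treed_fraction`, `deciduous_raw`, `vegetated_fraction`, `P`.
#' @export
generate_stand_pixels <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config$seed, 4L))
  n <- config$n_pixels
  hsd <- config$pixel_noise_sd[["height"]]
  psd <- config$pixel_noise_sd[["proportion"]]
  age <- runif(n, 0, 120)
  P <- runif(n, config$p_range[1], config$p_range[2])
  h_asym <- 8 + 14 * P
  h_rate <- 0.015 + 0.035 * P
  height <- pmax(0, h_asym * (1 - exp(-h_rate * age)) + rnorm(n, 0, hsd))
  c_asym <- 0.5 + 0.5 * P
  c_rate <- 0.03 + 0.05 * P
  canopy <- pmin(1, pmax(0, c_asym * (1 - exp(-c_rate * age)) + rnorm(n, 0, psd)))
  treed <- runif(n, 0.4, 1)
  treed[runif(n) < 0.02] <- 0                  # treeless pixels, to be filtered
  d_peak <- 0.08 + 0.35 * P
  decid <- pmin(1, pmax(0, d_peak * (age / 20) * exp(1 - age / 20) +
                          rnorm(n, 0, psd)))
  veg <- runif(n, 0.6, 1)
  data.frame(age = age, height = height,
             canopy_cover_raw = canopy * treed, treed_fraction = treed,
             deciduous_raw = decid * veg, vegetated_fraction = veg, P = P)
}
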