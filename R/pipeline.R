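## End-to-end pipeline: generate or read data, estimate vital rates, fit
## the mixed models, solve the viability thresholds, write every artefact
## plus a log of all records filtered along the way.

#' Read and write the pipeline's CSV tables
#'
#' Fixed schemas, ISO-8601 dates, "." decimal separator, proportions as
#' decimals in `[0, 1]`:
#' * collars: `animal_id, population, entry_date, exit_date, fate`
#' * surveys: `population, year, n_calves, n_adult_females, n_adult_males,
#'   n_adult_unclassified`
#' * ranges (long): `population, year, P, D`
#' * pixels: `age, height, canopy_cover_raw, treed_fraction,
#'   deciduous_raw, vegetated_fraction, P`
#'
#' @param path file path.
#' @return the table as a data frame (readers) or `path` invisibly
#'   (writer).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_collars <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "population", "entry_date", "exit_date",
                  "fate") %in% names(d)))
  d$entry_date <- as.Date(d$entry_date)
  d$exit_date <- as.Date(d$exit_date)
  stopifnot(all(d$fate %in% c("dead", "censored", "alive_at_year_end")))
  d
}

#' @rdname pipeline_io
#' @export
read_surveys <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "year", "n_calves", "n_adult_females",
            "n_adult_males", "n_adult_unclassified")
  stopifnot(all(need %in% names(d)), all(d[need[-1]] >= 0))
  d
}

#' @rdname pipeline_io
#' @export
read_ranges <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "year", "P", "D") %in% names(d)),
            all(d$P >= 0 & d$P <= 1), all(d$D >= 0 & d$D <= 1))
  d
}

#' @rdname pipeline_io
#' @export
read_pixels <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "height", "canopy_cover_raw", "treed_fraction",
                  "deciduous_raw", "vegetated_fraction", "P") %in% names(d)))
  d
}

#' Write a fitted vital-rate model to JSON / read it back
#'
#' Serialises coefficients, covariance, random-intercept SD, link and
#' sample size; reading back yields a coefficient-only
#' [vital_rate_model()] suitable for prediction and threshold solving.
#'
#' @param model a `vital_rate_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `vital_rate_model` (reader).
#' @export
write_vital_rate_model <- function(model, path) {
  stopifnot(inherits(model, "vital_rate_model"))
  jsonlite::write_json(list(
    rate = model$rate, beta = as.numeric(model$beta),
    vcov = if (!is.null(model$vcov)) unname(model$vcov),
    sigma_pop = model$sigma_pop, link = model$link,
    n_obs = if (!is.na(model$n_obs)) model$n_obs
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_vital_rate_model
#' @export
read_vital_rate_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- vital_rate_model(j$rate, beta = j$beta, vcov = j$vcov,
                        sigma_pop = j$sigma_pop)
  if (!is.null(j$n_obs)) m$n_obs <- as.integer(j$n_obs)
  m
}

#' Pipeline configuration
#'
#' One document controlling an end-to-end run. Either a
#' [generator_config()] (synthetic run) or a list of input paths
#' (`collars`, `surveys`, `ranges`, and optionally `pixels`) must be
#' given. The global `seed` fans out to the per-stage seeds by fixed
#' offsets, so identical configurations give byte-identical outputs.
#'
#' @param out_dir output directory (created if absent).
#' @param generator a [generator_config()], or `NULL` when reading inputs.
#' @param inputs named list of CSV paths, or `NULL` when generating.
#' @param seed global integer seed.
#' @param n_sim coefficient draws for the confidence threshold.
#' @param bootstrap_iter parametric-bootstrap iterations for coefficient
#'   CIs (0 skips the bootstrap).
#' @param nAGQ quadrature nodes for the mixed-model fits.
#' @param d_grid,p_grid viability-surface grids.
#' @param min_animals,min_individuals monitoring filters (defaults 6
#'   collared females, 50 surveyed individuals).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, generator = generator_config(),
                            inputs = NULL, seed = 1L, n_sim = 10000,
                            bootstrap_iter = 1000, nAGQ = 7,
                            d_grid = seq(0, 1, by = 0.01),
                            p_grid = seq(0, 1, by = 0.01),
                            min_animals = 6L, min_individuals = 50L) {
  stopifnot(!is.null(generator) || !is.null(inputs),
            length(seed) == 1, is.finite(seed))
  structure(as.list(environment()), class = "pipeline_config")
}

write_table <- function(d, dir, name) {
  path <- file.path(dir, name)
  sep <- if (grepl("\\.tsv$", name)) "\t" else ","
  write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full viability pipeline
#'
#' Generates (or reads) collar histories, aerial surveys, range tables and
#' stand pixels; estimates annual survival and recruitment with the
#' monitoring filters; fits both weighted binomial mixed models; solves
#' the viability surface and threshold curves; classifies each population
#' at its latest observed `(D, P)`; and writes every artefact to
#' `config$out_dir` together with a log of every record filtered and why.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a run report: list with the fitted models, the
#'   estimate tables, the `viability_surface`, the filter log, and the
#'   paths of all files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (!is.null(config$inputs)) {
    ranges <- read_ranges(config$inputs$ranges)
    collars <- read_collars(config$inputs$collars)
    surveys <- read_surveys(config$inputs$surveys)
    pixels <- if (!is.null(config$inputs$pixels))
      read_pixels(config$inputs$pixels)
  } else {
    gen <- config$generator
    gen$seed <- stage_seed(config$seed, 100L)
    ranges <- generate_ranges(gen)
    collars <- generate_collar_histories(ranges, gen)
    surveys <- generate_surveys(ranges, gen)
    pixels <- generate_stand_pixels(gen)
    paths$ranges <- write_table(ranges, config$out_dir, "ranges.csv")
    paths$collars <- write_table(collars, config$out_dir, "collars.csv")
    paths$surveys <- write_table(surveys, config$out_dir, "surveys.csv")
    paths$pixels <- write_table(pixels, config$out_dir, "pixels.csv")
  }

  ## vital-rate estimation with monitoring filters
  split <- split_biological_years(collars)
  est <- annual_survival(split, min_animals = config$min_animals)
  obs <- recruitment_observations(surveys, ranges,
                                  min_individuals = config$min_individuals)
  tag_stage <- function(d, stage) {
    data.frame(stage = rep(stage, nrow(d)), d)
  }
  filter_log <- rbind(
    tag_stage(attr(est, "filtered"), "survival"),
    tag_stage(attr(obs, "filtered"), "recruitment")
  )
  paths$survival_estimates <- write_table(est, config$out_dir,
                                          "survival_estimates.csv")
  paths$recruitment_observations <-
    write_table(obs, config$out_dir, "recruitment_observations.csv")
  paths$filter_log <- write_table(filter_log, config$out_dir,
                                  "filter_log.csv")

  ## mixed models
  sm <- fit_survival_model(est, ranges, nAGQ = config$nAGQ)
  rm_ <- fit_recruitment_model(obs, nAGQ = config$nAGQ)
  paths$survival_model <- write_vital_rate_model(
    sm, file.path(config$out_dir, "survival_model.json"))
  paths$recruitment_model <- write_vital_rate_model(
    rm_, file.path(config$out_dir, "recruitment_model.json"))
  coef_tab <- rbind(
    data.frame(rate = "survival", term = names(coef(sm)),
               estimate = as.numeric(coef(sm)),
               se = sqrt(diag(vcov(sm)))),
    data.frame(rate = "recruitment", term = names(coef(rm_)),
               estimate = as.numeric(coef(rm_)),
               se = sqrt(diag(vcov(rm_)))))
  cis <- NULL
  if (config$bootstrap_iter > 0) {
    ci_s <- bootstrap_ci(sm, n_iter = config$bootstrap_iter,
                         seed = stage_seed(config$seed, 200L))
    ci_r <- bootstrap_ci(rm_, n_iter = config$bootstrap_iter,
                         seed = stage_seed(config$seed, 201L))
    cis <- rbind(cbind(rate = "survival", ci_s),
                 cbind(rate = "recruitment", ci_r))
    coef_tab$ci_lower <- cis$lower
    coef_tab$ci_upper <- cis$upper
  }
  paths$coefficients <- write_table(coef_tab, config$out_dir,
                                    "coefficients.tsv")

  ## viability surface, thresholds, population status
  last <- ranges[ranges$year == max(ranges$year), ]
  pops <- data.frame(population = last$population, D = last$D, P = last$P)
  vs <- viability_surface(sm, rm_, D_grid = config$d_grid,
                          P_grid = config$p_grid, n_sim = config$n_sim,
                          seed = stage_seed(config$seed, 300L),
                          populations = pops)
  paths$surface <- write_table(vs$surface, config$out_dir,
                               "viability_surface.tsv")
  paths$thresholds <- write_table(vs$thresholds, config$out_dir,
                                  "thresholds.tsv")
  paths$classification <- write_table(vs$populations, config$out_dir,
                                      "population_status.csv")

  ## stand succession models (synthetic runs and runs providing pixels)
  succ <- NULL
  if (!is.null(pixels)) {
    structure_fit <- fit_structure_models(pixels)
    decid_fit <- fit_deciduous_model(pixels)
    curves <- predict_stand_curves(structure_fit, decid_fit)
    paths$stand_curves <- write_table(curves, config$out_dir,
                                      "stand_curves.tsv")
    succ <- list(structure = structure_fit, deciduous = decid_fit)
  }

  invisible(list(
    survival_model = sm, recruitment_model = rm_,
    survival_estimates = est, recruitment_observations = obs,
    bootstrap_cis = cis, viability = vs, succession = succ,
    filter_log = filter_log, paths = paths, config = config
  ))
}
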