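## Annual adult-female survival from collar telemetry:
## biological-year splitting and the staggered-entry Kaplan-Meier product.

suppressed <- function(reason) {
  structure(list(reason = reason), class = "suppressed_estimate")
}

#' Biological year of a date
#'
#' The biological year runs 1 April to 31 March and is labelled by the
#' calendar year containing its 1 April start.
#'
#' @param date a `Date` vector.
#' @return integer vector of biological-year labels.
#' @export
bio_year <- function(date) {
  date <- as.Date(date)
  as.integer(format(date, "%Y")) - (as.integer(format(date, "%m")) < 4L)
}

#' Split collar histories at biological-year boundaries
#'
#' A raw telemetry history may span several biological years (1 April - 31
#' March). Each input record is cut at every 1 April it crosses: all
#' segments but the last get fate `"alive_at_year_end"` (the animal
#' survived to 31 March and re-enters on 1 April), and the final segment
#' keeps the recorded fate.
#'
#' @param records data frame with columns `animal_id`, `population`,
#'   `entry_date`, `exit_date`, `fate` (`"dead"` or `"censored"`; already
#'   split inputs with `"alive_at_year_end"` pass through).
#' @return data frame of single-year records with an added integer `year`
#'   column (biological-year label).
#' @export
split_biological_years <- function(records) {
  stopifnot(all(c("animal_id", "population", "entry_date", "exit_date",
                  "fate") %in% names(records)))
  records$entry_date <- as.Date(records$entry_date)
  records$exit_date <- as.Date(records$exit_date)
  bad <- records$exit_date < records$entry_date
  if (any(bad)) {
    stop("malformed collar record(s): exit before entry for animal(s) ",
         paste(unique(records$animal_id[bad]), collapse = ", "))
  }
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    y0 <- bio_year(r$entry_date)
    y1 <- bio_year(r$exit_date)
    yrs <- y0:y1
    data.frame(
      animal_id = r$animal_id, population = r$population,
      year = yrs,
      entry_date = pmax(r$entry_date, april1(yrs)),
      exit_date = pmin(r$exit_date, april1(yrs + 1L) - 1L),
      fate = c(rep("alive_at_year_end", length(yrs) - 1L), r$fate)
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Staggered-entry Kaplan-Meier annual survival for one population-year
#'
#' Computes `S_hat = prod(1 - d_t / n_t)` over the ordered death times of a
#' biological year, where the risk set `n_t` holds every animal that has
#' entered on or before `t` and has not yet died or been censored before
#' `t`. Conventions: tied deaths form one step; a death and a censoring on
#' the same date count the death first; animals enter the risk set at their
#' individual entry dates (staggered entry). Population-years monitored
#' with fewer than `min_animals` distinct females are suppressed, mirroring
#' the at-least-six-individuals monitoring filter.
#'
#' @param records single-year records from [split_biological_years()].
#' @param population,year optional filters; if omitted, `records` must
#'   already contain exactly one population-year.
#' @param min_animals minimum number of distinct collared females for the
#'   estimate to be retained (default 6).
#' @return one-row data frame with columns `population`, `year`, `S_hat`,
#'   `n_females`, `n_deaths`; when filtered, an object of class
#'   `suppressed_estimate` carrying the reason.
#' @export
km_annual_survival <- function(records, population = NULL, year = NULL,
                               min_animals = 6L) {
  if (!is.null(population)) records <- records[records$population == population, ]
  if (!is.null(year)) records <- records[records$year == year, ]
  if (nrow(records) == 0) {
    return(suppressed("no records for this population-year"))
  }
  stopifnot(length(unique(records$population)) == 1L,
            length(unique(records$year)) == 1L)
  n_animals <- length(unique(records$animal_id))
  if (n_animals < min_animals) {
    return(suppressed(sprintf("only %d animal(s) monitored; fewer than %d",
                              n_animals, min_animals)))
  }
  ystart <- april1(records$year[1])
  t_entry <- as.numeric(as.Date(records$entry_date) - ystart)
  t_exit <- as.numeric(as.Date(records$exit_date) - ystart)
  dead <- records$fate == "dead"
  death_times <- sort(unique(t_exit[dead]))
  S <- 1
  for (t in death_times) {
    at_risk <- sum(t_entry <= t & t_exit >= t)
    d_t <- sum(dead & t_exit == t)
    if (at_risk < d_t || at_risk == 0) {
      stop("inconsistent records: empty risk set at a death time (day ", t, ")")
    }
    S <- S * (1 - d_t / at_risk)
  }
  data.frame(population = records$population[1], year = records$year[1],
             S_hat = S, n_females = n_animals, n_deaths = sum(dead))
}

#' Annual survival estimates for all population-years
#'
#' Applies [km_annual_survival()] to every population-year present in the
#' split records, collecting retained estimates and a log of the
#' population-years suppressed by the monitoring filter.
#'
#' @inheritParams km_annual_survival
#' @return data frame of estimates (`population`, `year`, `S_hat`,
#'   `n_females`, `n_deaths`) with a `filtered` attribute: a data frame
#'   (`population`, `year`, `reason`) of suppressed population-years.
#' @export
annual_survival <- function(records, min_animals = 6L) {
  keys <- unique(records[, c("population", "year")])
  keys <- keys[order(keys$population, keys$year), ]
  ests <- list(); filt <- list()
  for (i in seq_len(nrow(keys))) {
    est <- km_annual_survival(records, keys$population[i], keys$year[i],
                              min_animals = min_animals)
    if (inherits(est, "suppressed_estimate")) {
      filt[[length(filt) + 1L]] <- data.frame(
        population = keys$population[i], year = keys$year[i],
        reason = est$reason)
    } else {
      ests[[length(ests) + 1L]] <- est
    }
  }
  out <- if (length(ests)) do.call(rbind, ests) else
    data.frame(population = character(), year = integer(), S_hat = numeric(),
               n_females = integer(), n_deaths = integer())
  rownames(out) <- NULL
  attr(out, "filtered") <- if (length(filt)) do.call(rbind, filt) else
    data.frame(population = character(), year = integer(), reason = character())
  out
}
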