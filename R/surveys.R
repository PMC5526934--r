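## Aerial-survey processing: sex-ratio correction of unclassified adults
## and calf/female recruitment observations with the lagged disturbance.

#' Correct the adult female count for unclassified adults
#'
#' Unclassified adults are apportioned to females using the observed female
#' fraction `F / (F + M)` when fewer than 10% of adults were unclassified;
#' otherwise a 65% female / 35% male split (a 0.54 male-to-female ratio) is
#' assumed. The corrected count is `F + f * U` and is real-valued.
#'
#' @param n_adult_females,n_adult_males,n_adult_unclassified non-negative
#'   adult classification counts (vectorised).
#' @return numeric vector of corrected adult-female counts.
#' @export
correct_sex_ratio <- function(n_adult_females, n_adult_males,
                              n_adult_unclassified) {
  F <- n_adult_females; M <- n_adult_males; U <- n_adult_unclassified
  stopifnot(all(F >= 0), all(M >= 0), all(U >= 0))
  total <- F + M + U
  if (any(total == 0)) {
    stop("undefined sex ratio: all adult counts are zero")
  }
  ## strict "<": exactly 10% unclassified falls back to the 65/35 assumption
  use_observed <- U / total < 0.10
  f <- ifelse(use_observed, ifelse(F + M > 0, F / (F + M), 0.65), 0.65)
  F + f * U
}

#' Recruitment observations from aerial surveys
#'
#' Converts raw classification counts into calf per corrected-adult-female
#' ratios `R`, joined with the total disturbance of the year preceding each
#' survey (late-winter calves reflect the previous year's conditions).
#' Surveys where fewer than `min_individuals` animals (calves plus all
#' adults) were observed are dropped and logged.
#'
#' @param surveys data frame with columns `population`, `year`, `n_calves`,
#'   `n_adult_females`, `n_adult_males`, `n_adult_unclassified`.
#' @param ranges range table with columns `population`, `year`, `P`, `D`.
#' @param min_individuals minimum total animals observed (default 50).
#' @return data frame with columns `population`, `year`, `R`,
#'   `n_females_corrected`, `D_lagged`, `P`, plus a `filtered` attribute
#'   (data frame `population`, `year`, `reason`).
#' @export
recruitment_observations <- function(surveys, ranges, min_individuals = 50L) {
  stopifnot(all(c("population", "year", "n_calves", "n_adult_females",
                  "n_adult_males", "n_adult_unclassified") %in% names(surveys)))
  total <- surveys$n_calves + surveys$n_adult_females + surveys$n_adult_males +
    surveys$n_adult_unclassified
  keep <- total >= min_individuals
  filtered <- if (any(!keep)) {
    data.frame(population = surveys$population[!keep],
               year = surveys$year[!keep],
               reason = sprintf("only %d individuals observed; fewer than %d",
                                total[!keep], min_individuals))
  } else {
    data.frame(population = character(), year = integer(), reason = character())
  }
  s <- surveys[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    out <- data.frame(population = character(), year = integer(), R = numeric(),
                      n_females_corrected = numeric(), D_lagged = numeric(),
                      P = numeric())
    attr(out, "filtered") <- filtered
    return(out)
  }
  fc <- correct_sex_ratio(s$n_adult_females, s$n_adult_males,
                          s$n_adult_unclassified)
  key <- paste(s$population, s$year - 1L)
  idx <- match(key, paste(ranges$population, ranges$year))
  if (anyNA(idx)) {
    miss <- s[is.na(idx), c("population", "year")]
    stop("missing disturbance covariate for the year preceding survey(s): ",
         paste(sprintf("%s/%d", miss$population, miss$year), collapse = ", "))
  }
  out <- data.frame(
    population = s$population, year = s$year,
    R = s$n_calves / fc, n_females_corrected = fc,
    D_lagged = ranges$D[idx], P = ranges$P[idx]
  )
  rownames(out) <- NULL
  attr(out, "filtered") <- filtered
  out
}
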