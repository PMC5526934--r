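## Forest stand succession: cover corrections and the height / canopy /
## deciduous development models against stand age and productivity.

#' Correct canopy cover for the treeless part of a pixel
#'
#' Inventory canopy cover is recorded over the whole 250-m pixel, treeless
#' area included; dividing by the treed fraction gives the cover of the
#' forested stand itself. Values above 1 are capped with a warning.
#' Pixels without trees cannot be corrected and must be removed.
#'
#' @param canopy_cover_raw canopy cover over the whole pixel, in `[0, 1]`.
#' @param treed_fraction fraction of the pixel covered by trees, `> 0`.
#' @return corrected canopy cover in `[0, 1]` (vectorised).
#' @export
correct_canopy_cover <- function(canopy_cover_raw, treed_fraction) {
  if (any(treed_fraction <= 0)) {
    stop("pixel without trees: remove before correcting canopy cover")
  }
  out <- canopy_cover_raw / treed_fraction
  if (any(out > 1)) {
    warning(sum(out > 1), " corrected canopy cover value(s) > 1; capped at 1")
    out <- pmin(out, 1)
  }
  out
}

#' Correct the deciduous fraction for non-vegetated area
#'
#' Same rescaling as [correct_canopy_cover()], dividing the recorded
#' deciduous proportion by the vegetated fraction of the pixel.
#'
#' @param deciduous_raw deciduous proportion over the whole pixel.
#' @param vegetated_fraction vegetated fraction of the pixel, `> 0`.
#' @return corrected deciduous proportion in `[0, 1]` (vectorised).
#' @export
correct_deciduous <- function(deciduous_raw, vegetated_fraction) {
  if (any(vegetated_fraction <= 0)) {
    stop("pixel without vegetation: remove before correcting")
  }
  out <- deciduous_raw / vegetated_fraction
  if (any(out > 1)) {
    warning(sum(out > 1), " corrected deciduous value(s) > 1; capped at 1")
    out <- pmin(out, 1)
  }
  out
}

## apply the stated pixel filters and corrections; returns pixels with
## canopy_cover and deciduous columns plus an n_removed attribute
prepare_pixels <- function(pixels) {
  keep <- pixels$treed_fraction > 0 & pixels$vegetated_fraction > 0
  px <- pixels[keep, , drop = FALSE]
  px$canopy_cover <- correct_canopy_cover(px$canopy_cover_raw,
                                          px$treed_fraction)
  px$deciduous <- correct_deciduous(px$deciduous_raw, px$vegetated_fraction)
  attr(px, "n_removed") <- sum(!keep)
  px
}

#' Fit stand height and canopy-cover development models
#'
#' Ordinary least squares of stand height and corrected canopy cover on
#' age, age squared, productivity `P`, and the age-by-productivity
#' interaction, after removing treeless / unvegetated pixels and applying
#' the cover corrections. The quadratic captures the saturating shape of
#' stand development; the interaction lets productivity change the
#' development rate, not just the level.
#'
#' @param pixels data frame of stand pixels (see
#'   [generate_stand_pixels()] for the schema).
#' @param min_pixels minimum number of usable pixels (default 50).
#' @return object of class `stand_structure_models`: list with `lm` fits
#'   `height` and `cover`, `n_used`, `n_removed`.
#' @export
fit_structure_models <- function(pixels, min_pixels = 50L) {
  px <- prepare_pixels(pixels)
  if (nrow(px) < min_pixels) {
    stop("only ", nrow(px), " usable pixels after filtering; need >= ",
         min_pixels)
  }
  fml <- . ~ age + I(age^2) + P + age:P
  h <- lm(update(fml, height ~ .), data = px)
  cv <- lm(update(fml, canopy_cover ~ .), data = px)
  if (anyNA(coef(h)) || anyNA(coef(cv))) {
    stop("rank-deficient design: age and productivity terms are confounded ",
         "(e.g. all pixels share one age)")
  }
  structure(list(height = h, cover = cv, n_used = nrow(px),
                 n_removed = attr(px, "n_removed")),
            class = "stand_structure_models")
}

#' @export
print.stand_structure_models <- function(x, ...) {
  cat("Stand development models (OLS: age + age^2 + P + age:P)\n")
  cat(sprintf("  %d pixels used, %d removed (no trees / no vegetation)\n",
              x$n_used, x$n_removed))
  cat("  height coefficients:\n")
  print(round(coef(x$height), 4))
  cat("  canopy-cover coefficients:\n")
  print(round(coef(x$cover), 4))
  invisible(x)
}

#' Fit the deciduous-fraction smooth model
#'
#' Penalized cubic regression spline (generalised additive model) of the
#' corrected deciduous fraction on stand age, with a productivity-varying
#' smooth (`s(age, by = P)`) and a productivity main effect, smoothing
#' parameters chosen by generalized cross-validation. Captures the
#' unimodal pulse of deciduous vegetation that follows disturbance.
#'
#' @inheritParams fit_structure_models
#' @param min_pixels minimum number of usable pixels (default 100).
#' @param k basis dimension per smooth (default 10).
#' @return object of class `deciduous_model`: list with the `mgcv::gam`
#'   fit (`gam`), `n_used`, `n_removed`.
#' @export
fit_deciduous_model <- function(pixels, min_pixels = 100L, k = 10) {
  px <- prepare_pixels(pixels)
  if (nrow(px) < min_pixels) {
    stop("only ", nrow(px), " usable pixels after filtering; need >= ",
         min_pixels)
  }
  fit <- mgcv::gam(deciduous ~ s(age, k = k, bs = "cr") +
                     s(age, by = P, k = k, bs = "cr") + P, data = px)
  structure(list(gam = fit, n_used = nrow(px),
                 n_removed = attr(px, "n_removed")),
            class = "deciduous_model")
}

#' @export
print.deciduous_model <- function(x, ...) {
  cat("Deciduous-fraction smooth model (penalized cubic splines, GCV)\n")
  cat(sprintf("  %d pixels used, %d removed\n", x$n_used, x$n_removed))
  print(summary(x$gam)$s.table)
  invisible(x)
}

#' Predicted stand-development curves
#'
#' Evaluates the fitted height, canopy-cover and deciduous models over an
#' age grid for a set of productivity levels, in the long format used by
#' the pipeline's curve output.
#'
#' @param structure a `stand_structure_models` fit.
#' @param deciduous a `deciduous_model` fit.
#' @param ages numeric age grid (years).
#' @param P_levels productivity levels to profile.
#' @return data frame with columns `age`, `P`, `height`, `canopy_cover`,
#'   `deciduous`.
#' @export
predict_stand_curves <- function(structure, deciduous,
                                 ages = seq(0, 120, by = 5),
                                 P_levels = c(0.15, 0.35, 0.55, 0.75)) {
  nd <- expand.grid(age = ages, P = P_levels, KEEP.OUT.ATTRS = FALSE)
  data.frame(
    nd,
    height = as.numeric(predict(structure$height, nd)),
    canopy_cover = as.numeric(predict(structure$cover, nd)),
    deciduous = as.numeric(predict(deciduous$gam, nd))
  )
}
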