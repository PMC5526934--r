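## Finite annual growth rate of the female segment and the disturbance
## thresholds a population can withstand.

#' Convert the calf/female ratio to a female recruitment rate
#'
#' Assuming a 0.5 sex ratio at birth, `R_f = (R/2) / (1 + R/2)`: the
#' fraction of the next year's female population made up of recruited
#' female calves. Strictly increasing in `R` and always in `[0, 1)`.
#'
#' @param R calf per adult-female ratio, `>= 0` (vectorised).
#' @return numeric vector in `[0, 1)`.
#' @export
recruitment_to_female <- function(R) {
  if (any(R < 0)) stop("calf/female ratio R must be non-negative")
  (R / 2) / (1 + R / 2)
}

#' Finite annual rate of change of the female segment
#'
#' `lambda_f = S_f / (1 - R_f)` with `R_f = (R/2) / (1 + R/2)`: adult
#' female survival compounded by the recruitment of female calves.
#' `lambda_f = 1` exactly when `S_f = 1 / (1 + R/2)`.
#'
#' @param S_f annual adult-female survival probability in `(0, 1]`.
#' @param R calf per adult-female ratio, `>= 0`.
#' @return numeric vector of growth rates (vectorised).
#' @export
lambda_f <- function(S_f, R) {
  if (any(S_f <= 0)) stop("survival S_f must be positive")
  if (any(S_f > 1)) stop("survival S_f must not exceed 1")
  S_f / (1 - recruitment_to_female(R))
}

lambda_from_models <- function(survival_model, recruitment_model, D, P) {
  lambda_f(predict(survival_model, D = D, P = P),
           predict(recruitment_model, D = D, P = P))
}

#' Disturbance threshold where the point-estimate growth rate is one
#'
#' Solves `lambda_f(D, P) = 1` in `D` over `[0, 1]` by root bisection
#' (absolute tolerance `1e-6`), using fixed-effects predictions from both
#' vital-rate models. When both disturbance coefficients are negative,
#' `lambda_f` is strictly decreasing in `D` and the root is unique.
#'
#' @param survival_model,recruitment_model `vital_rate_model` objects.
#' @param P productivity proportion (scalar in `[0, 1]`).
#' @param tol absolute tolerance on `D`.
#' @return the threshold `D*` in `[0, 1]`. If `lambda_f < 1` even at
#'   `D = 0` the value is 0 with attribute `flag =
#'   "non-viable even undisturbed"`; if `lambda_f >= 1` across the whole
#'   interval it is 1 with attribute `flag = "viable at full disturbance"`.
#' @export
mean_threshold <- function(survival_model, recruitment_model, P, tol = 1e-6) {
  stopifnot(length(P) == 1, P >= 0, P <= 1)
  f <- function(D) lambda_from_models(survival_model, recruitment_model, D, P) - 1
  if (f(0) <= 0) return(structure(0, flag = "non-viable even undisturbed"))
  if (f(1) >= 0) return(structure(1, flag = "viable at full disturbance"))
  uniroot(f, c(0, 1), tol = tol)$root
}

## Vectorised per-draw thresholds: bs, br are n x 3 matrices of survival /
## recruitment coefficients. Monotone draws (both disturbance coefficients
## negative) are solved by bisection; the rest by a cumulative grid scan
## (threshold = largest D below which lambda_f >= 1 everywhere).
draw_thresholds <- function(bs, br, P, iters = 26, grid_step = 1e-3) {
  n <- nrow(bs)
  lam <- function(idx, D) {
    S <- plogis(bs[idx, 1] + bs[idx, 2] * D + bs[idx, 3] * P)
    R <- plogis(br[idx, 1] + br[idx, 2] * D + br[idx, 3] * P^2)
    S / (1 - (R / 2) / (1 + R / 2))
  }
  out <- numeric(n)
  mono <- bs[, 2] < 0 & br[, 2] < 0
  idx <- which(mono)
  if (length(idx)) {
    f0 <- lam(idx, 0); f1 <- lam(idx, 1)
    out[idx[f0 <= 1]] <- 0
    out[idx[f1 >= 1]] <- 1
    mid <- idx[f0 > 1 & f1 < 1]
    if (length(mid)) {
      lo <- rep(0, length(mid)); hi <- rep(1, length(mid))
      for (i in seq_len(iters)) {
        m <- (lo + hi) / 2
        up <- lam(mid, m) >= 1
        lo[up] <- m[up]; hi[!up] <- m[!up]
      }
      out[mid] <- (lo + hi) / 2
    }
  }
  rest <- which(!mono)
  if (length(rest)) {
    Dg <- seq(0, 1, by = grid_step)
    for (i in rest) {
      ok <- cumprod(lam(i, Dg) >= 1) == 1  # viable on [0, D] throughout
      out[i] <- if (ok[1]) Dg[max(which(ok))] else 0
    }
  }
  out
}

#' Disturbance limit with 95% confidence of at least a stable population
#'
#' Propagates coefficient uncertainty: draws `n_sim` coefficient vectors
#' for each vital-rate model from its multivariate normal sampling
#' distribution (`Normal(beta, vcov)`, the two models independent), solves
#' each draw's `lambda_f = 1` boundary in `D`, and returns the 5th
#' percentile of the per-draw thresholds - equivalently the largest
#' disturbance at which at least 95% of draws still give `lambda_f >= 1`.
#'
#' @inheritParams mean_threshold
#' @param n_sim number of coefficient draws (default 10,000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param details if `TRUE`, attach the draw matrices and per-draw
#'   thresholds as attributes `draws_survival`, `draws_recruitment`,
#'   `thresholds`.
#' @return the confidence threshold `D*_95` in `[0, 1]`.
#' @export
confident_threshold <- function(survival_model, recruitment_model, P,
                                n_sim = 10000, seed = NULL, level = 0.95,
                                details = FALSE) {
  stopifnot(length(P) == 1, P >= 0, P <= 1, n_sim >= 100)
  if (is.null(survival_model$vcov) || is.null(recruitment_model$vcov)) {
    stop("uncertainty unavailable: both models must carry a coefficient ",
         "covariance matrix")
  }
  if (!is.null(seed)) set.seed(seed)
  bs <- MASS::mvrnorm(n_sim, coef(survival_model), vcov(survival_model))
  br <- MASS::mvrnorm(n_sim, coef(recruitment_model), vcov(recruitment_model))
  th <- draw_thresholds(bs, br, P)
  out <- as.numeric(quantile(th, probs = 1 - level, type = 1))
  if (details) {
    attr(out, "draws_survival") <- bs
    attr(out, "draws_recruitment") <- br
    attr(out, "thresholds") <- th
  }
  out
}

#' Viability surface over disturbance and productivity
#'
#' Evaluates the fixed-effects vital rates and `lambda_f` over a `(D, P)`
#' grid, solves both threshold curves (point-estimate boundary
#' `D*_mean(P)` and the 95%-confidence lower limit `D*_95(P)`), and
#' classifies supplied populations as increasing (`lambda_f > 1`, below
#' the boundary), declining, or stable.
#'
#' @inheritParams confident_threshold
#' @param D_grid,P_grid grids of proportions in `[0, 1]`.
#' @param populations optional data frame with columns `population`, `D`,
#'   `P` to classify against the surface.
#' @param class_tol half-width of the "stable" band on the `lambda_f`
#'   scale.
#' @return an object of class `viability_surface`: list with `surface`
#'   (data frame `D`, `P`, `S_f`, `R`, `R_f`, `lambda_f`), `thresholds`
#'   (data frame `P`, `D_star_mean`, `D_star_95`), `populations`
#'   (classification or `NULL`), `n_sim`, `seed`.
#' @export
viability_surface <- function(survival_model, recruitment_model,
                              D_grid = seq(0, 1, by = 0.01),
                              P_grid = seq(0, 1, by = 0.01),
                              n_sim = 10000, seed = NULL,
                              populations = NULL, class_tol = 1e-6) {
  if (length(D_grid) == 0 || length(P_grid) == 0) {
    stop("D_grid and P_grid must be non-empty")
  }
  stopifnot(all(D_grid >= 0 & D_grid <= 1), all(P_grid >= 0 & P_grid <= 1))
  g <- expand.grid(D = D_grid, P = P_grid, KEEP.OUT.ATTRS = FALSE)
  g$S_f <- predict(survival_model, D = g$D, P = g$P)
  g$R <- predict(recruitment_model, D = g$D, P = g$P)
  g$R_f <- recruitment_to_female(g$R)
  g$lambda_f <- g$S_f / (1 - g$R_f)
  d_mean <- vapply(P_grid, function(p)
    as.numeric(mean_threshold(survival_model, recruitment_model, p)), 0)
  d_95 <- if (!is.null(survival_model$vcov) &&
              !is.null(recruitment_model$vcov)) {
    if (!is.null(seed)) set.seed(seed)
    bs <- MASS::mvrnorm(n_sim, coef(survival_model), vcov(survival_model))
    br <- MASS::mvrnorm(n_sim, coef(recruitment_model),
                        vcov(recruitment_model))
    vapply(P_grid, function(p)
      as.numeric(quantile(draw_thresholds(bs, br, p), probs = 0.05, type = 1)),
      0)
  } else {
    rep(NA_real_, length(P_grid))
  }
  thr <- data.frame(P = P_grid, D_star_mean = d_mean, D_star_95 = d_95)
  cls <- NULL
  if (!is.null(populations)) {
    stopifnot(all(c("population", "D", "P") %in% names(populations)))
    lam <- lambda_from_models(survival_model, recruitment_model,
                              populations$D, populations$P)
    cls <- data.frame(
      population = populations$population, D = populations$D,
      P = populations$P, lambda_f = lam,
      status = ifelse(lam > 1 + class_tol, "increasing",
                      ifelse(lam < 1 - class_tol, "declining", "stable")))
  }
  structure(list(surface = g, thresholds = thr, populations = cls,
                 n_sim = n_sim, seed = seed),
            class = "viability_surface")
}

#' @export
print.viability_surface <- function(x, ...) {
  cat(sprintf("Viability surface: %d (D, P) cells, %d productivity levels\n",
              nrow(x$surface), nrow(x$thresholds)))
  ok <- is.finite(x$thresholds$D_star_mean)
  cat(sprintf("  D*_mean range: %.3f - %.3f\n",
              min(x$thresholds$D_star_mean[ok]),
              max(x$thresholds$D_star_mean[ok])))
  if (any(is.finite(x$thresholds$D_star_95))) {
    cat(sprintf("  D*_95   range: %.3f - %.3f  (n_sim = %d)\n",
                min(x$thresholds$D_star_95, na.rm = TRUE),
                max(x$thresholds$D_star_95, na.rm = TRUE), x$n_sim))
  }
  if (!is.null(x$populations)) {
    cat("  populations:",
        paste(sprintf("%s (%s)", x$populations$population,
                      x$populations$status), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot the viability threshold curves
#'
#' Draws the point-estimate `lambda_f = 1` boundary and, when available,
#' the 95%-confidence lower disturbance limit against productivity;
#' populations (if classified) are overlaid as points. Populations below
#' the solid boundary tend to increase, above it to decline.
#'
#' @param x a `viability_surface`.
#' @param ... passed to [plot()].
#' @export
plot.viability_surface <- function(x, ...) {
  thr <- x$thresholds
  plot(thr$P, thr$D_star_mean, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "Proportion of potentially productive stands (P)",
       ylab = "Total disturbance (D)", ...)
  if (any(is.finite(thr$D_star_95))) {
    graphics::lines(thr$P, thr$D_star_95, lty = 2)
  }
  if (!is.null(x$populations)) {
    graphics::points(x$populations$P, x$populations$D, pch = 19,
                     col = ifelse(x$populations$status == "increasing",
                                  "forestgreen",
                                  ifelse(x$populations$status == "declining",
                                         "firebrick", "orange")))
  }
  graphics::legend("topleft", bty = "n", lty = c(1, 2), lwd = c(2, 1),
                   legend = c(expression(lambda[f] == 1),
                              "95% confidence limit"))
  invisible(x)
}
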