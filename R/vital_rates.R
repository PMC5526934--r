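## Weighted binomial mixed models for the two vital rates (logit link,
## population random intercept), their S3 class, and the parametric
## bootstrap for coefficient confidence intervals.

rate_terms <- function(rate) {
  switch(rate,
         survival = c("(Intercept)", "D", "P"),
         recruitment = c("(Intercept)", "D", "P2"),
         stop("unknown rate: ", rate))
}

#' Construct a vital-rate model from known coefficients
#'
#' Builds a `vital_rate_model` directly from logit-scale coefficients, for
#' example the published mixed-model estimates, so predictions and
#' viability thresholds can be computed without refitting. The linear
#' predictor is `b0 + bD * D + bP * P` for survival and
#' `b0 + bD * D + bP2 * P^2` for recruitment.
#'
#' @param rate `"survival"` or `"recruitment"`.
#' @param beta length-3 numeric: intercept, disturbance coefficient, and
#'   productivity (survival) or productivity-squared (recruitment)
#'   coefficient, on the logit scale.
#' @param vcov optional 3x3 covariance matrix of `beta`; required for
#'   confidence-based viability thresholds.
#' @param se optional length-3 standard errors, used as `diag(se^2)` when
#'   no full covariance is available (coefficients treated as independent).
#' @param sigma_pop random-intercept standard deviation (default 0).
#' @return an object of class `vital_rate_model`.
#' @examples
#' m <- vital_rate_model("recruitment", beta = c(-0.15, -5.05, 2.41))
#' predict_rate(m, D = 0.35, P = 0.21)
#' @export
vital_rate_model <- function(rate = c("survival", "recruitment"), beta,
                             vcov = NULL, se = NULL, sigma_pop = 0) {
  rate <- match.arg(rate)
  stopifnot(length(beta) == 3, all(is.finite(beta)), sigma_pop >= 0)
  if (is.null(vcov) && !is.null(se)) {
    stopifnot(length(se) == 3, all(se >= 0))
    vcov <- diag(se^2)
  }
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    stopifnot(nrow(vcov) == 3, ncol(vcov) == 3,
              isTRUE(all.equal(vcov, t(vcov), tolerance = 1e-8)),
              all(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
    dimnames(vcov) <- list(rate_terms(rate), rate_terms(rate))
  }
  structure(list(rate = rate, beta = setNames(as.numeric(beta), rate_terms(rate)),
                 vcov = vcov, sigma_pop = sigma_pop, link = "logit",
                 n_obs = NA_integer_, weights_used = NA, backend = "fixed",
                 fit = NULL, data = NULL),
            class = "vital_rate_model")
}

## shared fitting core for both vital rates.
## y: proportion response; w: prior weights; covariate column given by rate.
fit_vital_rate <- function(d, rate, random = TRUE, nAGQ = 7) {
  xname <- rate_terms(rate)[3]
  stopifnot(all(c("y", "w", "D", xname, "population") %in% names(d)))
  if (nrow(d) < 6) stop("too few observations (", nrow(d), ") to fit; need >= 6")
  if (all(d$y * d$w == 0) || all((1 - d$y) * d$w == 0)) {
    stop("complete separation: response is constant at the boundary (all ",
         if (all(d$y == 0)) "zero" else "one", "); coefficients diverge")
  }
  X <- model.matrix(as.formula(paste("~ D +", xname)), d)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: disturbance and productivity covariates ",
         "are confounded")
  }
  n_pop <- length(unique(d$population))
  if (random && n_pop < 2) {
    warning("single population: random intercept unidentifiable; ",
            "sigma_pop pinned to 0 (plain weighted GLM)")
    random <- FALSE
  }
  if (random) {
    fml <- as.formula(paste("y ~ D +", xname, "+ (1 | population)"))
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = d, family = binomial(), weights = w,
                  nAGQ = nAGQ),
      warning = function(wrn) {
        if (grepl("non-integer", conditionMessage(wrn)))
          invokeRestart("muffleWarning")
      })
    if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
      stop("mixed-model fit failed to converge (optimizer code ",
           fit@optinfo$conv$opt, "): ",
           paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
    }
    beta <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    sigma <- sqrt(as.numeric(lme4::VarCorr(fit)$population[1]))
  } else {
    fml <- as.formula(paste("y ~ D +", xname))
    fit <- withCallingHandlers(
      glm(fml, data = d, family = binomial(), weights = w),
      warning = function(wrn) {
        if (grepl("non-integer", conditionMessage(wrn)))
          invokeRestart("muffleWarning")
      })
    if (!fit$converged) stop("weighted GLM fit failed to converge")
    beta <- coef(fit)
    vc <- vcov(fit)
    sigma <- 0
  }
  if (anyNA(beta) || anyNA(vc)) {
    stop("fit produced undefined coefficients or covariance; ",
         "check the design for confounding")
  }
  names(beta) <- rate_terms(rate)
  dimnames(vc) <- list(rate_terms(rate), rate_terms(rate))
  structure(list(rate = rate, beta = beta, vcov = vc, sigma_pop = sigma,
                 link = "logit", n_obs = nrow(d), weights_used = TRUE,
                 backend = if (random) "glmer" else "glm", fit = fit,
                 data = d),
            class = "vital_rate_model")
}

#' Fit the weighted binomial mixed model for adult-female survival
#'
#' Annual Kaplan-Meier survival estimates are regressed on the range's
#' total disturbance `D` (year-specific) and productivity `P`
#' (population-specific) with a logit link and a population random
#' intercept, each observation weighted by the number of monitored females
#' (the weight carries the precision of the annual estimate; the response
#' is a Kaplan-Meier proportion, so the binomial likelihood is evaluated
#' with fractional successes).
#'
#' @param estimates output of [annual_survival()].
#' @param ranges range table (`population`, `year`, `P`, `D`).
#' @param random fit the population random intercept (default `TRUE`); with
#'   `FALSE` the model collapses to a plain weighted logistic regression.
#' @param nAGQ number of adaptive Gauss-Hermite quadrature nodes for the
#'   random-intercept integral (default 7; 1 = Laplace approximation).
#' @return a [vital_rate_model()] with `rate = "survival"`.
#' @export
fit_survival_model <- function(estimates, ranges, random = TRUE, nAGQ = 7) {
  d <- merge(estimates, ranges[, c("population", "year", "P", "D")],
             by = c("population", "year"))
  if (nrow(d) < nrow(estimates)) {
    stop("missing range covariates for ", nrow(estimates) - nrow(d),
         " survival estimate(s)")
  }
  dd <- data.frame(y = d$S_hat, w = d$n_females, D = d$D, P = d$P,
                   population = factor(d$population))
  fit_vital_rate(dd, "survival", random = random, nAGQ = nAGQ)
}

#' Fit the weighted binomial mixed model for recruitment
#'
#' Calf/female ratios are regressed on the previous year's total
#' disturbance and on squared productivity (the square linearises the
#' productivity-recruitment relationship on the logit scale), with a
#' population random intercept, each observation weighted by the corrected
#' number of adult females.
#'
#' @param observations output of [recruitment_observations()].
#' @inheritParams fit_survival_model
#' @return a [vital_rate_model()] with `rate = "recruitment"`.
#' @export
fit_recruitment_model <- function(observations, ranges = NULL, random = TRUE,
                                  nAGQ = 7) {
  obs <- observations
  if (!all(c("D_lagged", "P") %in% names(obs))) {
    stop("observations must carry D_lagged and P ",
         "(see recruitment_observations())")
  }
  dd <- data.frame(y = obs$R, w = obs$n_females_corrected, D = obs$D_lagged,
                   P2 = obs$P^2, population = factor(obs$population))
  if (any(dd$y > 1)) {
    stop("calf/female ratio exceeds 1; the binomial model requires R <= 1")
  }
  fit_vital_rate(dd, "recruitment", random = random, nAGQ = nAGQ)
}

#' @export
print.vital_rate_model <- function(x, ...) {
  cat(sprintf("Vital-rate model: %s (logit link, %s)\n", x$rate,
              switch(x$backend,
                     glmer = "population random intercept",
                     glm = "no random intercept",
                     fixed = "fixed coefficients")))
  print(round(x$beta, 4))
  cat(sprintf("sigma_pop = %.4f", x$sigma_pop))
  if (!is.na(x$n_obs)) cat(sprintf("; n_obs = %d", x$n_obs))
  cat("\n")
  invisible(x)
}

#' @export
summary.vital_rate_model <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else rep(NA_real_, 3)
  z <- object$beta / se
  tab <- data.frame(Estimate = object$beta, `Std. Error` = se,
                    `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)),
                    check.names = FALSE)
  structure(list(rate = object$rate, coefficients = tab,
                 sigma_pop = object$sigma_pop, n_obs = object$n_obs,
                 backend = object$backend),
            class = "summary.vital_rate_model")
}

#' @export
print.summary.vital_rate_model <- function(x, ...) {
  cat(sprintf("Weighted binomial %s model for %s (logit link)\n",
              if (x$backend == "glmer") "mixed" else "fixed-effects", x$rate))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("Random intercept SD (population): %.4f\n", x$sigma_pop))
  if (!is.na(x$n_obs)) cat(sprintf("Observations: %d\n", x$n_obs))
  invisible(x)
}

#' @export
coef.vital_rate_model <- function(object, ...) object$beta

#' @export
vcov.vital_rate_model <- function(object, ...) object$vcov

#' Predict a vital rate from fixed effects
#'
#' Inverse-logit of the fixed-effects linear predictor (population random
#' intercepts set to zero): `plogis(b0 + bD*D + bP*P)` for survival and
#' `plogis(b0 + bD*D + bP2*P^2)` for recruitment. For recruitment the
#' returned value is the expected calf/female ratio.
#'
#' @param object a `vital_rate_model`.
#' @param D,P disturbance and productivity proportions in `[0, 1]`
#'   (vectorised; recycled against each other).
#' @param type `"response"` (probability/ratio scale, default) or
#'   `"link"` (logit scale).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.vital_rate_model <- function(object, D, P, type = c("response", "link"),
                                     ...) {
  type <- match.arg(type)
  stopifnot(all(D >= 0 & D <= 1), all(P >= 0 & P <= 1))
  x3 <- if (object$rate == "recruitment") P^2 else P
  eta <- object$beta[1] + object$beta[2] * D + object$beta[3] * x3
  unname(if (type == "response") plogis(eta) else eta)
}

#' @rdname predict.vital_rate_model
#' @param model a `vital_rate_model` (alias of `predict(model, D, P)`).
#' @export
predict_rate <- function(model, D, P) predict(model, D = D, P = P)

#' Simulate responses from a fitted vital-rate model
#'
#' Parametric simulation at the fitted coefficients: a fresh population
#' random intercept is drawn per replicate (mixed backend), and each
#' observation's response is a binomial proportion with the observation's
#' rounded weight as the number of trials, so fractional weights (corrected
#' female counts, Kaplan-Meier weights) are handled.
#'
#' @param object a fitted `vital_rate_model` (`backend` `"glmer"` or
#'   `"glm"`).
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame of simulated response vectors (proportion scale).
#' @export
simulate.vital_rate_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$backend == "fixed") {
    stop("cannot simulate from a coefficient-only model: no data attached")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  xname <- rate_terms(object$rate)[3]
  eta_fix <- object$beta[1] + object$beta[2] * d$D + object$beta[3] * d[[xname]]
  pops <- factor(d$population)
  wr <- pmax(1L, round(d$w))
  sims <- vapply(seq_len(nsim), function(j) {
    u <- if (object$sigma_pop > 0) {
      rnorm(nlevels(pops), 0, object$sigma_pop)
    } else {
      numeric(nlevels(pops))
    }
    p <- plogis(eta_fix + u[as.integer(pops)])
    rbinom(length(p), wr, p) / wr
  }, numeric(nrow(d)))
  sims <- as.data.frame(sims, optional = TRUE)
  names(sims) <- paste0("sim_", seq_len(nsim))
  sims
}

#' @export
residuals.vital_rate_model <- function(object, type = "pearson", ...) {
  if (object$backend == "fixed") {
    stop("no residuals for a coefficient-only model")
  }
  residuals(object$fit, type = type)
}

## refit coefficient vector on a simulated response; NA on failure
refit_beta <- function(object, y) {
  p <- length(object$beta)
  tryCatch({
    if (object$backend == "glmer") {
      f <- suppressMessages(suppressWarnings(lme4::refit(object$fit, y)))
      as.numeric(lme4::fixef(f))
    } else {
      X <- model.matrix(object$fit)
      f <- suppressWarnings(
        glm.fit(X, y, weights = object$data$w, family = binomial()))
      if (!f$converged) rep(NA_real_, p) else as.numeric(f$coefficients)
    }
  }, error = function(e) rep(NA_real_, p))
}

#' Parametric-bootstrap confidence intervals for the coefficients
#'
#' Simulates `n_iter` response vectors from the fitted model (drawing new
#' population random intercepts each time for the mixed backend), refits
#' the model to each, and returns percentile intervals of the collected
#' fixed effects. Percentiles use the inverse-ECDF definition, so with two
#' draws the interval is their range.
#'
#' @param model a fitted `vital_rate_model`.
#' @param n_iter number of bootstrap iterations (published analyses use
#'   10,000; reduce for quick checks).
#' @param seed integer seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `name`, `lower`, `upper`, `level`;
#'   attribute `draws` holds the `n_iter x 3` matrix of refitted
#'   coefficients (failed refits as `NA` rows).
#' @export
bootstrap_ci <- function(model, n_iter = 1000, seed = NULL, level = 0.95) {
  stopifnot(inherits(model, "vital_rate_model"), n_iter >= 2)
  if (model$backend == "fixed") {
    stop("bootstrap requires a model fitted to data")
  }
  sims <- simulate(model, nsim = n_iter, seed = seed)
  draws <- t(vapply(sims, function(y) refit_beta(model, y),
                    numeric(length(model$beta))))
  colnames(draws) <- names(model$beta)
  n_fail <- sum(!complete.cases(draws))
  if (n_fail > 0.10 * n_iter) {
    stop("parametric bootstrap unstable: ", n_fail, " of ", n_iter,
         " refits failed")
  }
  a <- (1 - level) / 2
  ci <- apply(draws, 2, quantile, probs = c(a, 1 - a), type = 1, na.rm = TRUE)
  out <- data.frame(name = colnames(draws), lower = ci[1, ], upper = ci[2, ],
                    level = level, row.names = NULL)
  attr(out, "draws") <- draws
  out
}

#' @export
confint.vital_rate_model <- function(object, parm, level = 0.95, n_iter = 1000,
                                     seed = NULL, ...) {
  ci <- bootstrap_ci(object, n_iter = n_iter, seed = seed, level = level)
  m <- as.matrix(ci[, c("lower", "upper")])
  rownames(m) <- ci$name
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}
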