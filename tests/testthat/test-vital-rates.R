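# random small survival-style dataset with no population heterogeneity
sigma0_dataset <- function(n = 30, n_pop = 6) {
  P <- runif(n_pop, 0.1, 0.9)
  pop <- rep(seq_len(n_pop), length.out = n)
  d <- data.frame(population = sprintf("p%d", pop),
                  year = 2000 + seq_len(n) %% 5,
                  D = runif(n, 0.2, 0.8), P = P[pop])
  d$w <- sample(8:20, n, replace = TRUE)
  p <- plogis(1.5 - 1 * d$D + 1 * d$P)
  d$y <- rbinom(n, d$w, p) / d$w
  d
}

test_that("mixed fits that pin sigma_pop to zero equal the weighted-GLM
           oracle to four decimals", {
  set.seed(88)
  n_singular <- 0
  for (i in 1:50) {
    d <- sigma0_dataset()
    est <- data.frame(population = d$population, year = d$year, S_hat = d$y,
                      n_females = d$w, n_deaths = 0)
    rg <- data.frame(population = d$population, year = d$year, P = d$P, D = d$D)
    fm <- suppressMessages(suppressWarnings(fit_survival_model(est, rg)))
    if (fm$sigma_pop < 1e-6) {
      n_singular <- n_singular + 1
      oracle <- glm_oracle(d$y, d$w, d$D, d$P)
      expect_equal(coef(fm), oracle, tolerance = 1e-4)
    }
  }
  # the truth has no population effect, so most fits must hit the boundary
  expect_gt(n_singular, 25)
})

test_that("doubling all weights leaves point estimates unchanged", {
  # exact invariance of the weighted likelihood (fixed-effects model);
  # weights scale information only, so standard errors shrink
  set.seed(89)
  d <- sigma0_dataset(n = 36)
  est <- data.frame(population = d$population, year = d$year, S_hat = d$y,
                    n_females = d$w, n_deaths = 0)
  rg <- data.frame(population = d$population, year = d$year, P = d$P, D = d$D)
  f1 <- suppressWarnings(fit_survival_model(est, rg, random = FALSE))
  est2 <- transform(est, n_females = n_females * 2)
  f2 <- suppressWarnings(fit_survival_model(est2, rg, random = FALSE))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_true(all(diag(vcov(f2)) < diag(vcov(f1))))
  # in the mixed model the invariance holds whenever sigma_pop sits at the
  # boundary (the conditional likelihood is then the whole likelihood)
  g1 <- suppressMessages(suppressWarnings(fit_survival_model(est, rg)))
  g2 <- suppressMessages(suppressWarnings(fit_survival_model(est2, rg)))
  if (g1$sigma_pop < 1e-6 && g2$sigma_pop < 1e-6) {
    expect_equal(coef(g1), coef(g2), tolerance = 1e-4)
  }
})

test_that("fixed-effects predictions reproduce the published worked values", {
  rec <- table1_recruitment()
  expect_equal(round(predict_rate(rec, 0.35, 0.21), 2), 0.14)
  expect_equal(predict_rate(rec, 0.35, 0.85), 0.456, tolerance = 0.002)
  # logit identity at a null linear predictor
  null_m <- vital_rate_model("survival", beta = c(0, 0, 0))
  expect_equal(predict_rate(null_m, 0.3, 0.7), 0.5)
  # link-scale predictions invert through plogis
  expect_equal(plogis(predict(rec, D = 0.5, P = 0.5, type = "link")),
               predict(rec, D = 0.5, P = 0.5))
})

test_that("predictions are monotone in D and P at the published signs", {
  D <- seq(0, 1, by = 0.05)
  for (m in list(table1_survival(), table1_recruitment())) {
    s_d <- predict(m, D = D, P = 0.5)
    expect_true(all(diff(s_d) < 0))
    s_p <- predict(m, D = 0.4, P = D)
    expect_true(all(diff(s_p[-1]) > 0))   # strictly increasing on (0, 1]
  }
})

test_that("degenerate designs raise the documented errors", {
  obs <- data.frame(population = rep(c("a", "b"), each = 5), year = 1:5,
                    R = 0, n_females_corrected = 100,
                    D_lagged = runif(10, 0.2, 0.8), P = runif(10, 0.1, 0.9))
  expect_error(fit_recruitment_model(obs), "separation")
  # a single population has constant P: confounded with the intercept
  set.seed(90)
  d <- sigma0_dataset(n = 20, n_pop = 1)
  est <- data.frame(population = d$population, year = seq_len(20),
                    S_hat = d$y, n_females = d$w, n_deaths = 0)
  rg <- data.frame(population = d$population, year = est$year, P = d$P, D = d$D)
  expect_error(fit_survival_model(est, rg), "rank-deficient")
  # with a varying covariate, a lone population still cannot identify the
  # random intercept: warning, sigma_pop pinned to zero, plain GLM used
  obs1 <- data.frame(population = "solo", year = 1:20,
                     R = plogis(-0.5 - 2 * runif(20)),
                     n_females_corrected = 100,
                     D_lagged = runif(20, 0.2, 0.8), P = runif(20, 0.1, 0.9))
  expect_warning(fm <- fit_recruitment_model(obs1), "single population")
  expect_equal(fm$sigma_pop, 0)
  expect_equal(fm$backend, "glm")
})

test_that("bootstrap percentile intervals follow the inverse-ECDF edge case", {
  set.seed(91)
  d <- sigma0_dataset(n = 24)
  est <- data.frame(population = d$population, year = d$year, S_hat = d$y,
                    n_females = d$w, n_deaths = 0)
  rg <- data.frame(population = d$population, year = d$year, P = d$P, D = d$D)
  fm <- suppressMessages(suppressWarnings(fit_survival_model(est, rg)))
  ci <- suppressMessages(bootstrap_ci(fm, n_iter = 2, seed = 1))
  draws <- attr(ci, "draws")
  expect_equal(ci$lower, apply(draws, 2, min), ignore_attr = TRUE)
  expect_equal(ci$upper, apply(draws, 2, max), ignore_attr = TRUE)
  expect_true(all(ci$lower <= ci$upper))
  # confint method exposes the same machinery
  cm <- suppressMessages(confint(fm, level = 0.9, n_iter = 20, seed = 2))
  expect_equal(rownames(cm), names(coef(fm)))
  expect_true(all(cm[, 1] <= cm[, 2]))
})

test_that("interval width collapses as information grows", {
  set.seed(92)
  n <- 150
  d <- data.frame(D = runif(n, 0.2, 0.8), P = runif(n, 0.1, 0.9))
  w <- rep(5000, n)
  y <- rbinom(n, w, plogis(1.5 - 1 * d$D + 1 * d$P)) / w
  obs <- data.frame(population = rep(sprintf("p%d", 1:6), length.out = n),
                    year = seq_len(n), R = y, n_females_corrected = w,
                    D_lagged = d$D, P = sqrt(d$P))
  fm <- suppressMessages(suppressWarnings(
    fit_recruitment_model(obs, random = FALSE)))
  ci <- bootstrap_ci(fm, n_iter = 60, seed = 3)
  expect_true(all(ci$upper - ci$lower < 0.15))
})
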