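test_that("female recruitment conversion and lambda_f obey the algebra", {
  expect_equal(recruitment_to_female(0), 0)
  expect_equal(recruitment_to_female(2), 0.5)
  expect_equal(recruitment_to_female(0.45), 0.225 / 1.225)
  expect_error(recruitment_to_female(-0.1), "non-negative")
  R <- seq(0, 10, by = 0.1)
  rf <- recruitment_to_female(R)
  expect_true(all(rf >= 0 & rf < 1))
  expect_true(all(diff(rf) > 0))
  expect_equal(lambda_f(1, 0), 1)
  expect_equal(lambda_f(0.9, 2), 1.8)
  # lambda_f = 1 exactly on the S_f = 1/(1 + R/2) boundary
  for (r in c(0.1, 0.45, 1, 3)) {
    expect_equal(lambda_f(1 / (1 + r / 2), r), 1)
  }
  expect_error(lambda_f(0, 0.5), "positive")
  expect_error(lambda_f(1.2, 0.5), "exceed")
})

test_that("mean threshold agrees with a fine grid-scan oracle", {
  sm <- table1_survival(); rec <- table1_recruitment()
  for (P in c(0.21, 0.5, 0.85)) {
    D_star <- mean_threshold(sm, rec, P)
    Dg <- seq(0, 1, by = 1e-4)
    lam <- lambda_f(predict(sm, D = Dg, P = P), predict(rec, D = Dg, P = P))
    oracle <- if (lam[1] < 1) 0 else Dg[max(which(lam >= 1))]
    expect_lt(abs(as.numeric(D_star) - oracle), 2e-4)
  }
  # thresholds rise with productivity under the published signs
  expect_gt(mean_threshold(sm, rec, 0.8), mean_threshold(sm, rec, 0.2))
  d_seq <- vapply(seq(0.1, 0.9, by = 0.1),
                  function(p) as.numeric(mean_threshold(sm, rec, p)), 0)
  expect_true(all(diff(d_seq) > 0))
  # survival forced to 1 with positive recruitment: viable everywhere
  s_one <- vital_rate_model("survival", beta = c(50, 0, 0))
  full <- mean_threshold(s_one, rec, 0.5)
  expect_equal(as.numeric(full), 1)
  expect_equal(attr(full, "flag"), "viable at full disturbance")
  # recruitment and survival driven down: not viable even undisturbed
  s_low <- vital_rate_model("survival", beta = c(-1, -1, 0))
  none <- mean_threshold(s_low, rec, 0.5)
  expect_equal(as.numeric(none), 0)
  expect_match(attr(none, "flag"), "non-viable")
})

test_that("confidence threshold degenerates to the mean threshold and never
           exceeds it", {
  sm <- table1_survival(); rec <- table1_recruitment()
  sm0 <- table1_survival(); sm0$vcov <- matrix(0, 3, 3)
  rec0 <- table1_recruitment(); rec0$vcov <- matrix(0, 3, 3)
  for (P in c(0.3, 0.7)) {
    expect_equal(confident_threshold(sm0, rec0, P, n_sim = 200, seed = 1),
                 as.numeric(mean_threshold(sm0, rec0, P)), tolerance = 1e-6)
  }
  smv <- table1_survival(TRUE); recv <- table1_recruitment(TRUE)
  for (P in c(0.2, 0.5, 0.85)) {
    for (seed in 1:3) {
      d95 <- confident_threshold(smv, recv, P, n_sim = 400, seed = seed)
      expect_lte(d95, as.numeric(mean_threshold(smv, recv, P)))
      expect_true(d95 >= 0 && d95 <= 1)
    }
  }
  no_vcov <- table1_survival()
  expect_error(confident_threshold(no_vcov, recv, 0.5, n_sim = 200),
               "uncertainty unavailable")
})

test_that("per-draw thresholds match the pooled >=95%-of-draws definition", {
  smv <- table1_survival(TRUE); recv <- table1_recruitment(TRUE)
  P <- 0.6
  d95 <- confident_threshold(smv, recv, P, n_sim = 600, seed = 9,
                             details = TRUE)
  bs <- attr(d95, "draws_survival"); br <- attr(d95, "draws_recruitment")
  Dg <- seq(0, 1, by = 1e-3)
  frac_viable <- vapply(Dg, function(D) {
    S <- plogis(bs[, 1] + bs[, 2] * D + bs[, 3] * P)
    R <- plogis(br[, 1] + br[, 2] * D + br[, 3] * P^2)
    mean(S / (1 - (R / 2) / (1 + R / 2)) >= 1)
  }, 0)
  oracle <- if (frac_viable[1] < 0.95) 0 else Dg[max(which(frac_viable >= 0.95))]
  expect_lt(abs(as.numeric(d95) - oracle), 2e-3)
})

test_that("confidence threshold is stable across seeds at full simulation
           size", {
  smv <- table1_survival(TRUE); recv <- table1_recruitment(TRUE)
  a <- confident_threshold(smv, recv, 0.6, n_sim = 10000, seed = 1)
  b <- confident_threshold(smv, recv, 0.6, n_sim = 10000, seed = 2)
  expect_lt(abs(a - b), 0.01)
  # Monte-Carlo spread shrinks with n_sim
  spread <- function(n_sim) {
    th <- vapply(1:8, function(s)
      confident_threshold(smv, recv, 0.6, n_sim = n_sim, seed = s), 0)
    stats::sd(th)
  }
  expect_gt(spread(150), spread(5000))
})

test_that("the viability surface reproduces worked values and classifies
           populations consistently", {
  sm <- table1_survival(TRUE); rec <- table1_recruitment(TRUE)
  vs <- viability_surface(sm, rec, D_grid = 0.35, P_grid = c(0.21, 0.85),
                          n_sim = 300, seed = 4)
  expect_equal(vs$surface$R[vs$surface$P == 0.21], 0.1405, tolerance = 1e-3)
  expect_equal(vs$surface$R[vs$surface$P == 0.85], 0.456, tolerance = 1e-3)
  expect_equal(vs$surface$lambda_f,
               vs$surface$S_f / (1 - vs$surface$R_f))
  expect_true(all(vs$thresholds$D_star_95 <= vs$thresholds$D_star_mean + 1e-9))
  # degenerate 1x1 grid: a single viability point
  one <- viability_surface(sm, rec, D_grid = 0.3, P_grid = 0.5, n_sim = 300,
                           seed = 5)
  expect_equal(nrow(one$surface), 1)
  # classification flips exactly once along D (lambda monotone)
  pop_grid <- data.frame(population = sprintf("g%02d", 1:21),
                         D = seq(0, 1, by = 0.05), P = 0.6)
  cls <- viability_surface(sm, rec, D_grid = c(0.2, 0.4), P_grid = 0.6,
                           n_sim = 300, seed = 6,
                           populations = pop_grid)$populations
  inc <- cls$status == "increasing"
  expect_true(all(diff(inc) <= 0))       # once it stops increasing, it stays
  expect_equal(sum(diff(inc) != 0), 1)
  # a population placed on the boundary is stable within tolerance
  d_star <- as.numeric(mean_threshold(sm, rec, 0.6, tol = 1e-9))
  on_curve <- data.frame(population = "edge", D = d_star, P = 0.6)
  cls2 <- viability_surface(sm, rec, D_grid = 0.3, P_grid = 0.6, n_sim = 300,
                            seed = 7, populations = on_curve,
                            class_tol = 1e-4)$populations
  expect_equal(cls2$status, "stable")
  expect_error(viability_surface(sm, rec, D_grid = numeric(0)), "non-empty")
})
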