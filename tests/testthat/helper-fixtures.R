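# Shared fixtures: published-coefficient models and small record builders.

table1_survival <- function(with_se = FALSE) {
  vital_rate_model("survival", beta = c(1.67, -0.77, 1.22),
                   se = if (with_se) c(0.29, 0.29, 0.54))
}

table1_recruitment <- function(with_se = FALSE) {
  vital_rate_model("recruitment", beta = c(-0.15, -5.05, 2.41),
                   se = if (with_se) c(0.59, 0.14, 1.22))
}

# single-year collar records from day offsets within the 2005 biological year
collar_records <- function(entry_day, exit_day, fate, population = "popA",
                           year = 2005L) {
  n <- length(entry_day)
  start <- as.Date(sprintf("%d-04-01", year))
  data.frame(
    animal_id = sprintf("a%02d", seq_len(n)), population = population,
    year = year, entry_date = start + entry_day, exit_date = start + exit_day,
    fate = fate
  )
}

# independent Kaplan-Meier check via the survival package (counting-process
# form); valid when no death time coincides with another animal's entry day
survfit_oracle <- function(entry, exit, dead) {
  skip_if_not_installed("survival")
  sf <- survival::survfit(
    survival::Surv(entry, exit, dead) ~ 1,
    data = data.frame(entry = entry, exit = exit, dead = as.integer(dead)))
  min(sf$surv)
}

# weighted logistic-regression oracle for the sigma_pop = 0 mixed fits
glm_oracle <- function(y, w, x2, x3, names3 = c("(Intercept)", "D", "P")) {
  f <- suppressWarnings(glm(y ~ x2 + x3, family = binomial(), weights = w))
  setNames(as.numeric(coef(f)), names3)
}
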