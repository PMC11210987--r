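# Aalen-Johansen estimator, horizon evaluation, strata, heat map, summary.

test_that("two-subject example and input validation", {
  cur <- aalen_johansen(c(1, 2), c(1, 0))
  expect_equal(cur$times, 1)
  expect_equal(unname(cur$cif[1, 1]), 0.5)
  expect_error(aalen_johansen(c(-1, 2), c(1, 0)), class = "ckd_invalid_input_error")
  expect_error(aalen_johansen(c(1, 2), c(1, -2)), class = "ckd_invalid_input_error")
})

test_that("8-subject hand-tabulated dataset is reproduced exactly", {
  h <- aj_hand_data()
  cur <- aalen_johansen(h$time, h$code)
  expect_equal(cur$times, h$times)
  expect_equal(unname(cur$cif[, 1]), h$cif1)
  expect_equal(unname(cur$cif[, 2]), h$cif2)
  expect_equal(cur$surv, h$surv)
  # conservation at every event time
  expect_equal(rowSums(cur$cif) + cur$surv, rep(1, length(h$times)))
})

test_that("AJ equals 1 - KM when there are no competing events", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    time <- sample(1:30, n, replace = TRUE)
    code <- rbinom(n, 1, 0.6)
    cur <- aalen_johansen(time, code)
    km <- survival::survfit(survival::Surv(time, code) ~ 1)
    km_at <- summary(km, times = cur$times)$surv
    expect_equal(unname(cur$cif[, 1]), 1 - km_at, tolerance = 1e-12)
  }
})

test_that("AJ point estimates match survival's multistate estimator", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    time <- sample(1:40, n, replace = TRUE)
    code <- sample(0:2, n, replace = TRUE)
    if (!any(code > 0)) code[1] <- 1L
    cur <- aalen_johansen(time, code)
    fit <- survival::survfit(
      survival::Surv(time, factor(code, 0:2, c("censor", "c1", "c2"))) ~ 1)
    s <- summary(fit, times = cur$times)
    for (k in seq_along(cur$causes)) {
      col <- match(paste0("c", cur$causes[k]), fit$states)
      expect_equal(unname(cur$cif[, k]), unname(s$pstate[, col]),
                   tolerance = 1e-10, info = paste("rep", i, "cause", k))
    }
  }
})

test_that("CIF invariants hold on fuzzed data", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(10:100, 1)
    time <- round(rexp(n, 0.1), 2)
    code <- sample(0:2, n, replace = TRUE)
    cur <- aalen_johansen(time, code)
    if (length(cur$times) == 0) next
    for (k in seq_along(cur$causes)) {
      expect_true(all(diff(cur$cif[, k]) >= 0))             # monotone
      expect_true(all(cur$ci_lower[, k] <= cur$cif[, k] + 1e-12))
      expect_true(all(cur$ci_upper[, k] >= cur$cif[, k] - 1e-12))
      expect_true(all(cur$ci_lower[, k] >= 0 & cur$ci_upper[, k] <= 1))
    }
    expect_equal(rowSums(cur$cif) + cur$surv,
                 rep(1, length(cur$times)), tolerance = 1e-12)
    # permutation invariance
    p <- sample(n)
    cur2 <- aalen_johansen(time[p], code[p])
    expect_equal(cur2$cif, cur$cif)
    expect_equal(cur2$se, cur$se)
  }
})

test_that("risk_at is a right-continuous step function with truncation flag", {
  h <- aj_hand_data()
  cur <- aalen_johansen(h$time, h$code)
  expect_equal(risk_at(cur, 0.5)$risk, 0)
  expect_equal(risk_at(cur, 1)$risk, 0.125)   # includes the event at t = 1
  expect_equal(risk_at(cur, 4.9)$risk, 0.25)
  expect_equal(risk_at(cur, 5)$risk, 0.40625)
  expect_warning(r <- risk_at(cur, 100), "beyond last follow-up")
  expect_true(r$truncated)
  expect_equal(r$risk, 0.71875)
  expect_error(risk_at(cur, -1), class = "ckd_invalid_input_error")
})

test_that("stratified risks: single stratum identity, empty stratum flagged", {
  set.seed(14)
  time <- rexp(50, 0.2); code <- sample(0:2, 50, replace = TRUE)
  whole <- aalen_johansen(time, code)
  one <- stratified_risks(time, code, rep("all", 50))
  expect_equal(one$all$cif, whole$cif)
  two <- stratified_risks(c(time, time), c(code, code),
                          rep(c("a", "b"), each = 50))
  expect_equal(two$a$cif, two$b$cif) # exchangeability
  expect_warning(
    got <- stratified_risks(time, code, factor(rep("a", 50), levels = c("a", "b"))),
    "empty")
  expect_named(got, "a")
})

test_that("heat map: identical covariates give equal cells; sex swap transposes", {
  persons <- data.table::data.table(
    person_id = sprintf("P%02d", 1:40), sex = rep(c("female", "male"), 20),
    diabetes = FALSE, hypertension = FALSE, cvd = FALSE, uacr_mg_g = 10)
  set.seed(15)
  outcomes <- data.table::data.table(
    person_id = persons$person_id,
    time = round(rexp(40, 1 / 500)), code = sample(0:2, 40, replace = TRUE))
  hm <- heatmap_table(outcomes, persons, horizons = 365)
  filled <- hm[!hm$empty & hm$n > 0]
  expect_true(all(!is.na(filled$risk)))
  # swapping every sex label exactly transposes female/male cells
  persons2 <- data.table::copy(persons)
  persons2[, sex := ifelse(sex == "female", "male", "female")]
  hm2 <- heatmap_table(outcomes, persons2, horizons = 365)
  a <- hm[order(sex, albuminuria, diabetes, htn_or_cvd)]
  b <- hm2[, sex := ifelse(sex == "female", "male", "female")][
    order(sex, albuminuria, diabetes, htn_or_cvd)]
  expect_equal(a$risk, b$risk)
  expect_equal(a$n, b$n)
  # cells with zero persons are flagged empty
  expect_true(all(hm[n == 0, empty]))
})

test_that("cohort summary percentages normalize and quantiles match sort oracle", {
  set.seed(16)
  n <- 37
  cohort <- data.table::data.table(
    person_id = sprintf("P%02d", 1:n), index_time = sample(1000:2000, n),
    inclusion_egfr = runif(n, 30, 60),
    substage = sample(c("G3a", "G3b"), n, TRUE),
    age_at_index = runif(n, 20, 95))
  persons <- data.table::data.table(
    person_id = cohort$person_id,
    sex = sample(c("female", "male"), n, TRUE),
    diabetes = runif(n) < 0.2, hypertension = runif(n) < 0.6,
    cvd = runif(n) < 0.2,
    uacr_mg_g = ifelse(runif(n) < 0.5, NA, runif(n, 1, 500)))
  s <- cohort_summary(cohort, persons)
  for (v in unique(s$variable[!is.na(s$level)])) {
    expect_equal(sum(s$pct[s$variable == v]), 100, tolerance = 1e-9)
  }
  # median/quartile oracle by explicit sort (type-7 quantiles)
  q <- sort(cohort$age_at_index)
  oracle <- unname(quantile(q, c(.25, .5, .75)))
  expect_equal(s$summary[s$variable == "age at inclusion (years)"],
               sprintf("%.1f (%.1f-%.1f)", oracle[2], oracle[1], oracle[3]))
  # single person: percentages all 0 or 100
  s1 <- cohort_summary(cohort[1], persons[1])
  expect_true(all(s1$pct[!is.na(s1$pct)] %in% c(0, 100)))
})
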