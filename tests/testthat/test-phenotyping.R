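# Case-finding, substaging, slope, progression detectors, outcome coding.

test_that("incident CKD case-finding applies the 90-day pair rule", {
  r <- find_incident_ckd_g3(c(0, 90), c(55, 52), 0, 1000)
  expect_equal(r$index_time, 90)
  expect_equal(r$inclusion_egfr, 52)
  expect_null(find_incident_ckd_g3(c(0, 89), c(55, 52), 0, 1000))
  # prevalent: pair completes during lookback, another inside the window
  expect_null(find_incident_ckd_g3(c(0, 100, 500, 600), c(55, 52, 50, 49),
                                   enrollment_start = 400,
                                   enrollment_end = 1000))
  # pair completes after the window
  expect_null(find_incident_ckd_g3(c(0, 90), c(55, 52), 0, 50))
  # prior KRT blocks inclusion
  expect_null(find_incident_ckd_g3(c(0, 90), c(55, 52), 0, 1000, krt_time = 10))
  expect_equal(find_incident_ckd_g3(c(0, 90), c(55, 52), 0, 1000,
                                    krt_time = 95)$index_time, 90)
  expect_error(find_incident_ckd_g3(c(90, 0), c(55, 52), 0, 1000),
               class = "ckd_contract_error")
})

test_that("case-finding agrees with the all-pairs oracle on fuzzed series", {
  set.seed(202)
  for (i in 1:400) {
    s <- fuzz_egfr_series(lo = 20, hi = 75)
    start <- sample(c(0, 200, 600), 1)
    end <- start + sample(c(200, 800), 1)
    krt <- if (runif(1) < 0.3) sample(0:1500, 1) else NA
    got <- find_incident_ckd_g3(s$time, s$egfr, start, end, krt_time = krt)
    exp <- oracle_find_incident(s$time, s$egfr, start, end, krt)
    expect_equal(got, exp, info = paste("series", i))
  }
})

test_that("substage classification matches its definition and oracle", {
  expect_equal(classify_substage(c(0, 100), c(40, 42), 100), "G3b")
  expect_equal(classify_substage(c(0, 100), c(40, 55), 100), "G3a")
  expect_equal(classify_substage(c(0, 89), c(40, 44), 89), "G3a")
  # 45 is G3a, not in the G3b band
  expect_equal(classify_substage(c(0, 100), c(45, 44), 100), "G3a")
  set.seed(303)
  for (i in 1:300) {
    s <- fuzz_egfr_series(lo = 25, hi = 65)
    idx <- sample(s$time, 1)
    expect_equal(classify_substage(s$time, s$egfr, idx),
                 oracle_substage(s$time, s$egfr, idx),
                 info = paste("series", i))
  }
})

test_that("slope fit equals closed-form OLS and handles degeneracy", {
  f <- fit_egfr_slope(c(0, 365.25), c(50, 44))
  expect_equal(f$slope, -6)
  f <- fit_egfr_slope(c(0, 365.25, 730.5), 60 - 5 * c(0, 1, 2))
  expect_equal(f$slope, -5)
  # noisy cloud vs lm() as the independent oracle
  set.seed(9)
  t <- sort(runif(6, 0, 700)); y <- 70 - 4 * t / 365.25 + rnorm(6, 0, 2)
  f <- fit_egfr_slope(t, y)
  m <- lm(y ~ I(t / 365.25))
  expect_equal(f$slope, unname(coef(m)[2]))
  expect_equal(f$intercept, unname(coef(m)[1]))
  expect_error(fit_egfr_slope(c(5, 5), c(40, 41)),
               class = "ckd_degenerate_fit_error")
  expect_error(fit_egfr_slope(5, 40), class = "ckd_invalid_input_error")
})

# A hand-constructed trajectory exercising every clause of the
# rapid-progression definition. Inclusion eGFR 56 at index day 0;
# measurements at days 30 (54), 120 (50), 200 (48 = m1). The slope window
# (m1 - 365, m1] holds all three points, spans 170 >= 90 days and the OLS
# slope is ~ -12.9/yr <= -5; eGFR(m1) = 48 <= 51 = inclusion - 5.
rapid_base <- function() list(time = c(30, 120, 200), egfr = c(54, 50, 48))

test_that("rapid progression: confirmation window boundaries 29/30/180/181", {
  b <- rapid_base()
  run <- function(extra_t, extra_e, confirm = TRUE)
    detect_rapid_progression(c(b$time, extra_t), c(b$egfr, extra_e),
                             index_time = 0, inclusion_egfr = 56,
                             require_confirmation = confirm)
  expect_equal(run(260, 47), 260)          # +60 d, value <= m1
  expect_equal(run(230, 47), 230)          # +30 d boundary inclusive
  expect_equal(run(380, 47), 380)          # +180 d boundary inclusive
  expect_null(run(229, 47))                # +29 d: outside window
  expect_null(run(381, 47))                # +181 d: outside window
  expect_equal(run(229, 47, confirm = FALSE), 200) # potential: event at m1
  # confirmatory value above m1 but itself satisfying (a)-(c)
  expect_equal(run(260, 49), 260)
  # confirmatory value above m1 and not qualifying (drop < 5) -> no event
  expect_null(run(260, 53))
  # event date is the FIRST confirmatory measurement
  r <- detect_rapid_progression(c(b$time, 240, 260), c(b$egfr, 47.5, 47),
                                0, 56, TRUE)
  expect_equal(r, 240)
})

test_that("rapid progression: drop, slope, count and span clauses", {
  # flat series: no decline
  expect_null(detect_rapid_progression(c(100, 200, 300), c(56, 56, 56),
                                       0, 56, FALSE))
  # drop boundary: exactly inclusion - 5 qualifies, just above does not
  expect_equal(detect_rapid_progression(c(30, 120, 200), c(54, 52, 51),
                                        0, 56, FALSE), 200)
  expect_null(detect_rapid_progression(c(30, 120, 200), c(54, 52, 51.01),
                                       0, 56, FALSE))
  # only two points in the window: fails the >= 3 rule
  expect_null(detect_rapid_progression(c(30, 200), c(54, 48), 0, 56, FALSE))
  # span: 89 days from first window point to m1 fails, 90 passes
  expect_null(detect_rapid_progression(c(111, 150, 200), c(54, 50, 48),
                                       0, 56, FALSE))
  expect_equal(detect_rapid_progression(c(110, 150, 200), c(54, 50, 48),
                                        0, 56, FALSE), 200)
  # slope boundary: exactly -5/yr qualifies. Times are exact binary
  # multiples of a quarter year and values exact multiples of 0.25, so the
  # closed-form OLS slope is exactly -5 in floating point.
  t <- 365.25 * c(1, 1.25, 1.5)
  e <- c(53.5, 52.25, 51) # 51 = inclusion - 5
  expect_identical(fit_egfr_slope(t, e)$slope, -5)
  expect_equal(detect_rapid_progression(t, e, 0, 56, FALSE), 365.25 * 1.5)
  # slope just shallower than -5 fails even though the drop clause holds
  e2 <- 51 + 4.9 * (365.25 * 1.5 - t) / 365.25
  expect_null(detect_rapid_progression(t, e2, 0, 56, FALSE))
  # a failed candidate does not block a later qualifying one
  tt <- c(30, 120, 200, 500, 560, 620, 700)
  ee <- c(54, 50, 48, 54, 50, 44, 43)
  # m1 = 200 lacks confirmation within 30-180 d; m1 = 620 is confirmed at 700
  expect_equal(detect_rapid_progression(tt, ee, 0, 56, TRUE), 700)
})

test_that("measurements before index participate in the slope window only", {
  # window (m1 - 365, m1] may include pre-index measurements
  t <- c(-100, 30, 200); e <- c(54, 50, 48)
  expect_equal(detect_rapid_progression(t, e, 0, 56, FALSE), 200)
  # same geometry but pre-index point outside the window
  t2 <- c(-200, 30, 200)
  expect_null(detect_rapid_progression(t2, e, 0, 56, FALSE))
})

test_that("category drop requires both the 25% drop and a worse stage", {
  expect_equal(detect_category_drop(c(100), c(41), 0, 56), 100)
  expect_null(detect_category_drop(c(100), c(44), 0, 56)) # 44 > 42
  expect_equal(detect_category_drop(c(50), c(24), 0, 32), 50)
  set.seed(404)
  for (i in 1:300) {
    s <- fuzz_egfr_series(lo = 5, hi = 70)
    incl <- runif(1, 30, 59.9)
    idx <- sample(0:1000, 1)
    got <- detect_category_drop(s$time, s$egfr, idx, incl)
    exp <- oracle_category_drop(s$time, s$egfr, idx, incl)
    expect_equal(got, exp, info = paste("series", i))
  }
})

test_that("kidney failure takes the earlier of the eGFR pair and KRT", {
  expect_equal(detect_kidney_failure(c(0, 95), c(14, 13)), 95)
  expect_null(detect_kidney_failure(c(0), c(10)))
  expect_equal(detect_kidney_failure(c(0, 120), c(14, 13), krt_time = 50), 50)
  expect_null(detect_kidney_failure(c(0, 80), c(14, 13)))
  set.seed(505)
  for (i in 1:300) {
    s <- fuzz_egfr_series(lo = 5, hi = 40)
    krt <- if (runif(1) < 0.3) sample(0:1500, 1) else NA
    expect_equal(detect_kidney_failure(s$time, s$egfr, krt),
                 oracle_kidney_failure(s$time, s$egfr, krt),
                 info = paste("series", i))
  }
})

test_that("outcome coding matches the enumeration oracle over orderings", {
  co <- data.table::data.table(person_id = "A", index_time = 100)
  vals <- c(NA, 150, 250, 350)
  i <- 0
  for (ev in vals) for (dth in vals) for (em in vals) {
    i <- i + 1
    persons <- data.table::data.table(person_id = "A", death_time = dth,
                                      emigration_time = em)
    events <- data.table::data.table(person_id = "A", outcome = "rapid",
                                     event_time = ev)
    got <- assemble_outcomes(events, co, persons, admin_end = 300)
    exp <- oracle_outcome_code(ev, dth, em, 300, 100)
    expect_equal(got$time, exp$time, info = paste("case", i))
    expect_equal(got$code, exp$code, info = paste("case", i))
  }
  # event before index violates the contract
  expect_error(assemble_outcomes(
    data.table::data.table(person_id = "A", outcome = "rapid", event_time = 50),
    co, data.table::data.table(person_id = "A", death_time = NA_real_,
                               emigration_time = NA_real_), 300),
    class = "ckd_contract_error")
  # death outcome: the death is the event
  got <- assemble_outcomes(
    data.table::data.table(person_id = "A", outcome = "death",
                           event_time = NA_real_),
    co, data.table::data.table(person_id = "A", death_time = 200,
                               emigration_time = NA_real_), 300)
  expect_equal(got$code, 1L)
  expect_equal(got$time, 100)
})
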