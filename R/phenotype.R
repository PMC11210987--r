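# Incident CKD stage G3 case-finding and progression outcome classifiers.
#
# All detectors operate on one person's AKI-filtered, chronologically sorted
# eGFR series (numeric day times, full-precision eGFR). Day arithmetic is on
# integer day differences; every ">= N days" rule compares the raw
# difference.

#' Find incident CKD stage G3
#'
#' Incident CKD stage G3 is the earliest pair of eGFR values in `[30, 60)`
#' mL/min/1.73 m^2 separated by >= 90 days. The index date is the second
#' measurement of the pair and the inclusion eGFR is its value (the last of
#' the measurements used to define incident CKD). A person is not incident
#' if the earliest qualifying pair completes before `enrollment_start`
#' (prevalent disease), after `enrollment_end`, or if kidney replacement
#' therapy predates the index date.
#'
#' @param time Sorted measurement times (days).
#' @param egfr eGFR values (mL/min/1.73 m^2).
#' @param enrollment_start,enrollment_end Enrollment window (days). The
#'   caller guarantees at least `lookback_years` of measurement coverage
#'   before `enrollment_start`.
#' @param krt_time Day of first kidney replacement therapy, `NA` if none.
#' @param min_gap_days Minimum separation of the pair (default 90).
#' @param band eGFR band defining stage G3, default `c(30, 60)`,
#'   left-closed.
#' @return List with `index_time` and `inclusion_egfr`, or `NULL`.
#' @examples
#' find_incident_ckd_g3(c(0, 90), c(55, 52), enrollment_start = 0,
#'                      enrollment_end = 1000)
#' @export
find_incident_ckd_g3 <- function(time, egfr, enrollment_start, enrollment_end,
                                 krt_time = NA_real_, min_gap_days = 90,
                                 band = c(30, 60)) {
  assert_sorted(time, "egfr series")
  inb <- egfr >= band[1] & egfr < band[2]
  bt <- time[inb]
  if (length(bt) < 2L) return(NULL)
  be <- egfr[inb]
  # earliest completion: first band time >= 90 days after the earliest
  # preceding band time (the running minimum is the best partner)
  prior_min <- c(Inf, cummin(bt)[-length(bt)])
  idx <- which(bt - prior_min >= min_gap_days)
  if (length(idx) == 0L) return(NULL)
  i <- idx[1L]
  if (bt[i] < enrollment_start) return(NULL) # prevalent disease
  if (bt[i] > enrollment_end) return(NULL)
  if (!is.na(krt_time) && krt_time < bt[i]) return(NULL) # prior KRT
  list(index_time = bt[i], inclusion_egfr = be[i])
}

#' Classify the G3 substage at inclusion
#'
#' Stage G3b requires two or more eGFR values in `[30, 45)` at least 90
#' days apart at or before the index date; everyone else is G3a.
#'
#' @inheritParams find_incident_ckd_g3
#' @param index_time Index date from [find_incident_ckd_g3()].
#' @return `"G3b"` or `"G3a"`.
#' @export
classify_substage <- function(time, egfr, index_time, min_gap_days = 90) {
  assert_sorted(time, "egfr series")
  keep <- time <= index_time
  bt <- time[keep][egfr[keep] >= 30 & egfr[keep] < 45]
  if (length(bt) >= 2L &&
      any(bt - c(Inf, cummin(bt)[-length(bt)]) >= min_gap_days)) "G3b"
  else "G3a"
}

#' Ordinary least-squares eGFR slope
#'
#' Regresses eGFR on time expressed in years; the closed-form OLS slope
#' `sum((t - tbar) * (y - ybar)) / sum((t - tbar)^2)`.
#'
#' @param time Measurement times in days.
#' @param egfr eGFR values.
#' @return List with `slope` (mL/min/1.73 m^2 per year), `intercept`,
#'   `n_points`, `span_days`.
#' @export
fit_egfr_slope <- function(time, egfr) {
  n <- length(time)
  if (n < 2L) ckd_invalid_input("slope fit needs at least 2 points")
  t_yr <- time / DAYS_PER_YEAR
  tc <- t_yr - mean(t_yr)
  den <- sum(tc^2)
  if (den == 0) ckd_stop("all measurement times identical; slope undefined",
                         "ckd_degenerate_fit_error")
  slope <- sum(tc * (egfr - mean(egfr))) / den
  list(slope = slope, intercept = mean(egfr) - slope * mean(t_yr),
       n_points = n, span_days = max(time) - min(time))
}

# criteria (a)-(c) of the rapid-progression definition at candidate index i,
# evaluated on the full series
.rapid_m1_ok <- function(time, egfr, i, inclusion_egfr,
                         drop = 5, slope_threshold = -5,
                         window_days = 365, min_points = 3,
                         min_span_days = 90) {
  if (egfr[i] > inclusion_egfr - drop) return(FALSE)          # (a)
  w <- which(time > time[i] - window_days & time <= time[i])
  if (length(w) < min_points) return(FALSE)                   # (c) count
  if (time[i] - min(time[w]) < min_span_days) return(FALSE)   # (c) span
  fit_egfr_slope(time[w], egfr[w])$slope <= slope_threshold   # (b)
}

#' Detect rapid progression of CKD
#'
#' Rapid progression is an eGFR measurement m1 during follow-up that is
#' (a) >= 5 mL/min/1.73 m^2 below the inclusion eGFR, with (b) an OLS slope
#' over m1 and all measurements in the preceding 365 days of <=
#' -5 mL/min/1.73 m^2/year, (c) at least three measurements in that window
#' with >= 90 days between its first measurement and m1. In confirmed mode
#' m1 must additionally be followed, 30-180 days later, by a measurement
#' that is <= eGFR(m1) or itself satisfies (a)-(c); the event date is the
#' date of the first such confirmatory measurement. In unconfirmed mode
#' ("potential rapid progression") the event date is m1's date. Candidates
#' are scanned chronologically and a failed candidate does not block later
#' ones; the earliest event date over all candidates is returned.
#'
#' @inheritParams classify_substage
#' @param inclusion_egfr Inclusion eGFR of the person.
#' @param require_confirmation Confirmed (`TRUE`, default) vs. potential
#'   rapid progression.
#' @param drop Minimum absolute drop from inclusion (default 5).
#' @param slope_threshold Maximum slope (default -5 per year).
#' @param window_days Slope window preceding m1 (default 365).
#' @param min_points Minimum measurements in the window (default 3).
#' @param min_span_days Minimum span from the window's first measurement to
#'   m1 (default 90).
#' @param confirm_window Confirmation window in days after m1, default
#'   `c(30, 180)`, both ends inclusive.
#' @return Event day, or `NULL` if no event.
#' @export
detect_rapid_progression <- function(time, egfr, index_time, inclusion_egfr,
                                     require_confirmation = TRUE,
                                     drop = 5, slope_threshold = -5,
                                     window_days = 365, min_points = 3,
                                     min_span_days = 90,
                                     confirm_window = c(30, 180)) {
  assert_sorted(time, "egfr series")
  candidates <- which(time > index_time)
  best <- Inf
  for (i in candidates) {
    # no later candidate can confirm before the current best event date
    if (time[i] + (if (require_confirmation) confirm_window[1] else 0) >= best)
      break
    if (!.rapid_m1_ok(time, egfr, i, inclusion_egfr, drop, slope_threshold,
                      window_days, min_points, min_span_days))
      next
    if (!require_confirmation) {
      best <- time[i]
      break
    }
    conf <- which(time - time[i] >= confirm_window[1] &
                  time - time[i] <= confirm_window[2])
    for (j in conf) {
      if (egfr[j] <= egfr[i] ||
          .rapid_m1_ok(time, egfr, j, inclusion_egfr, drop, slope_threshold,
                       window_days, min_points, min_span_days)) {
        best <- min(best, time[j])
        break # first confirmatory measurement for this m1
      }
    }
  }
  if (is.finite(best)) best else NULL
}

#' Detect a drop in GFR category
#'
#' First post-index measurement whose eGFR is <= 75% of the inclusion eGFR
#' AND whose GFR stage is strictly worse than the stage of the inclusion
#' eGFR (both conditions must hold at the same measurement).
#'
#' @inheritParams detect_rapid_progression
#' @return Event day or `NULL`.
#' @export
detect_category_drop <- function(time, egfr, index_time, inclusion_egfr) {
  assert_sorted(time, "egfr series")
  post <- time > index_time
  if (!any(post)) return(NULL)
  incl_rank <- gfr_stage_rank(gfr_stage(inclusion_egfr))
  hit <- post & egfr <= 0.75 * inclusion_egfr &
    gfr_stage_rank(gfr_stage(pmax(egfr, .Machine$double.eps))) > incl_rank
  if (any(hit)) time[which(hit)[1L]] else NULL
}

#' Detect kidney failure
#'
#' Kidney failure is the earlier of (a) the second measurement of the first
#' pair of eGFR values below 15 mL/min/1.73 m^2 separated by >= 90 days,
#' and (b) kidney replacement therapy.
#'
#' @inheritParams find_incident_ckd_g3
#' @return Event day or `NULL`.
#' @export
detect_kidney_failure <- function(time, egfr, krt_time = NA_real_,
                                  min_gap_days = 90) {
  assert_sorted(time, "egfr series")
  bt <- time[egfr < 15]
  pair_time <- Inf
  if (length(bt) >= 2L) {
    idx <- which(bt - c(Inf, cummin(bt)[-length(bt)]) >= min_gap_days)
    if (length(idx)) pair_time <- bt[idx[1L]]
  }
  ev <- min(pair_time, if (is.na(krt_time)) Inf else krt_time)
  if (is.finite(ev)) ev else NULL
}

#' Assemble competing-risk outcome records
#'
#' For each person and outcome, codes the first event (1), competing death
#' (2) or censoring (0) with its time since the index date. Follow-up runs
#' from the index date until death, emigration or `admin_end`, whichever
#' first. Ties are resolved events-first: an event on the death/censoring
#' day counts as an event, and a death on the censoring day counts as a
#' death. For the outcome `"death"` the death itself is the event (code 1)
#' and there is no competing cause.
#'
#' @param events data.table with columns `person_id`, `outcome`,
#'   `event_time` (day of first event, `NA` if none observed).
#' @param cohort data.table with `person_id`, `index_time`.
#' @param persons data.table with `person_id`, `death_time`,
#'   `emigration_time` (both `NA` allowed).
#' @param admin_end Administrative end of study (day).
#' @return data.table `person_id`, `outcome`, `time` (days since index),
#'   `code` (0 censored / 1 event / 2 competing death).
#' @export
assemble_outcomes <- function(events, cohort, persons, admin_end) {
  ev <- as.data.table(events)
  x <- merge(ev, as.data.table(cohort)[, .(person_id, index_time)],
             by = "person_id")
  x <- merge(x,
             as.data.table(persons)[, .(person_id, death_time, emigration_time)],
             by = "person_id")
  if (any(!is.na(x$event_time) & x$event_time < x$index_time))
    ckd_contract_violation("event time before index date")
  x[, {
    cens <- pmin(ifelse(is.na(emigration_time), Inf, emigration_time),
                 admin_end)
    dth <- ifelse(is.na(death_time) | death_time > cens, Inf, death_time)
    evt <- ifelse(is.na(event_time), Inf, event_time)
    if (outcome == "death") {
      if (is.finite(dth)) list(time = dth - index_time, code = 1L)
      else list(time = cens - index_time, code = 0L)
    } else if (is.finite(evt) && evt <= cens && evt <= dth) {
      list(time = evt - index_time, code = 1L)
    } else if (is.finite(dth)) {
      list(time = dth - index_time, code = 2L)
    } else {
      list(time = cens - index_time, code = 0L)
    }
  }, by = .(person_id, outcome)]
}
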