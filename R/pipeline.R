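# The end-to-end pipeline: AKI filter -> eGFR -> case-finding ->
# outcome classification -> Aalen-Johansen estimation -> heat map.

OUTCOME_NAMES <- c("rapid", "potential_rapid", "category_drop",
                   "kidney_failure", "hospitalization", "death")

#' Pipeline configuration
#'
#' @param equation eGFR equation, `"2009"` (primary) or `"2021"`
#'   (sensitivity).
#' @param enrollment_start,enrollment_end Enrollment window (days since
#'   epoch).
#' @param admin_end Administrative end of study (days).
#' @param lookback_years Required measurement coverage before enrollment
#'   (informational; prevalence is judged by qualifying pairs completing
#'   before `enrollment_start`).
#' @param horizons Risk horizons in days (default 1 and 3 years).
#' @param conf_level Confidence level for all intervals.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(equation = c("2009", "2021"),
                            enrollment_start = 1095, enrollment_end = 2555,
                            admin_end = 2920, lookback_years = 3,
                            horizons = c(365L, 1095L), conf_level = 0.95) {
  equation <- match.arg(equation)
  if (any(horizons <= 0)) ckd_config_error("horizons must be positive")
  if (!(enrollment_start <= enrollment_end && enrollment_end <= admin_end))
    ckd_config_error("need enrollment_start <= enrollment_end <= admin_end")
  cfg <- list(equation = equation, enrollment_start = enrollment_start,
              enrollment_end = enrollment_end, admin_end = admin_end,
              lookback_years = lookback_years, horizons = horizons,
              conf_level = conf_level)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Compute AKI-filtered eGFR series
#'
#' Removes inpatient-setting measurements, runs the AKI filter on each
#' person's creatinine series, and computes eGFR on the surviving
#' measurements with the configured equation. Age is evaluated at each
#' measurement date from `birth_time`.
#'
#' @param measurements Measurement table (see [read_measurements()]).
#' @param persons Person table (see [read_persons()]).
#' @param equation `"2009"` or `"2021"`.
#' @return List: `egfr` (person_id, time, creatinine, egfr for non-AKI,
#'   outpatient/primary measurements), `episodes` (AKI episode table),
#'   `n_flagged` (measurements excluded for AKI).
#' @export
compute_egfr_points <- function(measurements, persons,
                                equation = c("2009", "2021")) {
  equation <- match.arg(equation)
  m <- as.data.table(measurements)
  if (!"setting" %in% names(m)) m[, setting := "primary"]
  m <- m[setting != "inpatient"]
  flt <- aki_filter(m)
  m <- flt$measurements
  n_flagged <- sum(m$excluded_for_aki)
  keep <- m[excluded_for_aki == FALSE]
  keep <- merge(keep,
                as.data.table(persons)[, .(person_id, sex, birth_time)],
                by = "person_id")
  keep[, age := (time - birth_time) / DAYS_PER_YEAR]
  keep <- keep[age >= 18]
  keep[, egfr := egfr_ckdepi(creatinine_umol_l, age, sex, equation)]
  setorder(keep, person_id, time)
  list(egfr = keep[, .(person_id, time, creatinine = creatinine_umol_l, egfr)],
       episodes = flt$episodes, n_flagged = n_flagged)
}

#' Build the incident CKD G3 cohort
#'
#' Runs [find_incident_ckd_g3()] and [classify_substage()] per person and
#' records the attrition: persons never meeting the pair criterion,
#' prevalent disease (pair completing before enrollment), pairs completing
#' after the enrollment window, and prior kidney replacement therapy.
#'
#' @param egfr_points `egfr` table from [compute_egfr_points()].
#' @param persons Person table.
#' @param config A [pipeline_config()].
#' @return List: `cohort` (person_id, index_time, inclusion_egfr, substage,
#'   age_at_index), `attrition` (category counts conserving the person
#'   total).
#' @export
build_cohort <- function(egfr_points, persons, config) {
  p <- as.data.table(persons)
  e <- merge(as.data.table(egfr_points),
             p[, .(person_id, krt_time, birth_time)], by = "person_id")
  setorder(e, person_id, time)
  per <- e[, {
    krt <- krt_time[1L]
    rec <- find_incident_ckd_g3(time, egfr, config$enrollment_start,
                                config$enrollment_end, krt_time = krt)
    if (is.null(rec)) {
      # classify the exclusion reason for the attrition table
      rec_any <- find_incident_ckd_g3(time, egfr, -Inf, Inf)
      reason <- if (is.null(rec_any)) "no_qualifying_pair"
      else if (rec_any$index_time < config$enrollment_start) "prevalent_ckd"
      else if (rec_any$index_time > config$enrollment_end) "after_window"
      else "prior_krt"
      list(index_time = NA_real_, inclusion_egfr = NA_real_,
           substage = NA_character_, age_at_index = NA_real_,
           reason = reason)
    } else {
      list(index_time = rec$index_time, inclusion_egfr = rec$inclusion_egfr,
           substage = classify_substage(time, egfr, rec$index_time),
           age_at_index = (rec$index_time - birth_time[1L]) / DAYS_PER_YEAR,
           reason = "included")
    }
  }, by = person_id]
  n_no_meas <- nrow(p) - uniqueN(e$person_id)
  attr_tab <- per[, .N, by = reason]
  attrition <- rbind(
    data.table(reason = "no_usable_measurements", N = n_no_meas),
    attr_tab
  )
  setnames(attrition, "N", "n_persons")
  cohort <- per[reason == "included",
                .(person_id, index_time, inclusion_egfr, substage,
                  age_at_index)]
  list(cohort = cohort, attrition = attrition)
}

#' Classify all progression outcomes for a cohort
#'
#' Applies the rapid-progression (confirmed and potential), category-drop
#' and kidney-failure detectors to each cohort person's post-index eGFR
#' series and takes the first inpatient admission after index as the
#' hospitalization event.
#'
#' @param egfr_points `egfr` table from [compute_egfr_points()].
#' @param cohort Cohort table from [build_cohort()].
#' @param persons Person table.
#' @param admissions Optional table of all admissions (`person_id`,
#'   `time`); falls back to `persons$first_admission_time`.
#' @return data.table `person_id`, `outcome`, `event_time` (`NA` = none).
#' @export
classify_outcomes <- function(egfr_points, cohort, persons,
                              admissions = NULL) {
  p <- as.data.table(persons)
  e <- merge(as.data.table(egfr_points),
             as.data.table(cohort)[, .(person_id, index_time, inclusion_egfr)],
             by = "person_id")
  e <- merge(e, p[, .(person_id, krt_time)], by = "person_id")
  setorder(e, person_id, time)
  nul <- function(x) if (is.null(x)) NA_real_ else x
  det <- e[, {
    idx <- index_time[1L]
    incl <- inclusion_egfr[1L]
    post <- time > idx
    krt <- krt_time[1L]
    if (!is.na(krt) && krt <= idx) krt <- NA_real_
    list(
      rapid = nul(detect_rapid_progression(time, egfr, idx, incl, TRUE)),
      potential_rapid = nul(detect_rapid_progression(time, egfr, idx, incl,
                                                     FALSE)),
      category_drop = nul(detect_category_drop(time, egfr, idx, incl)),
      kidney_failure = nul(detect_kidney_failure(time[post], egfr[post], krt))
    )
  }, by = person_id]
  long <- melt(det, id.vars = "person_id", variable.name = "outcome",
               value.name = "event_time", variable.factor = FALSE)
  # hospitalization: first inpatient admission strictly after index
  co <- as.data.table(cohort)
  if (!is.null(admissions)) {
    adm <- merge(as.data.table(admissions),
                 co[, .(person_id, index_time)], by = "person_id")
    hosp <- adm[time > index_time, .(event_time = min(time)), by = person_id]
  } else {
    hosp <- merge(p[, .(person_id, first_admission_time)],
                  co[, .(person_id, index_time)], by = "person_id")
    hosp <- hosp[!is.na(first_admission_time) & first_admission_time > index_time,
                 .(person_id, event_time = first_admission_time)]
  }
  hosp <- merge(co[, .(person_id)], hosp, by = "person_id", all.x = TRUE)
  hosp[, outcome := "hospitalization"]
  dth <- co[, .(person_id, outcome = "death", event_time = NA_real_)]
  rbindlist(list(long, hosp[, .(person_id, outcome, event_time)], dth))
}

#' Run the full pipeline and write artifacts
#'
#' simulate/read -> AKI filter -> eGFR -> case-finding -> outcomes ->
#' Aalen-Johansen curves -> heat map -> cohort summary, with an attrition
#' log and a reproducibility manifest (config echo, md5 hash, package and
#' R versions).
#'
#' @param measurements Measurement table or path.
#' @param persons Person table or path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for artifacts (`NULL` = do not write).
#' @param admissions Optional admissions table or path.
#' @return List: `cohort`, `outcomes`, `curves` (named list of
#'   `risk_curve`), `risks` (risk at each horizon per outcome), `heatmap`,
#'   `summary`, `attrition`, `episodes`, `manifest`.
#' @export
run_pipeline <- function(measurements, persons, config = pipeline_config(),
                         out_dir = NULL, admissions = NULL) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(persons)) persons <- read_persons(persons)
  if (is.character(admissions)) admissions <- fread(admissions)
  stage <- "aki_filter/egfr"
  res <- tryCatch({
    pts <- compute_egfr_points(measurements, persons, config$equation)
    stage <- "case_finding"
    bc <- build_cohort(pts$egfr, persons, config)
    stage <- "outcome_classification"
    events <- classify_outcomes(pts$egfr, bc$cohort, persons, admissions)
    outcomes <- assemble_outcomes(events, bc$cohort, persons,
                                  config$admin_end)
    stage <- "risk_estimation"
    curves <- lapply(setNames(OUTCOME_NAMES, OUTCOME_NAMES), function(o) {
      sub <- outcomes[outcome == o]
      aalen_johansen(sub$time, sub$code, config$conf_level)
    })
    risks <- rbindlist(lapply(OUTCOME_NAMES, function(o)
      rbindlist(lapply(config$horizons, function(h) {
        r <- suppressWarnings(risk_at(curves[[o]], h))
        data.table(outcome = o, horizon_days = h, risk = r$risk,
                   ci_lower = r$ci_lower, ci_upper = r$ci_upper,
                   truncated = r$truncated)
      }))))
    stage <- "heatmap/summary"
    hm <- heatmap_table(outcomes[outcome == "rapid"], persons,
                        config$horizons, config$conf_level)
    summ <- cohort_summary(bc$cohort, persons, measurements)
    list(cohort = bc$cohort, outcomes = outcomes, curves = curves,
         risks = risks, heatmap = hm, summary = summ,
         attrition = bc$attrition, episodes = pts$episodes,
         n_flagged_aki = pts$n_flagged)
  }, ckd_error = function(e) {
    ckd_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), class(e)[1])
  })
  res$manifest <- pipeline_manifest(config, res)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

pipeline_manifest <- function(config, res) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config = unclass(config), config_md5 = hash,
       n_cohort = nrow(res$cohort),
       n_flagged_aki = res$n_flagged_aki,
       attrition = as.list(setNames(res$attrition$n_persons,
                                    res$attrition$reason)),
       package_version = as.character(utils::packageVersion("ckdpheno")),
       r_version = as.character(getRversion()))
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(res$cohort, file.path(out_dir, "cohort.tsv"))
  write_table(res$outcomes, file.path(out_dir, "outcomes.tsv"))
  for (o in names(res$curves))
    write_table(risk_curve_table(res$curves[[o]]),
                file.path(out_dir, sprintf("curve_%s.tsv", o)))
  write_table(res$risks, file.path(out_dir, "risks.tsv"))
  write_table(res$heatmap, file.path(out_dir, "heatmap.tsv"))
  write_table(res$summary, file.path(out_dir, "cohort_summary.tsv"))
  write_table(res$attrition, file.path(out_dir, "attrition.tsv"))
  write_table(res$episodes, file.path(out_dir, "aki_episodes.tsv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
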