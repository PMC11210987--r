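# Synthetic registry generator.
#
# Emulates the statistical structure of nationwide laboratory/registry
# data: creatinine trajectories arising from a linear true-eGFR decline
# with a progressor/non-progressor mixture, a gamma-renewal visit process,
# multiplicative lognormal measurement noise, transient AKI excursions,
# covariate-dependent progression probability, and competing death,
# hospitalization and emigration processes. All ground truth is returned
# alongside the emitted tables so every pipeline stage can be verified.
#
# The time axis is integer-free "days since epoch": day 0 starts the
# lookback coverage, the enrollment window opens after `lookback_days`, and
# observation ends at `admin_end`.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()].
#' Defaults follow the marginals of a nationwide incident CKD G3 cohort
#' (55% female, 18% diabetes, 62% hypertension, 21% CVD; albuminuria
#' 22%/8%/2% with 67% unmeasured; median ~2 eGFR tests/year giving a mean
#' inter-visit gap of ~120 days; creatinine assay CV 6%). Slope mixture:
#' non-progressors N(-1, 1), progressors N(-8, 3) mL/min/1.73 m^2/year,
#' straddling the -5/year rapid-progression threshold.
#'
#' @param n_persons Number of persons.
#' @param seed Integer seed; all random streams derive from it via fixed
#'   offsets (covariates +1, trajectories +2, visits +3, noise +4, AKI +5,
#'   events +6).
#' @param lookback_days Measurement coverage before enrollment opens.
#' @param enrollment_start,enrollment_end Enrollment window (days).
#' @param admin_end Administrative end of study (days).
#' @param female_fraction Probability of female sex.
#' @param age_mean,age_sd,age_min,age_max Age (years) at epoch: truncated
#'   normal.
#' @param p_diabetes,p_hypertension,p_cvd Comorbidity prevalences.
#' @param albuminuria_probs Probabilities of stages A1, A2, A3 and missing
#'   uACR (must sum to 1).
#' @param baseline_egfr_mean,baseline_egfr_sd True eGFR at epoch.
#' @param egfr_floor Floor of the true eGFR trajectory.
#' @param progressor_model Named list of log-odds: `intercept`, `male`,
#'   `a2`, `a3`, `missing`, `diabetes`, `htn_cvd`.
#' @param slope_nonprog_mean,slope_nonprog_sd,slope_prog_mean,slope_prog_sd
#'   Slope mixture (mL/min/1.73 m^2 per year).
#' @param visit_gap_mean Mean inter-visit gap in days.
#' @param visit_shape Gamma shape of the renewal gaps (dispersion).
#' @param comorbid_gap_factor Multiplier on the gap for persons with
#'   diabetes or hypertension (< 1 = tested more often).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal creatinine measurement noise (0 disables noise).
#' @param p_inpatient Fraction of measurements drawn in the inpatient
#'   setting (removed upstream of phenotyping).
#' @param aki_rate AKI episodes per person-year (0 disables injection).
#' @param aki_mult_range,aki_duration_range Creatinine multiplier and
#'   episode duration (days) ranges, drawn uniformly.
#' @param gompertz_rate,gompertz_shape Death hazard a*exp(b*age)/year.
#' @param hosp_rate All-cause inpatient admission rate per person-year.
#' @param emigration_rate Emigration rate per person-year.
#' @param krt_egfr_threshold True-eGFR level at which kidney replacement
#'   therapy starts (`NA` disables KRT).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 1000, seed = 1,
                       lookback_days = 1095,
                       enrollment_start = 1095, enrollment_end = 2555,
                       admin_end = 2920,
                       female_fraction = 0.55,
                       age_mean = 71, age_sd = 9.5, age_min = 18, age_max = 99,
                       p_diabetes = 0.18, p_hypertension = 0.62, p_cvd = 0.21,
                       albuminuria_probs = c(A1 = 0.224, A2 = 0.085,
                                             A3 = 0.022, missing = 0.669),
                       baseline_egfr_mean = 68, baseline_egfr_sd = 8,
                       egfr_floor = 5,
                       progressor_model = list(intercept = qlogis(0.10),
                                               male = 0.3, a2 = 0.8, a3 = 1.8,
                                               missing = 0, diabetes = 0.5,
                                               htn_cvd = 0.5),
                       slope_nonprog_mean = -1, slope_nonprog_sd = 1,
                       slope_prog_mean = -8, slope_prog_sd = 3,
                       visit_gap_mean = 120, visit_shape = 2,
                       comorbid_gap_factor = 0.7,
                       noise_cv = 0.06, p_inpatient = 0.05,
                       aki_rate = 0.1, aki_mult_range = c(1.5, 3),
                       aki_duration_range = c(3, 14),
                       gompertz_rate = 8e-5, gompertz_shape = 0.09,
                       hosp_rate = 0.25, emigration_rate = 0.005,
                       krt_egfr_threshold = 10) {
  cfg <- as.list(environment())
  probs <- c(cfg$female_fraction, cfg$p_diabetes, cfg$p_hypertension,
             cfg$p_cvd, cfg$albuminuria_probs, cfg$p_inpatient)
  if (any(probs < 0 | probs > 1))
    ckd_config_error("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$albuminuria_probs) - 1) > 1e-8)
    ckd_config_error("albuminuria_probs must sum to 1")
  if (cfg$n_persons < 1) ckd_config_error("n_persons must be >= 1")
  if (any(c(cfg$age_sd, cfg$baseline_egfr_sd, cfg$slope_nonprog_sd,
            cfg$slope_prog_sd, cfg$visit_shape, cfg$visit_gap_mean) <= 0))
    ckd_config_error("scale/shape parameters must be positive")
  if (cfg$noise_cv < 0 || cfg$aki_rate < 0)
    ckd_config_error("noise_cv and aki_rate must be non-negative")
  if (cfg$baseline_egfr_mean <= cfg$egfr_floor)
    ckd_config_error("baseline eGFR mean must exceed the trajectory floor")
  if (!(cfg$enrollment_start <= cfg$enrollment_end &&
        cfg$enrollment_end <= cfg$admin_end))
    ckd_config_error("need enrollment_start <= enrollment_end <= admin_end")
  class(cfg) <- "sim_config"
  cfg
}

.rtnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# Gompertz death time (years from epoch) for hazard a*exp(b*(age0 + t))
.rgompertz <- function(n, a, b, age0) {
  e <- rexp(n)
  log(1 + b * e / (a * exp(b * age0))) / b
}

#' Simulate a synthetic registry cohort
#'
#' @param config A [sim_config()].
#' @return List with:
#' \describe{
#'   \item{persons}{`person_id`, `sex`, `birth_time`, `diabetes`,
#'     `hypertension`, `cvd`, `uacr_mg_g`, `death_time`,
#'     `emigration_time`, `krt_time`, `first_admission_time` (days; `NA`
#'     where unobserved before `admin_end`).}
#'   \item{measurements}{`person_id`, `time`, `creatinine_umol_l`,
#'     `setting` (`primary`/`outpatient`/`inpatient`).}
#'   \item{admissions}{all inpatient admission days per person.}
#'   \item{ground_truth}{per person: `baseline_egfr`, `slope`
#'     (per year), `progressor`, plus latent `death_time`,
#'     `emigration_time`, `krt_time`; and attribute-free `aki` table of
#'     injected excursions (`person_id`, `onset`, `end`, `multiplier`).}
#' }
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  n <- cfg$n_persons
  ids <- sprintf("P%06d", seq_len(n))

  set.seed(cfg$seed + 1) # covariates
  sex <- ifelse(runif(n) < cfg$female_fraction, "female", "male")
  age0 <- .rtnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max)
  birth_time <- -age0 * DAYS_PER_YEAR
  diabetes <- runif(n) < cfg$p_diabetes
  hypertension <- runif(n) < cfg$p_hypertension
  cvd <- runif(n) < cfg$p_cvd
  alb <- sample(ALBUMINURIA_LEVELS, n, replace = TRUE,
                prob = cfg$albuminuria_probs)
  uacr <- rep(NA_real_, n)
  uacr[alb == "A1"] <- runif(sum(alb == "A1"), 2, 29.9)
  uacr[alb == "A2"] <- runif(sum(alb == "A2"), 30, 300)
  uacr[alb == "A3"] <- runif(sum(alb == "A3"), 300.5, 1500)

  set.seed(cfg$seed + 2) # true trajectories
  pm <- cfg$progressor_model
  lin <- pm$intercept + pm$male * (sex == "male") +
    pm$a2 * (alb == "A2") + pm$a3 * (alb == "A3") +
    pm$missing * (alb == "missing") +
    pm$diabetes * diabetes + pm$htn_cvd * (hypertension | cvd)
  progressor <- runif(n) < plogis(lin)
  slope <- ifelse(progressor,
                  rnorm(n, cfg$slope_prog_mean, cfg$slope_prog_sd),
                  rnorm(n, cfg$slope_nonprog_mean, cfg$slope_nonprog_sd))
  baseline <- .rtnorm(n, cfg$baseline_egfr_mean, cfg$baseline_egfr_sd,
                      cfg$egfr_floor + 1, 150)

  set.seed(cfg$seed + 6) # competing processes
  death_time <- .rgompertz(n, cfg$gompertz_rate, cfg$gompertz_shape, age0) *
    DAYS_PER_YEAR
  emigration_time <- rexp(n, cfg$emigration_rate) * DAYS_PER_YEAR
  span_years <- cfg$admin_end / DAYS_PER_YEAR
  adm_counts <- rpois(n, cfg$hosp_rate * span_years)
  admissions <- data.table(
    person_id = rep(ids, adm_counts),
    time = runif(sum(adm_counts), 0, cfg$admin_end),
    alive_until = rep(pmin(death_time, emigration_time), adm_counts)
  )
  admissions <- admissions[time <= alive_until][, alive_until := NULL]
  setorder(admissions, person_id, time)
  first_adm <- admissions[, .(first_admission_time = min(time)),
                          by = person_id]
  krt_time <- rep(NA_real_, n)
  if (!is.na(cfg$krt_egfr_threshold)) {
    cross <- (cfg$krt_egfr_threshold - baseline) / slope # years; slope < 0
    hit <- !is.na(cross) & slope < 0 & cross > 0 &
      cross * DAYS_PER_YEAR <= cfg$admin_end
    krt_time[hit] <- cross[hit] * DAYS_PER_YEAR
  }

  set.seed(cfg$seed + 3) # visit process
  gap <- cfg$visit_gap_mean *
    ifelse(diabetes | hypertension, cfg$comorbid_gap_factor, 1)
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    end_i <- min(cfg$admin_end, death_time[i], emigration_time[i])
    if (end_i <= 0) next
    k <- ceiling(end_i / gap[i] * 3) + 10
    tt <- cumsum(c(runif(1, 0, gap[i]),
                   rgamma(k, shape = cfg$visit_shape,
                          scale = gap[i] / cfg$visit_shape)))
    visits[[i]] <- tt[tt <= end_i]
  }
  nv <- lengths(visits)
  meas <- data.table(person_id = rep(ids, nv), time = unlist(visits))

  set.seed(cfg$seed + 5) # AKI excursions
  aki_counts <- rpois(n, cfg$aki_rate * span_years)
  aki <- data.table(
    person_id = rep(ids, aki_counts),
    onset = runif(sum(aki_counts), 0, cfg$admin_end),
    multiplier = runif(sum(aki_counts), cfg$aki_mult_range[1],
                       cfg$aki_mult_range[2]),
    duration = runif(sum(aki_counts), cfg$aki_duration_range[1],
                     cfg$aki_duration_range[2])
  )
  aki[, end := onset + duration]
  setorder(aki, person_id, onset)

  set.seed(cfg$seed + 4) # measurement noise + setting
  idx <- rep(seq_len(n), nv)
  true_egfr <- pmax(baseline[idx] + slope[idx] * meas$time / DAYS_PER_YEAR,
                    cfg$egfr_floor)
  age_at <- (meas$time - birth_time[idx]) / DAYS_PER_YEAR
  creat <- invert_ckdepi(true_egfr, age_at, sex[idx], "2009")
  if (nrow(aki)) {
    meas[, creatinine_umol_l := creat]
    meas[aki, creatinine_umol_l := creatinine_umol_l * i.multiplier,
         on = .(person_id, time >= onset, time <= end)]
    creat <- meas$creatinine_umol_l
  }
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    creat <- creat * rlnorm(length(creat), meanlog = -sdlog^2 / 2,
                            sdlog = sdlog)
  }
  meas[, creatinine_umol_l := creat]
  meas[, setting := sample(c("inpatient", "primary", "outpatient"),
                           .N, replace = TRUE,
                           prob = c(cfg$p_inpatient,
                                    (1 - cfg$p_inpatient) * 0.6,
                                    (1 - cfg$p_inpatient) * 0.4))]
  setorder(meas, person_id, time)

  censor <- function(x, lim) ifelse(x <= lim, x, NA_real_)
  persons <- data.table(
    person_id = ids, sex = sex, birth_time = birth_time,
    diabetes = diabetes, hypertension = hypertension, cvd = cvd,
    uacr_mg_g = uacr,
    death_time = censor(death_time, cfg$admin_end),
    emigration_time = censor(emigration_time, cfg$admin_end),
    krt_time = krt_time
  )
  persons <- merge(persons, first_adm, by = "person_id", all.x = TRUE)
  ground_truth <- data.table(
    person_id = ids, baseline_egfr = baseline, slope = slope,
    progressor = progressor, death_time = death_time,
    emigration_time = emigration_time, krt_time = krt_time
  )
  list(persons = persons[], measurements = meas[],
       admissions = admissions[], ground_truth = ground_truth[],
       aki = aki[, .(person_id, onset, end, multiplier)], config = cfg)
}

#' Closed-form cumulative incidence under constant competing hazards
#'
#' For constant cause-specific hazards the cumulative incidence of cause
#' `k` at time `t` is `lambda_k / sum(lambda) * (1 - exp(-sum(lambda) t))`.
#' Serves as the independent oracle for the Aalen-Johansen estimator.
#'
#' @param lambdas Vector of constant cause-specific hazards (per year).
#' @param cause Index of the cause of interest.
#' @param horizon_years Horizon in years.
#' @return Probability.
#' @export
true_cif <- function(lambdas, cause, horizon_years) {
  if (any(lambdas < 0) || length(lambdas) < 1)
    ckd_config_error("hazards must be non-negative")
  if (cause < 1 || cause > length(lambdas))
    ckd_config_error("unknown cause")
  tot <- sum(lambdas)
  if (tot == 0) return(0)
  lambdas[cause] / tot * (1 - exp(-tot * horizon_years))
}

#' Simulate a constant-hazard competing-risks cohort
#'
#' Latent cause-specific exponential event times with administrative
#' censoring; the sampling counterpart of [true_cif()] used in
#' parameter-recovery tests.
#'
#' @param n Number of subjects.
#' @param lambdas Constant cause-specific hazards per year.
#' @param admin_years Administrative censoring time in years.
#' @return data.table `time` (years), `code` (0 censored, else cause).
#' @export
simulate_constant_hazard_cohort <- function(n, lambdas, admin_years = 3) {
  tot <- sum(lambdas)
  t_event <- rexp(n, tot)
  cause <- sample.int(length(lambdas), n, replace = TRUE,
                      prob = lambdas / tot)
  data.table(time = pmin(t_event, admin_years),
             code = ifelse(t_event <= admin_years, cause, 0L))
}
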