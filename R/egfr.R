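# CKD-EPI creatinine equations and KDIGO staging.
#
# Creatinine is carried in umol/L throughout the package (Scandinavian
# laboratory convention); the equations are defined on mg/dL, so values are
# divided by 88.42 before evaluation. eGFR is carried at full floating
# precision -- no rounding before any threshold comparison.

UMOL_PER_MGDL <- 88.42

.ckdepi <- list(
  "2009" = list(
    intercept = 141, age_base = 0.993, max_exp = -1.209,
    female = list(kappa = 0.7, alpha = -0.329, sex_mult = 1.018),
    male   = list(kappa = 0.9, alpha = -0.411, sex_mult = 1.000)
  ),
  "2021" = list(
    intercept = 142, age_base = 0.9938, max_exp = -1.200,
    female = list(kappa = 0.7, alpha = -0.241, sex_mult = 1.012),
    male   = list(kappa = 0.9, alpha = -0.302, sex_mult = 1.000)
  )
)

#' Constants of the CKD-EPI creatinine equations
#'
#' Returns the published coefficients used by [egfr_ckdepi_2009()] and
#' [egfr_ckdepi_2021()], for transparency and downstream reuse. The 2009
#' race coefficient is not part of this implementation (Nordic laboratory
#' registries carry no race variable; the race-free convention is used
#' throughout).
#'
#' @param equation `"2009"` or `"2021"`.
#' @return A data.frame with one row per sex: `kappa` (mg/dL), `alpha`,
#'   `max_exp`, `age_base`, `sex_mult`, `intercept`.
#' @export
ckdepi_constants <- function(equation = c("2009", "2021")) {
  equation <- match.arg(equation)
  p <- .ckdepi[[equation]]
  data.frame(
    equation = equation,
    sex = c("female", "male"),
    kappa = c(p$female$kappa, p$male$kappa),
    alpha = c(p$female$alpha, p$male$alpha),
    max_exp = p$max_exp,
    age_base = p$age_base,
    sex_mult = c(p$female$sex_mult, p$male$sex_mult),
    intercept = p$intercept,
    umol_per_mgdl = UMOL_PER_MGDL
  )
}

validate_sex <- function(sex) {
  sex <- as.character(sex)
  if (anyNA(sex) || !all(sex %in% c("female", "male")))
    ckd_invalid_input("sex must be 'female' or 'male' with no missing values")
  sex
}

.egfr_ckdepi <- function(creatinine, age, sex, equation) {
  sex <- validate_sex(sex)
  if (anyNA(creatinine) || any(!is.finite(creatinine)) || any(creatinine <= 0))
    ckd_invalid_input("creatinine must be positive and finite (umol/L)")
  if (anyNA(age) || any(!is.finite(age)) || any(age < 18))
    ckd_invalid_input("age must be finite and >= 18 years")
  p <- .ckdepi[[equation]]
  female <- sex == "female"
  kappa <- ifelse(female, p$female$kappa, p$male$kappa)
  alpha <- ifelse(female, p$female$alpha, p$male$alpha)
  mult <- ifelse(female, p$female$sex_mult, p$male$sex_mult)
  r <- (creatinine / UMOL_PER_MGDL) / kappa
  p$intercept * pmin(r, 1)^alpha * pmax(r, 1)^p$max_exp * p$age_base^age * mult
}

#' Estimated GFR by the 2009 CKD-EPI creatinine equation
#'
#' eGFR = 141 x min(Scr/kappa, 1)^alpha x max(Scr/kappa, 1)^-1.209 x
#' 0.993^age x 1.018 (if female), with Scr in mg/dL, kappa = 0.7 (female) /
#' 0.9 (male) and alpha = -0.329 / -0.411. The race coefficient is not
#' applied.
#'
#' @param creatinine Plasma creatinine in umol/L (positive).
#' @param age Age in years (>= 18).
#' @param sex `"female"` or `"male"` (recycled with the other arguments).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckdepi_2009(88.42, 60, "female")
#' @export
egfr_ckdepi_2009 <- function(creatinine, age, sex) {
  .egfr_ckdepi(creatinine, age, sex, "2009")
}

#' Estimated GFR by the 2021 (race-free) CKD-EPI creatinine equation
#'
#' eGFR = 142 x min(Scr/kappa, 1)^alpha x max(Scr/kappa, 1)^-1.200 x
#' 0.9938^age x 1.012 (if female), kappa as in the 2009 equation,
#' alpha = -0.241 (female) / -0.302 (male).
#'
#' @inheritParams egfr_ckdepi_2009
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi_2021 <- function(creatinine, age, sex) {
  .egfr_ckdepi(creatinine, age, sex, "2021")
}

#' Evaluate an eGFR equation chosen by name
#' @param equation `"2009"` or `"2021"`.
#' @inheritParams egfr_ckdepi_2009
#' @export
egfr_ckdepi <- function(creatinine, age, sex, equation = c("2009", "2021")) {
  equation <- match.arg(equation)
  .egfr_ckdepi(creatinine, age, sex, equation)
}

GFR_STAGE_LEVELS <- c("G1", "G2", "G3a", "G3b", "G4", "G5")

#' KDIGO GFR stage
#'
#' Stages eGFR with left-closed intervals: G1 `[90, Inf)`, G2 `[60, 90)`,
#' G3a `[45, 60)`, G3b `[30, 45)`, G4 `[15, 30)`, G5 `(0, 15)`. The
#' half-open convention reproduces the printed inclusive integer ranges
#' (e.g. "45-59") for integer-reported eGFR.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (positive).
#' @return Factor with levels `G1 > G2 > G3a > G3b > G4 > G5` (mildest
#'   first).
#' @examples
#' gfr_stage(c(59, 45, 44.999, 14.9))
#' @export
gfr_stage <- function(egfr) {
  if (anyNA(egfr) || any(!is.finite(egfr)) || any(egfr <= 0))
    ckd_invalid_input("egfr must be positive and finite")
  idx <- findInterval(egfr, c(15, 30, 45, 60, 90)) # 0..5, 5 = G1
  factor(GFR_STAGE_LEVELS[6L - idx], levels = GFR_STAGE_LEVELS)
}

#' Severity rank of a GFR stage (G1 = 1 ... G5 = 6)
#'
#' Used for "drop in GFR category" comparisons; a strictly larger rank is a
#' strictly worse stage.
#' @param stage Factor or character of GFR stages.
#' @return Integer ranks.
#' @export
gfr_stage_rank <- function(stage) {
  match(as.character(stage), GFR_STAGE_LEVELS)
}

ALBUMINURIA_LEVELS <- c("A1", "A2", "A3", "missing")

#' KDIGO albuminuria stage from uACR
#'
#' A1: uACR < 30 mg/g; A2: 30-300 mg/g (300 inclusive); A3: > 300 mg/g.
#' `NA` maps to the explicit level `"missing"` -- in routine care most
#' persons with new CKD have no uACR measurement and they must remain
#' visible as their own stratum.
#'
#' @param uacr Urine albumin-creatinine ratio in mg/g, `NA` for not
#'   measured.
#' @return Factor with levels `A1, A2, A3, missing`.
#' @examples
#' albuminuria_stage(c(14, 300, 300.1, NA))
#' @export
albuminuria_stage <- function(uacr) {
  if (any(uacr < 0, na.rm = TRUE))
    ckd_invalid_input("uacr must be non-negative")
  out <- rep("missing", length(uacr))
  out[!is.na(uacr) & uacr < 30] <- "A1"
  out[!is.na(uacr) & uacr >= 30 & uacr <= 300] <- "A2"
  out[!is.na(uacr) & uacr > 300] <- "A3"
  factor(out, levels = ALBUMINURIA_LEVELS)
}

#' Invert a CKD-EPI creatinine equation
#'
#' Returns the creatinine (umol/L) whose eGFR equals `target_egfr` for the
#' given age and sex. The equation is a strictly decreasing piecewise power
#' law in creatinine, so the inverse is closed-form on each side of the
#' kappa breakpoint; the branch is chosen by comparing the target with the
#' eGFR at Scr = kappa.
#'
#' @param target_egfr Desired eGFR in mL/min/1.73 m^2 (positive).
#' @param age Age in years (>= 18).
#' @param sex `"female"` or `"male"`.
#' @param equation `"2009"` (default) or `"2021"`.
#' @return Creatinine in umol/L such that the round trip through the
#'   forward equation recovers `target_egfr` to ~1e-12 relative error.
#' @export
invert_ckdepi <- function(target_egfr, age, sex, equation = c("2009", "2021")) {
  equation <- match.arg(equation)
  sex <- validate_sex(sex)
  if (anyNA(target_egfr) || any(!is.finite(target_egfr)) || any(target_egfr <= 0))
    ckd_invalid_input("target_egfr must be positive and finite")
  p <- .ckdepi[[equation]]
  female <- sex == "female"
  kappa <- ifelse(female, p$female$kappa, p$male$kappa)
  alpha <- ifelse(female, p$female$alpha, p$male$alpha)
  mult <- ifelse(female, p$female$sex_mult, p$male$sex_mult)
  g <- p$intercept * p$age_base^age * mult # eGFR at Scr = kappa
  ratio <- target_egfr / g
  # target below the breakpoint value -> Scr > kappa branch (exponent max_exp)
  r <- ifelse(ratio <= 1, ratio^(1 / p$max_exp), ratio^(1 / alpha))
  if (any(!is.finite(r)) || any(r <= 0))
    ckd_stop("no valid inversion branch for the requested eGFR",
             "ckd_inversion_error")
  r * kappa * UMOL_PER_MGDL
}

#' @rdname invert_ckdepi
#' @export
invert_ckdepi_2009 <- function(target_egfr, age, sex) {
  invert_ckdepi(target_egfr, age, sex, "2009")
}
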