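# Stratified risks, the risk-marker heat map and cohort description.

#' Age groups used for stratified risks and cohort description
#'
#' Cuts age in years into `18-49, 50-59, 60-69, 70-79, 80-89, 90+`.
#' @param age Age in years.
#' @return Factor of age groups.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(18, 50, 60, 70, 80, 90, Inf),
      labels = c("18-49", "50-59", "60-69", "70-79", "80-89", "90+"),
      right = FALSE, include.lowest = TRUE)
}

#' Aalen-Johansen curves per stratum
#'
#' Partitions subjects by a stratum label and estimates one risk curve per
#' non-empty stratum. Empty strata are flagged with a warning and omitted.
#'
#' @param time,code Outcome data as in [aalen_johansen()].
#' @param strata Factor/character stratum label per subject.
#' @param conf_level Confidence level.
#' @return Named list of `risk_curve` objects.
#' @export
stratified_risks <- function(time, code, strata, conf_level = 0.95) {
  strata <- as.factor(strata)
  out <- list()
  for (lev in levels(strata)) {
    sel <- !is.na(strata) & strata == lev
    if (!any(sel)) {
      warning(sprintf("stratum '%s' is empty; curve omitted", lev),
              call. = FALSE)
      next
    }
    out[[lev]] <- aalen_johansen(time[sel], code[sel], conf_level)
  }
  out
}

#' Risk-marker heat map table
#'
#' Estimates the risk of an outcome (by default confirmed rapid
#' progression) at each horizon within every combination of sex x
#' albuminuria stage x diabetes x hypertension/CVD. Persons with missing
#' albuminuria form their own explicit stratum (level `"missing"`) rather
#' than being dropped. Cells with no persons are flagged `empty`; cells
#' with persons but no events by the horizon report risk 0 with the exact
#' one-sided binomial upper bound `1 - (alpha/2)^(1/n)` so that small
#' cells are not displayed with a misleading zero-width interval.
#'
#' @param outcomes data.table with `person_id`, `time`, `code` for one
#'   outcome (see [assemble_outcomes()]).
#' @param persons data.table with `person_id`, `sex`, `diabetes`,
#'   `hypertension`, `cvd`, `uacr_mg_g`.
#' @param horizons Horizons in days, default 1 and 3 years.
#' @param conf_level Confidence level.
#' @return data.table: `sex`, `albuminuria`, `diabetes`, `htn_or_cvd`,
#'   `horizon_days`, `n`, `risk`, `ci_lower`, `ci_upper`, `empty`.
#' @export
heatmap_table <- function(outcomes, persons, horizons = c(365L, 1095L),
                          conf_level = 0.95) {
  p <- as.data.table(persons)
  p[, albuminuria := albuminuria_stage(uacr_mg_g)]
  p[, htn_or_cvd := hypertension | cvd]
  x <- merge(as.data.table(outcomes), p, by = "person_id")
  grid <- CJ(sex = c("female", "male"), albuminuria = ALBUMINURIA_LEVELS,
             diabetes = c(FALSE, TRUE), htn_or_cvd = c(FALSE, TRUE),
             horizon_days = as.numeric(horizons))
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i]
    sub <- x[sex == g$sex & albuminuria == g$albuminuria &
               diabetes == g$diabetes & htn_or_cvd == g$htn_or_cvd]
    if (nrow(sub) == 0L)
      return(data.table(g, n = 0L, risk = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, empty = TRUE))
    curve <- aalen_johansen(sub$time, sub$code, conf_level)
    r <- suppressWarnings(risk_at(curve, g$horizon_days))
    # a cell with no events by the horizon still carries information: report
    # the exact one-sided upper bound (Clopper-Pearson with zero events,
    # the "rule of three") instead of a degenerate zero-width interval
    up <- if (r$risk == 0) 1 - ((1 - conf_level) / 2)^(1 / nrow(sub))
          else r$ci_upper
    data.table(g, n = nrow(sub), risk = r$risk, ci_lower = r$ci_lower,
               ci_upper = up, empty = FALSE)
  })
  rbindlist(cells)
}

#' Plot a 3-year (or 1-year) risk heat map
#'
#' Base-graphics rendering of a [heatmap_table()] at one horizon: rows are
#' sex x albuminuria stage, columns diabetes x hypertension/CVD, cells
#' colored by risk and annotated with the risk and its CI.
#'
#' @param cells Output of [heatmap_table()].
#' @param horizon Horizon (days) to display, default 1095.
#' @param main Plot title.
#' @export
plot_risk_heatmap <- function(cells, horizon = 1095,
                              main = sprintf("%g-year risk of rapid progression",
                                             horizon / 365)) {
  x <- as.data.table(cells)[horizon_days == horizon & albuminuria != "missing"]
  rows <- CJ(sex = c("female", "male"), albuminuria = c("A1", "A2", "A3"))
  cols <- CJ(diabetes = c(FALSE, TRUE), htn_or_cvd = c(FALSE, TRUE))
  nr <- nrow(rows); nc <- nrow(cols)
  pal <- grDevices::colorRampPalette(c("#fff5eb", "#d94801"))(101)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, nc), ylim = c(0, nr))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cell <- x[sex == rows$sex[i] & albuminuria == rows$albuminuria[i] &
                diabetes == cols$diabetes[j] & htn_or_cvd == cols$htn_or_cvd[j]]
    risk <- if (nrow(cell)) cell$risk[1] else NA_real_
    col <- if (is.na(risk)) "grey90" else pal[round(100 * min(risk, 1)) + 1]
    graphics::rect(j - 1, nr - i, j, nr - i + 1, col = col, border = "white")
    lab <- if (is.na(risk)) "n/a" else
      sprintf("%.0f%%\n(%.0f-%.0f)", 100 * risk, 100 * cell$ci_lower[1],
              100 * cell$ci_upper[1])
    graphics::text(j - 0.5, nr - i + 0.5, lab, cex = 0.7)
  }
  graphics::axis(2, at = seq_len(nr) - 0.5,
                 labels = rev(paste(rows$sex, rows$albuminuria)), las = 1,
                 tick = FALSE)
  graphics::axis(3, at = seq_len(nc) - 0.5,
                 labels = paste0("DM:", ifelse(cols$diabetes, "+", "-"),
                                 " HTN/CVD:", ifelse(cols$htn_or_cvd, "+", "-")),
                 tick = FALSE, cex.axis = 0.8)
  graphics::title(main = main, line = 2.5)
  invisible(x)
}

.median_q <- function(x) {
  if (sum(!is.na(x)) == 0) return(NA_character_)
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

#' Cohort description table
#'
#' Counts and percentages for the categorical characteristics (sex, age
#' group, substage, comorbidities, albuminuria stage) and median (Q1-Q3)
#' for continuous ones (age, inclusion eGFR, uACR, eGFR testing frequency
#' in the year before inclusion when measurements are supplied).
#' Percentages for a categorical variable are over its non-missing
#' denominator and sum to 100.
#'
#' @param cohort data.table with `person_id`, `index_time`,
#'   `inclusion_egfr`, `substage`, `age_at_index`.
#' @param persons Person table (sex, comorbidity flags, `uacr_mg_g`).
#' @param measurements Optional measurement table for testing frequency.
#' @return data.table `variable`, `level`, `n`, `pct`, `summary`.
#' @export
cohort_summary <- function(cohort, persons, measurements = NULL) {
  x <- merge(as.data.table(cohort), as.data.table(persons), by = "person_id")
  n <- nrow(x)
  cat_row <- function(variable, values) {
    values <- as.factor(values)
    tab <- table(values)
    data.table(variable = variable, level = names(tab), n = as.integer(tab),
               pct = 100 * as.integer(tab) / sum(tab), summary = NA_character_)
  }
  num_row <- function(variable, v)
    data.table(variable = variable, level = NA_character_,
               n = sum(!is.na(v)), pct = NA_real_, summary = .median_q(v))
  out <- list(
    data.table(variable = "cohort size", level = NA, n = n, pct = NA_real_,
               summary = NA_character_),
    cat_row("sex", x$sex),
    num_row("age at inclusion (years)", x$age_at_index),
    cat_row("age group", age_group(x$age_at_index)),
    cat_row("CKD substage", x$substage),
    cat_row("diabetes", ifelse(x$diabetes, "yes", "no")),
    cat_row("hypertension", ifelse(x$hypertension, "yes", "no")),
    cat_row("CVD", ifelse(x$cvd, "yes", "no")),
    cat_row("albuminuria stage", albuminuria_stage(x$uacr_mg_g)),
    num_row("inclusion eGFR (mL/min/1.73m2)", x$inclusion_egfr),
    num_row("uACR (mg/g), measured only", x$uacr_mg_g[!is.na(x$uacr_mg_g)])
  )
  if (!is.null(measurements)) {
    m <- as.data.table(measurements)
    freq <- m[x, on = "person_id",
              .(k = sum(time > index_time - DAYS_PER_YEAR & time <= index_time)),
              by = .EACHI]$k
    out <- c(out, list(num_row("eGFR tests in prior year", freq)))
  }
  rbindlist(out)
}
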