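# Aalen-Johansen estimation of cause-specific cumulative incidence.
#
# Right-censored competing-risks data arrive as (time, code) pairs with
# code 0 = censored and codes 1, 2, ... the competing causes. At each
# distinct event time t with risk set n(t) and d_k(t) events of cause k:
#
#   S(t)     = prod_{s<=t} (1 - sum_k d_k(s) / n(s))     (all-cause KM)
#   CIF_k(t) = sum_{s<=t} S(s-) d_k(s) / n(s)
#
# Ties between events and censorings are events-first (censored subjects
# remain in the risk set at their own time); ties between causes enter the
# hazard denominator jointly. The variance is Aalen's counting-process
# estimator (Aalen 1978, in the Marubini-Valsecchi form), computed in O(J)
# via cumulative sums; confidence intervals use the log(-log) transform so
# bounds stay inside [0, 1].

#' Aalen-Johansen estimator of cumulative incidence
#'
#' @param time Event/censoring times (days, >= 0).
#' @param code Integer codes: 0 censored, 1, 2, ... event causes.
#' @param conf_level Confidence level for pointwise intervals
#'   (default 0.95).
#' @return Object of class `risk_curve`: list with `times` (distinct event
#'   times), `n_risk`, `surv` (all-cause survival), and per cause matrices
#'   `cif`, `se`, `ci_lower`, `ci_upper` (columns named `cause1`, ...),
#'   plus `causes`, `n` (subjects) and `max_followup`.
#' @examples
#' aalen_johansen(c(1, 2), c(1, 0))  # CIF1(1) = 0.5
#' @export
aalen_johansen <- function(time, code, conf_level = 0.95) {
  if (length(time) != length(code))
    ckd_invalid_input("time and code lengths differ")
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0))
    ckd_invalid_input("times must be finite and non-negative")
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L))
    ckd_invalid_input("codes must be non-negative integers (0 = censored)")
  n <- length(time)
  causes <- sort(unique(code[code > 0L]))
  ut <- sort(unique(time[code > 0L]))
  J <- length(ut)
  K <- length(causes)
  empty <- matrix(numeric(0), nrow = J, ncol = 0)
  if (J == 0L) {
    out <- list(times = numeric(0), n_risk = integer(0), surv = numeric(0),
                cif = empty, se = empty, ci_lower = empty, ci_upper = empty,
                causes = causes, n = n, conf_level = conf_level,
                max_followup = if (n) max(time) else 0)
    class(out) <- "risk_curve"
    return(out)
  }
  # risk set just before each event time; events-first tie convention means
  # everyone with observed time >= t is at risk at t
  st <- sort(time)
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  d <- matrix(0, nrow = J, ncol = K, dimnames = list(NULL, paste0("cause", causes)))
  for (k in seq_len(K))
    d[, k] <- tabulate(match(time[code == causes[k]], ut), nbins = J)
  d_tot <- rowSums(d)
  surv <- cumprod(1 - d_tot / n_risk)
  s_prev <- c(1, surv[-J])
  cif <- apply(d / n_risk * s_prev, 2, cumsum)
  cif <- matrix(cif, nrow = J, ncol = K, dimnames = dimnames(d))

  # Aalen-type variance via cumulative sums:
  # Var(F_k(t_j)) = sum_{i<=j} (F_j - F_i)^2 a_i
  #              + sum_{i<=j} S_{i-1}^2 d_ki (n_i - d_ki) / n_i^3
  #              - 2 sum_{i<=j} (F_j - F_i) b_i
  # with a_i = d_i / (n_i (n_i - d_i)), b_i = S_{i-1} d_ki / n_i^2.
  a <- ifelse(n_risk > d_tot, d_tot / (n_risk * (n_risk - d_tot)), 0)
  se <- ci_lo <- ci_hi <- matrix(0, nrow = J, ncol = K, dimnames = dimnames(d))
  z <- qnorm(1 - (1 - conf_level) / 2)
  for (k in seq_len(K)) {
    Fk <- cif[, k]
    b <- s_prev * d[, k] / n_risk^2
    c2 <- s_prev^2 * d[, k] * (n_risk - d[, k]) / n_risk^3
    v <- Fk^2 * cumsum(a) - 2 * Fk * cumsum(Fk * a) + cumsum(Fk^2 * a) +
      cumsum(c2) - 2 * Fk * cumsum(b) + 2 * cumsum(Fk * b)
    v <- pmax(v, 0)
    se[, k] <- sqrt(v)
    pos <- Fk > 0 & Fk < 1
    se_theta <- ifelse(pos, se[, k] / (Fk * abs(log(Fk))), 0)
    ci_lo[, k] <- ifelse(pos, Fk^exp(z * se_theta), Fk)
    ci_hi[, k] <- ifelse(pos, Fk^exp(-z * se_theta), Fk)
  }
  out <- list(times = ut, n_risk = n_risk, surv = surv, cif = cif, se = se,
              ci_lower = ci_lo, ci_upper = ci_hi, causes = causes, n = n,
              conf_level = conf_level, max_followup = max(time))
  class(out) <- "risk_curve"
  out
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("Aalen-Johansen risk curve: %d subjects, %d event times, causes: %s\n",
              x$n, length(x$times),
              if (length(x$causes)) paste(x$causes, collapse = ", ") else "none"))
  for (k in seq_along(x$causes)) {
    j <- length(x$times)
    cat(sprintf("  CIF cause %d at last event time (day %g): %.4f (%.0f%% CI %.4f-%.4f)\n",
                x$causes[k], x$times[j], x$cif[j, k],
                100 * x$conf_level, x$ci_lower[j, k], x$ci_upper[j, k]))
  }
  invisible(x)
}

#' Convert a risk curve to a data.table
#' @param curve A `risk_curve`.
#' @return data.table in long format: `time`, `cause`, `cif`, `se`,
#'   `ci_lower`, `ci_upper`, `surv`, `n_risk`.
#' @export
risk_curve_table <- function(curve) {
  if (length(curve$times) == 0L)
    return(data.table(time = numeric(0), cause = integer(0), cif = numeric(0),
                      se = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0), surv = numeric(0),
                      n_risk = numeric(0)))
  rbindlist(lapply(seq_along(curve$causes), function(k)
    data.table(time = curve$times, cause = curve$causes[k],
               cif = curve$cif[, k], se = curve$se[, k],
               ci_lower = curve$ci_lower[, k], ci_upper = curve$ci_upper[, k],
               surv = curve$surv, n_risk = curve$n_risk)))
}

#' Evaluate a risk curve at a horizon
#'
#' Step-function (right-continuous) evaluation: the value at the largest
#' event time <= `horizon`, 0 before the first event. A horizon beyond the
#' last observed follow-up returns the last value with `truncated = TRUE`
#' and a warning.
#'
#' @param curve A `risk_curve`.
#' @param horizon Horizon in days (>= 0).
#' @param cause Cause of interest (default 1).
#' @return List `risk`, `se`, `ci_lower`, `ci_upper`, `truncated`.
#' @export
risk_at <- function(curve, horizon, cause = 1L) {
  if (horizon < 0) ckd_invalid_input("horizon must be >= 0")
  truncated <- horizon > curve$max_followup
  if (truncated)
    warning("horizon beyond last follow-up; returning last value",
            call. = FALSE)
  k <- match(cause, curve$causes)
  if (is.na(k) || length(curve$times) == 0L)
    return(list(risk = 0, se = 0, ci_lower = 0, ci_upper = 0,
                truncated = truncated))
  j <- findInterval(horizon, curve$times)
  if (j == 0L)
    return(list(risk = 0, se = 0, ci_lower = 0, ci_upper = 0,
                truncated = truncated))
  list(risk = unname(curve$cif[j, k]), se = unname(curve$se[j, k]),
       ci_lower = unname(curve$ci_lower[j, k]),
       ci_upper = unname(curve$ci_upper[j, k]), truncated = truncated)
}
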