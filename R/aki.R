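# KDIGO acute kidney injury detection on creatinine time series.
#
# A creatinine measurement marks AKI onset when it rises >= 26.5 umol/L
# above some earlier measurement taken within the preceding 48 h, or when it
# is >= 1.5x the baseline, baseline being the minimum creatinine over the
# preceding 7 days. Measurements falling inside an AKI episode are excluded
# from all chronic-disease phenotyping downstream.
#
# Episode extent is not defined by the KDIGO onset criteria; here an episode
# runs from its onset until the first subsequent measurement below 1.25x the
# pre-onset baseline, capped at 90 days, and overlapping episodes are
# merged. Time is in days; the 48 h window is 2 days, closed on the left
# comparison (a measurement exactly 48 h earlier counts).

#' Detect KDIGO AKI onsets in one person's creatinine series
#'
#' @param time Measurement times in days, sorted increasing.
#' @param creatinine Plasma creatinine in umol/L, same length as `time`.
#' @param abs_increase Absolute criterion in umol/L (default 26.5).
#' @param abs_window_days Window for the absolute criterion (default 2 days
#'   = 48 h).
#' @param rel_ratio Relative criterion vs. baseline (default 1.5).
#' @param baseline_window_days Lookback defining baseline as the minimum
#'   creatinine over the preceding window (default 7 days).
#' @return Numeric vector of onset times (possibly empty).
#' @examples
#' detect_aki_onsets(c(0, 1), c(80, 110)) # delta 30 >= 26.5 within 48 h
#' @export
detect_aki_onsets <- function(time, creatinine,
                              abs_increase = 26.5, abs_window_days = 2,
                              rel_ratio = 1.5, baseline_window_days = 7) {
  assert_sorted(time, "creatinine series")
  n <- length(time)
  if (length(creatinine) != n)
    ckd_invalid_input("time and creatinine lengths differ")
  if (n < 2L) return(numeric(0))
  onset <- logical(n)
  # first index inside each lookback window (windows are [t_i - w, t_i))
  lo_abs <- findInterval(time - abs_window_days, time, left.open = TRUE) + 1L
  lo_base <- findInterval(time - baseline_window_days, time,
                          left.open = TRUE) + 1L
  for (i in 2:n) {
    hi <- i - 1L
    while (hi >= 1L && time[hi] >= time[i]) hi <- hi - 1L # ties: need dt > 0
    if (hi < 1L) next
    if (lo_abs[i] <= hi &&
        creatinine[i] - min(creatinine[lo_abs[i]:hi]) >= abs_increase) {
      onset[i] <- TRUE
      next
    }
    if (lo_base[i] <= hi &&
        creatinine[i] >= rel_ratio * min(creatinine[lo_base[i]:hi]))
      onset[i] <- TRUE
  }
  time[onset]
}

#' Build AKI episodes from detected onsets
#'
#' Each episode starts at an onset and resolves at the first later
#' measurement below `resolution_ratio` times the pre-onset baseline (the
#' minimum creatinine in the 7 days before onset, falling back to the last
#' prior value), or `cap_days` after onset if no such recovery is observed
#' first. Overlapping or touching episodes are merged.
#'
#' @inheritParams detect_aki_onsets
#' @param onsets Onset times as returned by [detect_aki_onsets()].
#' @param resolution_ratio Recovery threshold relative to baseline
#'   (default 1.25).
#' @param cap_days Maximum episode length without recovery (default 90).
#' @param baseline_window_days Baseline lookback before onset (default 7).
#' @return data.table with columns `onset_time`, `resolution_time`.
#' @export
build_episodes <- function(time, creatinine, onsets,
                           resolution_ratio = 1.25, cap_days = 90,
                           baseline_window_days = 7) {
  assert_sorted(time, "creatinine series")
  if (length(onsets) == 0L)
    return(data.table(onset_time = numeric(0), resolution_time = numeric(0)))
  if (!all(onsets %in% time))
    ckd_contract_violation("onsets must be a subset of measurement times")
  res <- vapply(onsets, function(o) {
    before <- which(time < o)
    if (length(before) == 0L) return(o + cap_days)
    in_win <- before[o - time[before] <= baseline_window_days]
    base <- if (length(in_win)) min(creatinine[in_win])
            else creatinine[max(before)]
    after <- which(time > o & creatinine < resolution_ratio * base)
    first_rec <- if (length(after)) time[min(after)] else Inf
    min(first_rec, o + cap_days)
  }, numeric(1))
  ep <- data.table(onset_time = onsets, resolution_time = res)
  setorder(ep, onset_time)
  merge_episodes(ep)
}

# merge intervals that overlap or touch (closed intervals)
merge_episodes <- function(ep) {
  if (nrow(ep) <= 1L) return(ep)
  on <- ep$onset_time
  off <- ep$resolution_time
  keep_on <- on[1]
  keep_off <- off[1]
  out_on <- numeric(0)
  out_off <- numeric(0)
  for (i in 2:nrow(ep)) {
    if (on[i] <= keep_off) {
      keep_off <- max(keep_off, off[i])
    } else {
      out_on <- c(out_on, keep_on)
      out_off <- c(out_off, keep_off)
      keep_on <- on[i]
      keep_off <- off[i]
    }
  }
  data.table(onset_time = c(out_on, keep_on),
             resolution_time = c(out_off, keep_off))
}

#' Flag measurements falling inside AKI episodes
#'
#' A measurement is flagged iff its time lies in the closed interval
#' `[onset_time, resolution_time]` of any episode. Flagging is idempotent
#' and monotone in the episode set.
#'
#' @inheritParams detect_aki_onsets
#' @param episodes data.table from [build_episodes()].
#' @return Logical vector, `TRUE` = excluded for AKI.
#' @export
flag_excluded <- function(time, episodes) {
  if (nrow(episodes) == 0L) return(rep(FALSE, length(time)))
  flagged <- rep(FALSE, length(time))
  for (i in seq_len(nrow(episodes)))
    flagged <- flagged |
      (time >= episodes$onset_time[i] & time <= episodes$resolution_time[i])
  flagged
}

#' Run the AKI filter over a long-format measurement table
#'
#' Convenience wrapper applying onset detection, episode construction and
#' flagging per person. Adds/overwrites the logical column
#' `excluded_for_aki`.
#'
#' @param measurements data.table with `person_id`, `time`,
#'   `creatinine_umol_l`, sorted by person and time.
#' @return List with `measurements` (copy, flag column added) and
#'   `episodes` (data.table `person_id`, `onset_time`, `resolution_time`).
#' @export
aki_filter <- function(measurements) {
  m <- as.data.table(measurements)
  setorder(m, person_id, time)
  eps <- m[, {
    ons <- detect_aki_onsets(time, creatinine_umol_l)
    build_episodes(time, creatinine_umol_l, ons)
  }, by = person_id]
  m[, excluded_for_aki := FALSE]
  if (nrow(eps)) {
    m[eps, excluded_for_aki := TRUE,
      on = .(person_id, time >= onset_time, time <= resolution_time)]
  }
  list(measurements = m[], episodes = eps[])
}
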