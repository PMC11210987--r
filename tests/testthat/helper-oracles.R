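# Independent oracles and frozen expected values.
#
# The eGFR grid below was hand-evaluated OUTSIDE this package (plain
# transcription of the published CKD-EPI formulas in a separate scripting
# language) before the R implementation was written, and frozen here.

ckdepi_oracle_grid <- function() {
  txt <- "creatinine age sex egfr2009 egfr2021
40 30 female 134.22053992668785 132.4736407000026
40 30 male 151.52205169876822 145.0358923458531
40 60 female 108.71674382707425 109.92570110805188
40 60 male 122.7307242817332 120.34976971799588
40 80 female 94.46727900012198 97.0686729750312
40 80 male 106.64445203630369 106.27353131815279
61.894 30 female 116.26375504057825 119.2445747588726
61.894 30 male 126.63534691649726 127.12171591498485
61.894 60 female 94.17200139430383 98.94831465668567
61.894 60 male 102.57284449677634 105.4847113295425
61.894 80 female 81.82891076894191 87.37521343984197
61.894 80 male 89.12865836311043 93.14710613351657
70 30 female 100.18989300115382 102.87248761164767
70 30 male 120.38911012089167 122.48361638598561
70 60 female 81.15239990405253 85.36287117713019
70 60 male 97.51348081099465 101.63604875908628
70 80 female 70.51578380106376 75.3787380292235
70 80 male 84.73242367061405 89.74858727325802
88.42 30 female 75.53841638783041 77.72420296357097
88.42 30 male 100.54853827709209 103.83628170555637
88.42 60 female 61.18505161746657 64.4950003539451
88.42 60 male 81.44289751798158 86.16262077966914
88.42 80 female 53.16554873072515 56.951595803131525
88.42 80 male 70.76820599637487 76.08494805880026
100 30 female 65.09497179694472 67.05279567362632
100 30 male 86.6473587395167 89.57972826012868
100 60 female 52.72600882953177 55.63994117418543
100 60 male 70.1831382031537 74.33263237901802
100 80 female 45.81522966310419 49.13223386110723
100 80 male 60.984259317839665 65.63860781456141
130 30 female 47.40126482174784 48.94235548206561
130 30 male 63.095417116527436 65.38493824827196
130 60 female 38.39435579323433 40.61202448892509
130 60 male 51.10639774707084 54.255964740371425
130 80 female 33.36202127722451 35.86199846107392
130 80 male 44.407900427398886 47.910128798279466
200 30 female 28.158024237065955 29.186424522127652
200 30 male 37.48090459391787 38.99184144838438
200 60 female 22.807602393267995 24.21869106547517
200 60 male 30.35900395997263 32.35515749441893
200 80 female 19.818218084564577 21.3860469318919
200 80 male 26.37986014200627 28.570863503469905
400 30 female 12.180269950933564 12.70412915416902
400 30 male 16.213052880256893 16.97218476842209
400 60 female 9.865846827345065 10.54179757467211
400 60 male 13.132344107693635 14.083400291150605
400 80 female 8.57273380348588 9.308817601617921
400 80 male 11.41109245067507 12.4361906584012"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# O(n^2) pairwise AKI onset oracle: explicit double loop, no shortcuts
oracle_aki_onsets <- function(time, creat) {
  onsets <- numeric(0)
  n <- length(time)
  for (i in seq_len(n)) {
    is_onset <- FALSE
    base <- Inf
    for (j in seq_len(n)) {
      if (time[j] >= time[i]) next
      dt <- time[i] - time[j]
      if (dt <= 2 && creat[i] - creat[j] >= 26.5) is_onset <- TRUE
      if (dt <= 7) base <- min(base, creat[j])
    }
    if (!is_onset && is.finite(base) && creat[i] >= 1.5 * base)
      is_onset <- TRUE
    if (is_onset) onsets <- c(onsets, time[i])
  }
  onsets
}

# brute-force all-pairs incident CKD oracle
oracle_find_incident <- function(time, egfr, start, end, krt = NA) {
  best_t <- Inf; best_e <- NA
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[j] - time[i] < 90) next
    if (egfr[i] < 30 || egfr[i] >= 60) next
    if (egfr[j] < 30 || egfr[j] >= 60) next
    if (time[j] < best_t) { best_t <- time[j]; best_e <- egfr[j] }
  }
  if (!is.finite(best_t)) return(NULL)
  if (best_t < start || best_t > end) return(NULL)
  if (!is.na(krt) && krt < best_t) return(NULL)
  list(index_time = best_t, inclusion_egfr = best_e)
}

oracle_substage <- function(time, egfr, index_time) {
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] > index_time || time[j] > index_time) next
    if (time[j] - time[i] < 90) next
    if (egfr[i] >= 30 && egfr[i] < 45 && egfr[j] >= 30 && egfr[j] < 45)
      return("G3b")
  }
  "G3a"
}

oracle_category_drop <- function(time, egfr, index_time, incl) {
  sev <- function(e) {
    if (e >= 90) 1 else if (e >= 60) 2 else if (e >= 45) 3
    else if (e >= 30) 4 else if (e >= 15) 5 else 6
  }
  for (i in seq_along(time)) {
    if (time[i] <= index_time) next
    if (egfr[i] <= 0.75 * incl && sev(egfr[i]) > sev(incl))
      return(time[i])
  }
  NULL
}

oracle_kidney_failure <- function(time, egfr, krt = NA) {
  best <- if (is.na(krt)) Inf else krt
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[j] - time[i] < 90) next
    if (egfr[i] < 15 && egfr[j] < 15) best <- min(best, time[j])
  }
  if (is.finite(best)) best else NULL
}

# enumeration oracle for outcome coding (events-first tie convention)
oracle_outcome_code <- function(event, death, emig, admin_end, index) {
  cens <- min(c(emig, admin_end), na.rm = TRUE)
  dth <- if (!is.na(death) && death <= cens) death else Inf
  evt <- if (!is.na(event)) event else Inf
  if (evt <= cens && evt <= dth) list(time = evt - index, code = 1L)
  else if (is.finite(dth)) list(time = dth - index, code = 2L)
  else list(time = cens - index, code = 0L)
}

# random short series generators for fuzzing
fuzz_creatinine_series <- function(n_max = 12) {
  n <- sample(2:n_max, 1)
  time <- sort(sample(0:400, n) + round(runif(n), 2))
  creat <- round(runif(n, 40, 250), 1)
  list(time = time, creat = creat)
}

fuzz_egfr_series <- function(n_max = 12, lo = 10, hi = 95) {
  n <- sample(2:n_max, 1)
  time <- sort(sample(0:1500, n))
  egfr <- round(runif(n, lo, hi), 1)
  list(time = time, egfr = egfr)
}

# hand-tabulated 8-subject Aalen-Johansen walk (risk-set table done on
# paper): subjects (1,c1) (1,c2) (2,c1) (3,cens) (4,c2) (5,c1) (6,cens)
# (7,c1)
aj_hand_data <- function() {
  list(time = c(1, 1, 2, 3, 4, 5, 6, 7),
       code = c(1L, 2L, 1L, 0L, 2L, 1L, 0L, 1L),
       times = c(1, 2, 4, 5, 7),
       cif1 = c(0.125, 0.25, 0.25, 0.40625, 0.71875),
       cif2 = c(0.125, 0.125, 0.28125, 0.28125, 0.28125),
       surv = c(0.75, 0.625, 0.46875, 0.3125, 0))
}
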