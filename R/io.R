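# Delimited-text interchange. Registry extracts are tabular; all artifacts
# are TSV with explicit headers, times as numeric days since the epoch.

MEASUREMENT_COLS <- c("person_id", "time", "creatinine_umol_l")
PERSON_COLS <- c("person_id", "sex", "birth_time", "diabetes", "hypertension",
                 "cvd", "uacr_mg_g", "death_time", "emigration_time",
                 "krt_time", "first_admission_time")

#' Read a long-format creatinine measurement table
#'
#' Expects columns `person_id`, `time` (days), `creatinine_umol_l` and
#' optionally `setting` (defaults to `"primary"`). Rows with non-numeric
#' time/creatinine are dropped with a warning naming the offending line
#' numbers, creatinine outside the plausibility range 10-2000 umol/L is
#' dropped with a warning, and exact duplicate rows are deduplicated with
#' a warning. The result is sorted by person and time.
#'
#' @param path Path to a delimited text file (any separator fread
#'   understands).
#' @return data.table `person_id`, `time`, `creatinine_umol_l`, `setting`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) ckd_data_error(sprintf("no such file: %s", path))
  raw <- fread(path, colClasses = "character")
  missing_cols <- setdiff(MEASUREMENT_COLS, names(raw))
  if (length(missing_cols))
    ckd_data_error(sprintf("missing column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  if (!"setting" %in% names(raw)) raw[, setting := "primary"]
  t_num <- suppressWarnings(as.numeric(raw$time))
  c_num <- suppressWarnings(as.numeric(raw$creatinine_umol_l))
  bad <- which(is.na(t_num) | is.na(c_num))
  if (length(bad)) {
    warning(sprintf("dropping %d malformed row(s) at line(s): %s",
                    length(bad),
                    paste(head(bad + 1L, 20), collapse = ", ")),
            call. = FALSE)
  }
  m <- data.table(person_id = raw$person_id, time = t_num,
                  creatinine_umol_l = c_num, setting = raw$setting)
  m <- m[!is.na(time) & !is.na(creatinine_umol_l)]
  implaus <- m$creatinine_umol_l < 10 | m$creatinine_umol_l > 2000
  if (any(implaus)) {
    warning(sprintf("dropping %d measurement(s) outside 10-2000 umol/L",
                    sum(implaus)), call. = FALSE)
    m <- m[!implaus]
  }
  ndup <- sum(duplicated(m))
  if (ndup) {
    warning(sprintf("deduplicating %d exact duplicate row(s)", ndup),
            call. = FALSE)
    m <- unique(m)
  }
  setorder(m, person_id, time)
  m[]
}

#' Read a person table
#'
#' Requires the columns `person_id`, `sex`, `birth_time`, `diabetes`,
#' `hypertension`, `cvd`, `uacr_mg_g`, `death_time`, `emigration_time`,
#' `krt_time`, `first_admission_time` (empty fields = `NA`).
#'
#' @param path Path to a delimited text file.
#' @return data.table with typed columns.
#' @export
read_persons <- function(path) {
  if (!file.exists(path)) ckd_data_error(sprintf("no such file: %s", path))
  p <- fread(path)
  missing_cols <- setdiff(PERSON_COLS, names(p))
  if (length(missing_cols))
    ckd_data_error(sprintf("missing column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  validate_sex(p$sex)
  for (col in c("diabetes", "hypertension", "cvd"))
    set(p, j = col, value = as.logical(p[[col]]))
  for (col in c("birth_time", "uacr_mg_g", "death_time", "emigration_time",
                "krt_time", "first_admission_time"))
    set(p, j = col, value = as.numeric(p[[col]]))
  p[]
}

#' Write a table as TSV
#' @param x data.table/data.frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  fwrite(x, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Write simulated registry data to a directory
#'
#' Emits `persons.tsv`, `measurements.tsv`, `admissions.tsv`,
#' `ground_truth.tsv` and `aki_truth.tsv` in the interchange format that
#' [read_measurements()] / [read_persons()] consume.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(sim$persons, file.path(dir, "persons.tsv"))
  write_table(sim$measurements, file.path(dir, "measurements.tsv"))
  write_table(sim$admissions, file.path(dir, "admissions.tsv"))
  write_table(sim$ground_truth, file.path(dir, "ground_truth.tsv"))
  write_table(sim$aki, file.path(dir, "aki_truth.tsv"))
  invisible(dir)
}
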