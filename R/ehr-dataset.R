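#' EHR dataset container
#'
#' Bundles the three long-format tables the pipeline operates on: one row per
#' ICU stay, one row per laboratory measurement, and one row per clinical
#' event (prescription or procedure). All timestamps are hours from the start
#' of the stay, so `intime_h` is 0 and `outtime_h` is the stay duration.
#'
#' @param stays Tibble with columns `patient_id`, `stay_id`, `intime_h`,
#'   `outtime_h`, `age_group`, `race`, `sex`, `died` (0/1).
#' @param labs Tibble with columns `stay_id`, `lab_name`, `time_h`,
#'   `value_raw` (character; may hold textual values such as `"error"`).
#' @param events Tibble with columns `stay_id`, `event_name`, `event_kind`
#'   (`"prescription"` or `"procedure"`), `time_h`.
#'
#' @return An object of class `ehr_dataset`: a named list of the three
#'   tibbles.
#' @export
ehr_dataset <- function(stays, labs, events) {
  stays <- tibble::as_tibble(stays)
  labs <- tibble::as_tibble(labs)
  events <- tibble::as_tibble(events)
  check_columns(stays, STAYS_COLS, "stays")
  check_columns(labs, LABS_COLS, "labs")
  check_columns(events, EVENTS_COLS, "events")
  labs$value_raw <- as.character(labs$value_raw)
  structure(list(stays = stays, labs = labs, events = events),
            class = "ehr_dataset")
}

STAYS_COLS <- c("patient_id", "stay_id", "intime_h", "outtime_h",
                "age_group", "race", "sex", "died")
LABS_COLS <- c("stay_id", "lab_name", "time_h", "value_raw")
EVENTS_COLS <- c("stay_id", "event_name", "event_kind", "time_h")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` table is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' @exportS3Method base::print
print.ehr_dataset <- function(x, ...) {
  cat(sprintf(
    "<ehr_dataset> %d stays (%d died), %d lab events, %d clinical events\n",
    nrow(x$stays), sum(x$stays$died), nrow(x$labs), nrow(x$events)))
  invisible(x)
}

#' Write an EHR dataset to a directory of CSV files
#'
#' Writes `stays.csv`, `labs.csv` and `events.csv`. The round trip through
#' [read_ehr_dataset()] is lossless (doubles are written in shortest
#' round-trippable form).
#'
#' @param dataset An [ehr_dataset()].
#' @param dir Directory to write into; created if absent.
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$stays, file.path(dir, "stays.csv"))
  readr::write_csv(dataset$labs, file.path(dir, "labs.csv"))
  readr::write_csv(dataset$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' Read an EHR dataset from a directory of CSV files
#'
#' @param dir Directory holding `stays.csv`, `labs.csv`, `events.csv`.
#' @return An [ehr_dataset()].
#' @export
read_ehr_dataset <- function(dir) {
  stays <- read_checked(file.path(dir, "stays.csv"), readr::cols(
    patient_id = readr::col_character(), stay_id = readr::col_character(),
    intime_h = readr::col_double(), outtime_h = readr::col_double(),
    age_group = readr::col_character(), race = readr::col_character(),
    sex = readr::col_character(), died = readr::col_integer()),
    STAYS_COLS, "stays")
  labs <- read_checked(file.path(dir, "labs.csv"), readr::cols(
    stay_id = readr::col_character(), lab_name = readr::col_character(),
    time_h = readr::col_double(), value_raw = readr::col_character()),
    LABS_COLS, "labs")
  events <- read_checked(file.path(dir, "events.csv"), readr::cols(
    stay_id = readr::col_character(), event_name = readr::col_character(),
    event_kind = readr::col_character(), time_h = readr::col_double()),
    EVENTS_COLS, "events")
  ehr_dataset(stays, labs, events)
}

read_checked <- function(path, col_spec, required, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
  df <- readr::read_csv(path, col_types = col_spec, show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at row(s) %s",
                  path, paste(unique(probs$row), collapse = ", ")))
  }
  df
}

#' Restrict an EHR dataset to stays meeting cohort criteria
#'
#' Keeps stays with duration at least `min_stay_hours` (48 h by default, the
#' usual horizon for first-48-hour mortality features) and, optionally, with a
#' TRUE case-definition flag column. Lab and clinical events belonging to
#' dropped stays are removed. A step-by-step attrition funnel is attached as
#' the `"funnel"` attribute.
#'
#' @param dataset An [ehr_dataset()].
#' @param min_stay_hours Minimum stay duration in hours (inclusive).
#' @param require_flag Optional name of a logical/0-1 column in `stays` that
#'   must be truthy for a stay to be retained (e.g. a phenotype flag).
#' @return The filtered [ehr_dataset()] with a `"funnel"` attribute (tibble
#'   of step, n_stays).
#' @export
filter_cohort <- function(dataset, min_stay_hours = 48, require_flag = NULL) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  funnel <- tibble::tibble(step = "input", n_stays = nrow(dataset$stays))
  stays <- dataset$stays
  if (!is.null(require_flag)) {
    if (!require_flag %in% names(stays)) {
      abort(sprintf("flag column `%s` not present in stays", require_flag))
    }
    stays <- stays[as.logical(stays[[require_flag]]) %in% TRUE, ]
    funnel <- dplyr::bind_rows(funnel, tibble::tibble(
      step = paste0("flag:", require_flag), n_stays = nrow(stays)))
  }
  stays <- stays[stays$outtime_h - stays$intime_h >= min_stay_hours, ]
  funnel <- dplyr::bind_rows(funnel, tibble::tibble(
    step = sprintf("duration>=%gh", min_stay_hours), n_stays = nrow(stays)))
  keep <- stays$stay_id
  out <- ehr_dataset(
    stays,
    dataset$labs[dataset$labs$stay_id %in% keep, ],
    dataset$events[dataset$events$stay_id %in% keep, ])
  attr(out, "funnel") <- funnel
  out
}

#' Validate referential and temporal integrity of an EHR dataset
#'
#' Report-only: returns one row per violation (events referencing unknown
#' stays, timestamps outside the stay window, unparseable stay rows). A clean
#' dataset yields a zero-row report.
#'
#' @param dataset An [ehr_dataset()].
#' @return Tibble with columns `table`, `row`, `problem`.
#' @export
validate_ehr_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  report <- list()
  note <- function(table, row, problem) {
    tibble::tibble(table = table, row = as.integer(row), problem = problem)
  }
  bad <- which(dataset$stays$outtime_h <= dataset$stays$intime_h)
  if (length(bad)) report <- c(report, list(note("stays", bad, "outtime_h <= intime_h")))
  bad <- which(!dataset$stays$died %in% c(0L, 1L))
  if (length(bad)) report <- c(report, list(note("stays", bad, "died not in {0,1}")))

  window <- dataset$stays[, c("stay_id", "intime_h", "outtime_h")]
  for (tab in c("labs", "events")) {
    df <- dataset[[tab]]
    unknown <- which(!df$stay_id %in% window$stay_id)
    if (length(unknown)) report <- c(report, list(note(tab, unknown, "unknown stay_id")))
    m <- match(df$stay_id, window$stay_id)
    out_of_window <- which(!is.na(m) &
                             (df$time_h < window$intime_h[m] |
                                df$time_h > window$outtime_h[m]))
    if (length(out_of_window)) {
      report <- c(report, list(note(tab, out_of_window, "time_h outside stay window")))
    }
  }
  if (length(report) == 0) {
    return(tibble::tibble(table = character(), row = integer(),
                          problem = character()))
  }
  dplyr::bind_rows(report)
}
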