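#' Feature matrix with column metadata
#'
#' A numeric design matrix (one row per stay) plus a metadata tibble tagging
#' every column with its block (`lab`, `demographic`, `event`, `triple`) and,
#' where applicable, the laboratory/attribute/event name, the 0-based hour
#' slot and the slot statistic. The `subset` tag records which of the four
#' nested data subsets the matrix represents.
#'
#' @param values Numeric matrix, rownames = stay ids.
#' @param columns Tibble with at least `name` and `block`.
#' @param subset One of `"Labs"`, `"Labs+demo"`, `"Labs+demo+events"`,
#'   `"Labs+demo+events+triples"`.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, columns, subset) {
  stopifnot(is.matrix(values), nrow(columns) == ncol(values))
  colnames(values) <- columns$name
  structure(list(values = values, columns = tibble::as_tibble(columns),
                 subset = subset),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d stays x %d columns (%s)\n",
              x$subset, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$columns$block)),
                            table(x$columns$block)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

SUBSET_LEVELS <- c("Labs", "Labs+demo", "Labs+demo+events",
                   "Labs+demo+events+triples")
SLOT_STATS <- c("mean", "min", "max", "sd", "skew")

#' Build the Labs design matrix of hourly slot statistics
#'
#' For each laboratory and each of the `horizon` one-hour slots from stay
#' start, computes the mean, min, max, standard deviation and skew of the
#' slot's measurements — `f x horizon x 5` columns in total. A slot with no
#' measurement contributes five zeros; a single-measurement slot has
#' mean = min = max = value and sd = skew = 0. Raw values are coerced via
#' [coerce_lab_values()]; unconvertible entries are ignored.
#'
#' @param dataset An [ehr_dataset()] (labs may carry a pre-coerced `value`
#'   column, otherwise `value_raw` is coerced here).
#' @param lab_list Laboratories to include, in column-block order; each must
#'   appear in the dataset.
#' @param horizon Number of hourly slots (default 48).
#' @return A [feature_matrix()] with subset `"Labs"`.
#' @export
build_lab_features <- function(dataset, lab_list, horizon = 48) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  missing <- setdiff(lab_list, unique(dataset$labs$lab_name))
  if (length(missing) > 0) {
    abort(sprintf("lab(s) absent from dataset: %s",
                  paste(missing, collapse = ", ")))
  }
  labs <- data.table::as.data.table(dataset$labs)
  labs <- labs[labs$lab_name %in% lab_list]
  if (!"value" %in% names(labs)) labs[, value := coerce_lab_values(value_raw)]
  labs <- labs[!is.na(value)]
  labs[, hour := as.integer(floor(time_h))]
  labs <- labs[hour >= 0 & hour < horizon]

  # grouped moments from power sums (keeps the aggregation on data.table's
  # optimized C paths); sd is the n-1 estimator, skew the third standardized
  # moment, both defined as 0 when degenerate so the matrix width is fixed
  labs[, `:=`(v2 = value^2, v3 = value^3)]
  st <- labs[, list(n = .N, s1 = sum(value), s2 = sum(v2),
                    s3 = sum(v3), min = min(value), max = max(value)),
             by = c("stay_id", "lab_name", "hour")]
  st[, mean := s1 / n]
  st[, m2 := pmax(s2 / n - mean^2, 0)]
  st[, sd := ifelse(n > 1, sqrt(m2 * n / pmax(n - 1, 1)), 0)]
  st[, m3 := s3 / n - 3 * mean * s2 / n + 2 * mean^3]
  st[, skew := ifelse(n > 2 & m2 > 0, m3 / m2^1.5, 0)]

  n_pat <- nrow(dataset$stays)
  f <- length(lab_list)
  values <- matrix(0, nrow = n_pat, ncol = f * horizon * 5,
                   dimnames = list(dataset$stays$stay_id, NULL))
  if (nrow(st) > 0) {
    row_idx <- match(st$stay_id, dataset$stays$stay_id)
    base <- ((match(st$lab_name, lab_list) - 1L) * horizon + st$hour) * 5L
    for (j in seq_along(SLOT_STATS)) {
      values[cbind(row_idx, base + j)] <- st[[SLOT_STATS[j]]]
    }
  }
  columns <- tibble::tibble(
    block = "lab",
    lab_name = rep(lab_list, each = horizon * 5),
    hour = rep(rep(seq_len(horizon) - 1L, each = 5), times = f),
    statistic = rep(SLOT_STATS, times = f * horizon))
  columns$name <- sprintf("%s.h%02d.%s", columns$lab_name, columns$hour,
                          columns$statistic)
  feature_matrix(values, columns, "Labs")
}

#' Append integer-coded demographic columns
#'
#' Adds one integer-coded column per attribute (age group over six ordered
#' codes, race/ethnicity over six codes, sex over two) repeated for every
#' hour slot — `3 x horizon` columns, constant across a patient's slots.
#' Unrecognized race strings are coded as `other`.
#'
#' @param fm A `"Labs"` [feature_matrix()].
#' @param stays Stays tibble aligned with the matrix rows by `stay_id`.
#' @return A [feature_matrix()] with subset `"Labs+demo"`.
#' @export
append_demographics <- function(fm, stays) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$subset != "Labs") abort("append_demographics expects a Labs matrix")
  horizon <- max(fm$columns$hour) + 1L
  m <- match(rownames(fm$values), stays$stay_id)
  if (anyNA(m)) abort("matrix rows missing from stays")
  age <- match(stays$age_group[m], AGE_GROUPS)
  if (anyNA(age)) abort("unrecognized age_group value")
  race <- match(stays$race[m], RACE_GROUPS)
  race[is.na(race)] <- match("other", RACE_GROUPS)
  sex <- match(stays$sex[m], SEX_GROUPS)
  if (anyNA(sex)) abort("unrecognized sex value")

  codes <- cbind(age = age, race = race, sex = sex)
  block <- codes[, rep(seq_len(3), each = horizon), drop = FALSE]
  columns <- tibble::tibble(
    block = "demographic",
    lab_name = NA_character_,
    hour = rep(seq_len(horizon) - 1L, times = 3),
    statistic = NA_character_,
    name = sprintf("%s.h%02d", rep(c("age_group", "race", "sex"),
                                   each = horizon),
                   rep(seq_len(horizon) - 1L, times = 3)))
  feature_matrix(cbind(fm$values, block),
                 dplyr::bind_rows(fm$columns, columns), "Labs+demo")
}

#' Append binary clinical-event indicator columns
#'
#' One column per (event, hour slot): 1 if the event was recorded during
#' `[hour, hour + 1)` of the stay, 0 otherwise.
#'
#' @param fm A `"Labs+demo"` [feature_matrix()].
#' @param events Clinical-events tibble.
#' @param event_list Events to encode (typically the distinct events among
#'   the expert-filtered triplets), in column order.
#' @return A [feature_matrix()] with subset `"Labs+demo+events"`.
#' @export
append_events <- function(fm, events, event_list) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$subset != "Labs+demo") abort("append_events expects a Labs+demo matrix")
  horizon <- max(fm$columns$hour, na.rm = TRUE) + 1L
  n <- nrow(fm$values)
  block <- matrix(0, nrow = n, ncol = length(event_list) * horizon)
  ev <- events[events$event_name %in% event_list &
                 events$stay_id %in% rownames(fm$values), ]
  ev <- ev[floor(ev$time_h) >= 0 & floor(ev$time_h) < horizon, ]
  if (nrow(ev) > 0) {
    row_idx <- match(ev$stay_id, rownames(fm$values))
    col_idx <- (match(ev$event_name, event_list) - 1L) * horizon +
      as.integer(floor(ev$time_h)) + 1L
    block[cbind(row_idx, col_idx)] <- 1
  }
  columns <- tibble::tibble(
    block = "event",
    lab_name = NA_character_,
    hour = rep(seq_len(horizon) - 1L, times = length(event_list)),
    statistic = NA_character_,
    event_name = rep(event_list, each = horizon))
  columns$name <- sprintf("ev.%s.h%02d", columns$event_name, columns$hour)
  feature_matrix(cbind(fm$values, block),
                 dplyr::bind_rows(fm$columns, columns),
                 "Labs+demo+events")
}

#' Append the event-masked duplicate of the Labs block
#'
#' Duplicates the `f x horizon x 5` Labs block, zeroing a (patient, hour)
#' slot's statistics whenever all of that patient's event indicators for the
#' slot are zero; slots co-occurring with at least one event keep their lab
#' values as-is.
#'
#' @param fm A `"Labs+demo+events"` [feature_matrix()].
#' @return A [feature_matrix()] with subset `"Labs+demo+events+triples"`.
#' @export
append_triples <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$subset != "Labs+demo+events") {
    abort("append_triples expects a Labs+demo+events matrix")
  }
  lab_cols <- which(fm$columns$block == "lab")
  event_cols <- which(fm$columns$block == "event")
  horizon <- max(fm$columns$hour[lab_cols]) + 1L
  n <- nrow(fm$values)

  any_event <- matrix(0, nrow = n, ncol = horizon)
  if (length(event_cols) > 0) {
    ev_hours <- fm$columns$hour[event_cols]
    for (h in seq_len(horizon) - 1L) {
      cols <- event_cols[ev_hours == h]
      if (length(cols) > 0) {
        any_event[, h + 1L] <- as.numeric(rowSums(
          fm$values[, cols, drop = FALSE]) > 0)
      }
    }
  }
  mask <- any_event[, fm$columns$hour[lab_cols] + 1L, drop = FALSE]
  block <- fm$values[, lab_cols, drop = FALSE] * mask
  columns <- fm$columns[lab_cols, ]
  columns$block <- "triple"
  columns$name <- paste0("triple.", columns$name)
  feature_matrix(cbind(fm$values, block),
                 dplyr::bind_rows(fm$columns, columns),
                 "Labs+demo+events+triples")
}

#' Fit a per-column standardizer on training rows
#'
#' Learns per-column mean and SD so features can be centred and scaled to
#' unit variance; zero-variance columns map to 0. Always fit on the training
#' split only and applied unchanged to test rows.
#'
#' @param fm Training [feature_matrix()].
#' @return Object of class `standardizer`.
#' @export
fit_standardizer <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  mu <- colMeans(fm$values)
  sigma <- apply(fm$values, 2, sd)
  structure(list(mean = mu, sd = sigma, columns = fm$columns$name),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param fm A [feature_matrix()] with the same columns the standardizer was
#'   fitted on.
#' @param std A [fit_standardizer()] object.
#' @return `fm` with transformed values.
#' @export
apply_standardizer <- function(fm, std) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(std, "standardizer"))
  if (!identical(fm$columns$name, std$columns)) {
    abort("feature matrix columns do not match the standardizer")
  }
  scale_ <- ifelse(std$sd > 0, std$sd, 1)
  z <- sweep(sweep(fm$values, 2, std$mean, "-"), 2, scale_, "/")
  z[, std$sd == 0] <- 0
  fm$values <- z
  fm
}

#' Build a design matrix for one of the four data subsets
#'
#' Convenience composition of [build_lab_features()],
#' [append_demographics()], [append_events()] and [append_triples()].
#'
#' @param dataset An [ehr_dataset()].
#' @param lab_list Laboratories (column-block order).
#' @param subset Target subset tag.
#' @param event_list Events to encode (required beyond `"Labs+demo"`).
#' @param horizon Hour slots (default 48).
#' @return A [feature_matrix()].
#' @export
build_design <- function(dataset, lab_list,
                         subset = SUBSET_LEVELS, event_list = NULL,
                         horizon = 48) {
  subset <- match.arg(subset)
  fm <- build_lab_features(dataset, lab_list, horizon = horizon)
  if (subset == "Labs") return(fm)
  fm <- append_demographics(fm, dataset$stays)
  if (subset == "Labs+demo") return(fm)
  if (is.null(event_list)) abort("event_list required for event-bearing subsets")
  fm <- append_events(fm, dataset$events, event_list)
  if (subset == "Labs+demo+events") return(fm)
  append_triples(fm)
}
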