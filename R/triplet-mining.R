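#' Extract lab-event-lab triplet instances
#'
#' For every clinical event occurrence and every laboratory measured in the
#' same stay, one triplet instance pairs the latest measurement at or before
#' the event time ("before") with the earliest measurement strictly after it
#' ("after"). Pairs lacking either side emit nothing. A laboratory can pair
#' with several events and a patient can contribute many instances. When
#' several measurements share the boundary timestamp, the last in file order
#' is "before" and the first strictly-later one is "after".
#'
#' @param labs_binned Binned lab events from [bin_lab_events()] (columns
#'   `stay_id`, `lab_name`, `time_h`, `bin`).
#' @param events Clinical events tibble (`stay_id`, `event_name`,
#'   `event_kind`, `time_h`).
#' @param stays Stays tibble; every event `stay_id` must appear here.
#' @return Tibble of triplet instances: `stay_id`, `lab_name`, `event_name`,
#'   `event_kind`, `t_before`, `t_event`, `t_after`, `bin_before`,
#'   `bin_after`, `direction`.
#' @export
extract_triplets <- function(labs_binned, events, stays) {
  unknown <- which(!events$stay_id %in% stays$stay_id)
  if (length(unknown) > 0) {
    abort(sprintf("events reference unknown stay_id at row(s): %s",
                  paste(head(unknown, 20), collapse = ", ")))
  }
  if (nrow(labs_binned) == 0 || nrow(events) == 0) return(empty_triplets())

  lb <- data.table::as.data.table(
    labs_binned[, c("stay_id", "lab_name", "time_h", "bin")])
  lb[, rid := .I]  # file order, used to break ties at equal timestamps
  data.table::setorder(lb, stay_id, lab_name, time_h, rid)

  ev <- data.table::as.data.table(
    events[, c("stay_id", "event_name", "event_kind", "time_h")])
  data.table::setnames(ev, "time_h", "t_event")

  # candidate (event occurrence x lab series in the same stay) pairs
  series <- unique(lb[, c("stay_id", "lab_name")])
  cand <- merge(series, ev, by = "stay_id", allow.cartesian = TRUE)
  if (nrow(cand) == 0) return(empty_triplets())
  cand[, cand_id := .I]

  cart <- lb[cand, on = c("stay_id", "lab_name"), allow.cartesian = TRUE]
  data.table::setorder(cart, cand_id, time_h, rid)

  bef <- cart[time_h <= t_event]
  bef <- bef[bef[, .I[.N], by = cand_id]$V1]
  aft <- cart[time_h > t_event]
  aft <- aft[aft[, .I[1L], by = cand_id]$V1]

  out <- merge(
    bef[, .(cand_id, stay_id, lab_name, event_name, event_kind, t_event,
            t_before = time_h, bin_before = bin)],
    aft[, .(cand_id, t_after = time_h, bin_after = bin)],
    by = "cand_id")
  if (nrow(out) == 0) return(empty_triplets())
  out[, cand_id := NULL]
  out <- tibble::as_tibble(out)
  out$direction <- categorize_direction(out$bin_before, out$bin_after)
  out[order(out$stay_id, out$lab_name, out$event_name, out$t_event), ]
}

empty_triplets <- function() {
  tibble::tibble(stay_id = character(), lab_name = character(),
                 event_name = character(), event_kind = character(),
                 t_event = numeric(), t_before = numeric(),
                 bin_before = integer(), t_after = numeric(),
                 bin_after = integer(), direction = character())
}

#' Categorize a triplet's direction of change
#'
#' Compares bin indices, not raw values: equal bins mean `no_change`, a
#' higher bin after the event means `increasing`, a lower one `decreasing`.
#'
#' @param bin_before,bin_after Integer bin indices.
#' @return Character vector over `c("no_change", "increasing", "decreasing")`.
#' @export
categorize_direction <- function(bin_before, bin_after) {
  ifelse(bin_after == bin_before, "no_change",
         ifelse(bin_after > bin_before, "increasing", "decreasing"))
}

#' Cross-tabulate triplet instances against mortality
#'
#' For each distinct (laboratory, event) pair, counts instances in a 2x3
#' table: rows survived/died, columns no_change/increasing/decreasing.
#' Counting is at the instance level — a patient may contribute several
#' instances to the same cell.
#'
#' @param triplets Instances from [extract_triplets()].
#' @param stays Stays tibble supplying the `died` label per `stay_id`.
#' @return Tibble with one row per (lab_name, event_name, event_kind) and
#'   count columns `n_survived_no_change`, `n_survived_increasing`,
#'   `n_survived_decreasing`, `n_died_no_change`, `n_died_increasing`,
#'   `n_died_decreasing`, plus `n_total`.
#' @export
cross_tabulate <- function(triplets, stays) {
  if (nrow(triplets) == 0) return(empty_tables())
  m <- match(triplets$stay_id, stays$stay_id)
  if (anyNA(m)) abort("triplet instances reference stays without labels")
  outcome <- ifelse(stays$died[m] == 1L, "died", "survived")
  counts <- dplyr::count(
    tibble::tibble(lab_name = triplets$lab_name,
                   event_name = triplets$event_name,
                   event_kind = triplets$event_kind,
                   cell = paste0("n_", outcome, "_", triplets$direction)),
    .data$lab_name, .data$event_name, .data$event_kind, .data$cell)
  wide <- tidyr::pivot_wider(counts, names_from = "cell", values_from = "n",
                             values_fill = 0L)
  for (col in cell_cols()) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  wide <- wide[, c("lab_name", "event_name", "event_kind", cell_cols())]
  wide$n_total <- as.integer(rowSums(wide[, cell_cols()]))
  dplyr::arrange(wide, .data$lab_name, .data$event_name)
}

cell_cols <- function() {
  paste0("n_", rep(OUTCOME_LEVELS, each = 3), "_", DIRECTION_LEVELS)
}

empty_tables <- function() {
  out <- tibble::tibble(lab_name = character(), event_name = character(),
                        event_kind = character())
  for (col in cell_cols()) out[[col]] <- integer()
  out$n_total <- integer()
  out
}

#' Convert one table row to a 2x3 count matrix
#'
#' Rows survived/died, columns no_change/increasing/decreasing.
#'
#' @param tables Cross-tabulation tibble from [cross_tabulate()].
#' @param i Row index.
#' @return 2x3 integer matrix with dimnames.
#' @export
table_counts <- function(tables, i = 1L) {
  matrix(as.numeric(tables[i, cell_cols()]), nrow = 2, byrow = TRUE,
         dimnames = list(OUTCOME_LEVELS, DIRECTION_LEVELS))
}

#' Filter triplet tables by support
#'
#' Small tables cannot support a reliable association estimate; tables with
#' a total instance count below `min_total` are dropped. The default of 11
#' retains tables with more than 10 instances.
#'
#' @param tables Cross-tabulation tibble.
#' @param min_total Minimum total instance count (inclusive).
#' @return Subset of `tables`.
#' @export
filter_by_support <- function(tables, min_total = 11) {
  stopifnot(min_total >= 0)
  tables[tables$n_total >= min_total, ]
}
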