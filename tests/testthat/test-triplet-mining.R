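make_mining_input <- function(lab_times, lab_bins, event_times,
                              stay = "s1", out = 60) {
  list(
    labs = tibble::tibble(stay_id = stay, lab_name = "lab_a",
                          time_h = lab_times, value_raw = "0",
                          value = 0, bin = as.integer(lab_bins)),
    events = tibble::tibble(stay_id = stay, event_name = "drug_a",
                            event_kind = "prescription",
                            time_h = event_times),
    stays = tibble::tibble(patient_id = "p", stay_id = stay, intime_h = 0,
                           outtime_h = out, age_group = "35-49",
                           race = "white", sex = "male", died = 0L))
}

test_that("a before/after lab pair around an event yields one instance", {
  inp <- make_mining_input(c(1, 3), c(2, 4), 2)
  out <- extract_triplets(inp$labs, inp$events, inp$stays)
  expect_equal(nrow(out), 1)
  expect_equal(out$bin_before, 2L)
  expect_equal(out$bin_after, 4L)
  expect_equal(out$direction, "increasing")
  expect_equal(out$t_before, 1)
  expect_equal(out$t_after, 3)
})

test_that("events without a prior or later lab emit nothing", {
  # no lab before the event
  inp <- make_mining_input(c(1, 3), c(2, 4), 0.5)
  expect_equal(nrow(extract_triplets(inp$labs, inp$events, inp$stays)), 0)
  # no lab after the event
  inp <- make_mining_input(c(1, 3), c(2, 4), 3.5)
  expect_equal(nrow(extract_triplets(inp$labs, inp$events, inp$stays)), 0)
})

test_that("each event occurrence pairs independently with the same labs", {
  inp <- make_mining_input(c(1, 3), c(2, 4), c(2, 2.5))
  out <- extract_triplets(inp$labs, inp$events, inp$stays)
  expect_equal(nrow(out), 2)
  expect_equal(out$bin_before, c(2L, 2L))
  expect_equal(out$bin_after, c(4L, 4L))
})

test_that("a lab exactly at the event time counts as before, not after", {
  inp <- make_mining_input(c(2, 5), c(1, 6), 2)
  out <- extract_triplets(inp$labs, inp$events, inp$stays)
  expect_equal(out$t_before, 2)
  expect_equal(out$t_after, 5)
  # equal timestamps: last in file order is before, first strictly later after
  inp <- make_mining_input(c(2, 2, 3, 3), c(1, 4, 5, 6), 2)
  out <- extract_triplets(inp$labs, inp$events, inp$stays)
  expect_equal(out$bin_before, 4L)
  expect_equal(out$bin_after, 5L)
})

test_that("events referencing unknown stays are rejected with row numbers", {
  inp <- make_mining_input(c(1, 3), c(2, 4), 2)
  inp$events$stay_id <- "ghost"
  expect_error(extract_triplets(inp$labs, inp$events, inp$stays),
               "unknown stay_id.*1")
})

test_that("direction compares bin indices only", {
  expect_equal(categorize_direction(3L, 3L), "no_change")
  expect_equal(categorize_direction(2L, 5L), "increasing")
  expect_equal(categorize_direction(5L, 1L), "decreasing")
})

test_that("cross-tabulation counts instances per outcome and direction", {
  fx <- instances_from_counts(matrix(c(0, 0, 0, 0, 3, 0), nrow = 2,
                                     byrow = TRUE))
  tab <- cross_tabulate(fx$instances, fx$stays)
  expect_equal(tab$n_died_increasing, 3L)
  expect_equal(tab$n_total, 3L)
  expect_equal(sum(tab$n_survived_no_change + tab$n_survived_increasing +
                     tab$n_survived_decreasing), 0L)
  expect_equal(nrow(cross_tabulate(fx$instances[0, ], fx$stays)), 0)
})

test_that("the worked drug example reconstructs from instances", {
  counts <- matrix(c(25, 8, 5, 12, 23, 27), nrow = 2, byrow = TRUE)
  fx <- instances_from_counts(counts)
  tab <- cross_tabulate(fx$instances, fx$stays)
  expect_equal(table_counts(tab), counts,
               ignore_attr = TRUE)
  expect_equal(tab$n_total, 100L)
  expect_equal(mi_score(table_counts(tab)), 0.11523, tolerance = 1e-4)
})

test_that("support filtering keeps tables with more than 10 instances", {
  fx10 <- instances_from_counts(matrix(c(2, 2, 2, 2, 1, 1), nrow = 2,
                                       byrow = TRUE))
  fx11 <- instances_from_counts(matrix(c(2, 2, 2, 2, 2, 1), nrow = 2,
                                       byrow = TRUE), lab = "lab_b")
  tabs <- dplyr::bind_rows(cross_tabulate(fx10$instances, fx10$stays),
                           cross_tabulate(fx11$instances, fx11$stays))
  kept <- filter_by_support(tabs, min_total = 11)
  expect_equal(kept$lab_name, "lab_b")
  expect_equal(nrow(filter_by_support(tabs[0, ], 11)), 0)
})

test_that("instances are conserved into table cells", {
  d <- generate_cohort(quick_config(seed = 9, n = 120))
  binned <- bin_lab_events(d$labs, fit_binning_schemes(d$labs))
  inst <- extract_triplets(binned, d$events, d$stays)
  tabs <- cross_tabulate(inst, d$stays)
  expect_equal(sum(tabs$n_total), nrow(inst))
  expect_true(all(inst$t_after > inst$t_event))
  expect_true(all(inst$t_before <= inst$t_event))
})

test_that("swapping before/after bins swaps the direction columns", {
  d <- generate_cohort(quick_config(seed = 10, n = 120))
  binned <- bin_lab_events(d$labs, fit_binning_schemes(d$labs))
  inst <- extract_triplets(binned, d$events, d$stays)
  tabs <- cross_tabulate(inst, d$stays)
  swapped <- inst
  swapped$bin_before <- inst$bin_after
  swapped$bin_after <- inst$bin_before
  swapped$direction <- categorize_direction(swapped$bin_before,
                                            swapped$bin_after)
  tabs2 <- cross_tabulate(swapped, d$stays)
  expect_equal(tabs2$n_survived_increasing, tabs$n_survived_decreasing)
  expect_equal(tabs2$n_died_increasing, tabs$n_died_decreasing)
  expect_equal(tabs2$n_survived_no_change, tabs$n_survived_no_change)
  expect_equal(tabs2$n_died_no_change, tabs$n_died_no_change)
})
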