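slot_dataset <- function(values, times = NULL, lab = "lab_a") {
  n <- length(values)
  if (is.null(times)) times <- seq(5.1, 5.9, length.out = n)
  stays <- tibble::tibble(patient_id = "p1", stay_id = "s1", intime_h = 0,
                          outtime_h = 60, age_group = "35-49", race = "white",
                          sex = "male", died = 0L)
  ehr_dataset(stays,
              tibble::tibble(stay_id = "s1", lab_name = lab, time_h = times,
                             value_raw = as.character(values)),
              tibble::tibble(stay_id = character(), event_name = character(),
                             event_kind = character(), time_h = numeric()))
}

test_that("the Labs block is f x 48 x 5 wide", {
  d <- generate_cohort(quick_config(seed = 1, n = 20, n_null = 3))
  fm <- build_lab_features(d, c("lactate", "null1"))
  expect_equal(ncol(fm$values), 2 * 48 * 5)
  expect_equal(fm$subset, "Labs")
  expect_error(build_lab_features(d, "ghost_lab"), "ghost_lab")
})

test_that("slot statistics handle empty, single and multi-value slots", {
  d <- slot_dataset(7.4)
  fm <- build_lab_features(d, "lab_a")
  slot5 <- fm$values[1, fm$columns$hour == 5]
  expect_equal(unname(slot5), c(7.4, 7.4, 7.4, 0, 0))
  # all other slots are zero
  expect_equal(sum(fm$values != 0), 3)

  vals <- c(1.2, 3.4, 2.2, 9.1)
  fm <- build_lab_features(slot_dataset(vals), "lab_a")
  slot5 <- fm$values[1, fm$columns$hour == 5]
  skip_if_not_installed("e1071")
  expect_equal(unname(slot5),
               c(mean(vals), min(vals), max(vals), sd(vals),
                 e1071::skewness(vals, type = 1)),
               tolerance = 1e-10)
})

test_that("textual lab entries are ignored when building slots", {
  d <- slot_dataset(c("2.0", "error", "4.0"))
  fm <- build_lab_features(d, "lab_a")
  expect_equal(unname(fm$values[1, fm$columns$hour == 5][1:3]), c(3, 2, 4))
})

test_that("demographics add 144 constant integer-coded columns", {
  d <- generate_cohort(quick_config(seed = 2, n = 15, n_null = 3))
  fm <- build_lab_features(d, "lactate")
  fm2 <- append_demographics(fm, d$stays)
  expect_equal(ncol(fm2$values) - ncol(fm$values), 144)
  expect_equal(fm2$subset, "Labs+demo")
  demo <- fm2$values[, fm2$columns$block == "demographic"]
  # constant across a patient's 48 slots
  age_cols <- demo[, grep("^age_group", colnames(demo))]
  expect_true(all(apply(age_cols, 1, function(r) length(unique(r)) == 1)))
  # a 40-year-old style age group lands on the 35-49 code in every slot
  i <- which(d$stays$age_group == "35-49")[1]
  skip_if(is.na(i))
  expect_true(all(age_cols[i, ] == 4))
  expect_error(append_demographics(fm2, d$stays), "Labs matrix")
})

test_that("unknown race strings fall back to the other code", {
  d <- generate_cohort(quick_config(seed = 2, n = 5, n_null = 3))
  d$stays$race[1] <- "unrecorded-category"
  fm2 <- append_demographics(build_lab_features(d, "lactate"), d$stays)
  race_cols <- fm2$values[, grep("^race", fm2$columns$name)]
  expect_true(all(race_cols[1, ] == 6))
})

test_that("event indicators mark the hour slot of each occurrence", {
  d <- generate_cohort(quick_config(seed = 3, n = 10, n_null = 3))
  d$events <- tibble::tibble(stay_id = d$stays$stay_id[1],
                             event_name = "epinephrine",
                             event_kind = "prescription", time_h = 2.5)
  fm <- append_demographics(build_lab_features(d, "lactate"), d$stays)
  fm3 <- append_events(fm, d$events, "epinephrine")
  ev <- fm3$values[, fm3$columns$block == "event"]
  expect_equal(ncol(ev), 48)
  expect_equal(unname(ev[1, ]), as.numeric(seq_len(48) - 1 == 2))
  expect_true(all(ev[-1, ] == 0))

  # a 28-event list adds 28 x 48 columns
  fm28 <- append_events(fm, d$events, sprintf("e%02d", 1:28))
  expect_equal(ncol(fm28$values) - ncol(fm$values), 1344)
})

test_that("the triples block duplicates lab columns masked by event slots", {
  d <- generate_cohort(quick_config(seed = 4, n = 12, n_null = 3))
  fm <- build_design(d, "lactate", "Labs+demo+events+triples",
                     event_list = "epinephrine")
  lab_block <- fm$values[, fm$columns$block == "lab"]
  tri_block <- fm$values[, fm$columns$block == "triple"]
  expect_equal(ncol(tri_block), 240)

  has_event <- d$stays$stay_id %in%
    d$events$stay_id[d$events$event_name == "epinephrine"]
  if (any(!has_event)) {
    expect_true(all(tri_block[!has_event, ] == 0))
  }
  # masked entries are either zero or identical to the lab block
  expect_true(all(tri_block == 0 | tri_block == lab_block))
  # within event-hour slots the copy is exact
  ev_cols <- fm$values[, fm$columns$block == "event", drop = FALSE]
  for (i in which(has_event)[1]) {
    hrs <- fm$columns$hour[fm$columns$block == "event"][ev_cols[i, ] == 1]
    sel <- fm$columns$hour[fm$columns$block == "triple"] %in% hrs
    expect_equal(unname(tri_block[i, sel]), unname(lab_block[i, sel]))
  }
})

test_that("standardization centres and scales training columns only", {
  d <- generate_cohort(quick_config(seed = 5, n = 30, n_null = 3))
  sp <- split_cohort(d, 0.3, seed = 1)
  fm_tr <- build_lab_features(sp$train, "lactate")
  fm_te <- build_lab_features(sp$test, "lactate")
  std <- fit_standardizer(fm_tr)
  z_tr <- apply_standardizer(fm_tr, std)$values
  z_te <- apply_standardizer(fm_te, std)$values

  live <- std$sd > 0
  expect_equal(unname(colMeans(z_tr[, live])), rep(0, sum(live)),
               tolerance = 1e-12)
  expect_equal(unname(apply(z_tr[, live], 2, sd)), rep(1, sum(live)),
               tolerance = 1e-12)
  expect_true(all(z_tr[, !live] == 0))
  # test rows transformed with training parameters, not their own
  j <- which(live)[1]
  expect_equal(z_te[, j],
               (fm_te$values[, j] - std$mean[j]) / std$sd[j],
               ignore_attr = TRUE)
  # column mismatch is refused
  fm_bad <- build_lab_features(sp$test, "null1")
  expect_error(apply_standardizer(fm_bad, std), "columns")
})

test_that("row order permutes rows without altering content", {
  d <- generate_cohort(quick_config(seed = 6, n = 15, n_null = 3))
  fm <- build_lab_features(d, c("lactate", "null1"))
  perm <- withr::with_seed(1, sample(nrow(d$stays)))
  d2 <- d
  d2$stays <- d$stays[perm, ]
  fm2 <- build_lab_features(d2, c("lactate", "null1"))
  expect_equal(fm2$values, fm$values[perm, ])
})
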