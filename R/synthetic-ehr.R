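#' Specify a simulated laboratory test
#'
#' @param name Laboratory name.
#' @param mean,sd Generative normal mean and SD of the measured value.
#' @param rate Per-hour sampling rate (expected measurements per hour). The
#'   default 0.25 corresponds to a draw roughly every four hours, typical of
#'   ICU chemistry panels.
#' @return A `sim_lab` spec list.
#' @export
sim_lab <- function(name, mean = 0, sd = 1, rate = 0.25) {
  stopifnot(is.character(name), length(name) == 1, sd > 0, rate > 0)
  list(name = name, mean = mean, sd = sd, rate = rate)
}

#' Specify a simulated clinical event
#'
#' Each stay experiences the event at most once, with probability `prob`,
#' at a uniform time away from the stay edges so laboratory measurements
#' typically exist on both sides.
#'
#' @param name Event name.
#' @param kind `"prescription"` or `"procedure"`.
#' @param prob Per-stay occurrence probability.
#' @return A `sim_event` spec list.
#' @export
sim_event <- function(name, kind = c("prescription", "procedure"), prob = 0.5) {
  kind <- match.arg(kind)
  stopifnot(prob >= 0, prob <= 1)
  list(name = name, kind = kind, prob = prob)
}

#' Specify a planted lab-event-lab mortality association
#'
#' In stays experiencing `event_name`, the planted effect (realized with
#' probability `effect_strength`) makes the laboratory's post-event bin move
#' in an outcome-conditional direction: pre-event values are pulled into the
#' central bins, and every post-event value is pinned at the last pre-event
#' value plus three generative SDs (`"increase"`), minus three
#' (`"decrease"`), or exactly at it (`"no_change"`). The three-SD offset
#' from the pre-event anchor exceeds the widest inter-divider gap of the
#' default binning even after the plant inflates the estimated SD, so a
#' realized plant changes bin in the planted direction deterministically.
#'
#' @param lab_name,event_name Names matching the config's lab/event specs.
#' @param direction_if_died,direction_if_survived One of `"increase"`,
#'   `"decrease"`, `"no_change"`.
#' @param effect_strength Probability in `[0.5, 1]` that the planted
#'   direction is realized for a given stay.
#' @return A `planted_effect` spec list.
#' @export
planted_effect <- function(lab_name, event_name,
                           direction_if_died = "increase",
                           direction_if_survived = "decrease",
                           effect_strength = 0.9) {
  dirs <- c("increase", "decrease", "no_change")
  stopifnot(direction_if_died %in% dirs, direction_if_survived %in% dirs)
  if (effect_strength < 0.5 || effect_strength > 1) {
    abort("effect_strength must be in [0.5, 1]")
  }
  list(lab_name = lab_name, event_name = event_name,
       direction_if_died = direction_if_died,
       direction_if_survived = direction_if_survived,
       effect_strength = effect_strength)
}

#' Configuration for the synthetic ICU cohort generator
#'
#' @param n_patients Number of patients (one stay each).
#' @param labs List of [sim_lab()] specs.
#' @param events List of [sim_event()] specs.
#' @param planted_effects List of [planted_effect()] specs.
#' @param stay_hours_min Minimum stay duration in hours; actual durations are
#'   `stay_hours_min` plus an Exp(mean 24 h) tail.
#' @param mortality_rate In-hospital death probability (default 0.49, the
#'   death rate typical of severe-asthma ICU benchmark cohorts).
#' @param textual_noise_rate Probability that a lab value is emitted as a
#'   non-numeric string (`"error"`, or a comparator form such as `"≤1"`).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients, labs, events = list(),
                       planted_effects = list(), stay_hours_min = 48,
                       mortality_rate = 0.49, textual_noise_rate = 0.02,
                       seed = 1L) {
  fail <- function(field, msg) abort(sprintf("invalid `%s`: %s", field, msg))
  if (!is.numeric(n_patients) || n_patients < 1) {
    fail("n_patients", "must be a positive count")
  }
  if (mortality_rate < 0 || mortality_rate > 1) {
    fail("mortality_rate", "must be in [0, 1]")
  }
  if (textual_noise_rate < 0 || textual_noise_rate > 1) {
    fail("textual_noise_rate", "must be in [0, 1]")
  }
  if (stay_hours_min <= 0) fail("stay_hours_min", "must be positive")
  if (length(labs) == 0) fail("labs", "need at least one lab spec")
  lab_names <- vapply(labs, `[[`, character(1), "name")
  event_names <- vapply(events, `[[`, character(1), "name")
  if (anyDuplicated(lab_names)) fail("labs", "duplicate lab names")
  if (anyDuplicated(event_names)) fail("events", "duplicate event names")
  for (pe in planted_effects) {
    if (!pe$lab_name %in% lab_names) {
      fail("planted_effects", sprintf("lab `%s` not among lab specs", pe$lab_name))
    }
    if (!pe$event_name %in% event_names) {
      fail("planted_effects", sprintf("event `%s` not among event specs", pe$event_name))
    }
  }
  structure(list(n_patients = as.integer(n_patients), labs = labs,
                 events = events, planted_effects = planted_effects,
                 stay_hours_min = stay_hours_min,
                 mortality_rate = mortality_rate,
                 textual_noise_rate = textual_noise_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic ICU cohort
#'
#' Emulates a MIMIC-like extract: one >=48-hour stay per patient with
#' demographics and a binary in-hospital mortality label, per-lab measurement
#' streams (normal values, occasional textual strings), at-most-one
#' occurrence per stay of each clinical event, and any configured planted
#' lab-event-lab/mortality associations. Generation is deterministic in the
#' config (a single seeded random stream; the caller's RNG state is left
#' untouched).
#'
#' @param config A [sim_config()].
#' @return An [ehr_dataset()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  duration <- config$stay_hours_min + rexp(n, rate = 1 / 24)
  stays <- tibble::tibble(
    patient_id = sprintf("p%05d", seq_len(n)),
    stay_id = sprintf("s%05d", seq_len(n)),
    intime_h = 0,
    outtime_h = duration,
    age_group = sample(AGE_GROUPS, n, replace = TRUE,
                       prob = c(0.01, 0.04, 0.20, 0.25, 0.30, 0.20)),
    race = sample(RACE_GROUPS, n, replace = TRUE,
                  prob = c(0.60, 0.15, 0.05, 0.12, 0.03, 0.05)),
    sex = sample(SEX_GROUPS, n, replace = TRUE),
    died = rbinom(n, 1, config$mortality_rate))

  labs <- data.table::rbindlist(lapply(config$labs, function(spec) {
    counts <- rpois(n, spec$rate * duration)
    sid <- rep(stays$stay_id, counts)
    data.table::data.table(
      stay_id = sid,
      lab_name = spec$name,
      time_h = runif(sum(counts)) * rep(duration, counts),
      value = rnorm(sum(counts), spec$mean, spec$sd))
  }))
  data.table::setorder(labs, stay_id, lab_name, time_h)
  labs[, rid := .I]

  # events fall inside the first-48h observation window (with 6h margins) so
  # planted associations are visible to the hourly feature encodings and
  # labs exist on both sides of the event
  events <- data.table::rbindlist(lapply(config$events, function(spec) {
    occurs <- rbinom(n, 1, spec$prob) == 1L
    d <- pmin(duration[occurs], config$stay_hours_min)
    data.table::data.table(
      stay_id = stays$stay_id[occurs],
      event_name = spec$name,
      event_kind = spec$kind,
      time_h = 6 + runif(sum(occurs)) * (d - 12))
  }))
  if (nrow(events) == 0) {
    events <- data.table::data.table(stay_id = character(),
                                     event_name = character(),
                                     event_kind = character(),
                                     time_h = numeric())
  }
  data.table::setorder(events, stay_id, event_name, time_h)

  exempt <- rep(FALSE, nrow(labs))  # rows shielded from textual noise
  for (pe in config$planted_effects) {
    spec <- config$labs[[match(pe$lab_name,
                               vapply(config$labs, `[[`, character(1), "name"))]]
    res <- plant_effect(labs, events, stays, pe, spec)
    labs <- res$labs
    exempt[res$exempt_rid] <- TRUE
  }

  value_raw <- as.character(labs$value)
  noisy <- runif(nrow(labs)) < config$textual_noise_rate & !exempt
  if (any(noisy)) {
    form <- sample(c("error", "le", "ge"), sum(noisy), replace = TRUE)
    v <- signif(labs$value[noisy], 3)
    value_raw[noisy] <- ifelse(form == "error", "error",
                               ifelse(form == "le", paste0("≤", v),
                                      paste0("≥", v)))
  }

  ehr_dataset(
    stays,
    tibble::tibble(stay_id = labs$stay_id, lab_name = labs$lab_name,
                   time_h = labs$time_h, value_raw = value_raw),
    tibble::as_tibble(events))
}

# Apply one planted effect in place on the labs table. In each realized stay,
# pre-event values of the lab are clamped into mean +/- 1.25 sd and every
# post-event value is shifted +/- 3 sd (or pinned to the last pre-event value
# for no_change), so the before/after bin comparison lands in the planted
# direction regardless of where the default dividers are later estimated.
plant_effect <- function(labs, events, stays, pe, lab_spec) {
  ev <- events[events$event_name == pe$event_name, ]
  if (nrow(ev) == 0) return(list(labs = labs, exempt_rid = integer()))
  realized <- runif(nrow(ev)) < pe$effect_strength
  ev <- ev[realized, ]
  if (nrow(ev) == 0) return(list(labs = labs, exempt_rid = integer()))

  died <- stays$died[match(ev$stay_id, stays$stay_id)]
  dir_map <- setNames(
    ifelse(died == 1L, pe$direction_if_died, pe$direction_if_survived),
    ev$stay_id)
  tev_map <- setNames(ev$time_h, ev$stay_id)

  sub <- labs[labs$lab_name == pe$lab_name & labs$stay_id %in% ev$stay_id, ]
  if (nrow(sub) == 0) return(list(labs = labs, exempt_rid = integer()))
  tev <- tev_map[sub$stay_id]
  dirs <- dir_map[sub$stay_id]
  pre <- sub$time_h <= tev
  shift <- 3 * lab_spec$sd
  lo <- lab_spec$mean - 1.25 * lab_spec$sd
  hi <- lab_spec$mean + 1.25 * lab_spec$sd

  labs$value[sub$rid[pre]] <- pmin(pmax(labs$value[sub$rid[pre]], lo), hi)

  # post-event values are pinned to anchor +/- shift (the clamped last
  # pre-event value), not shifted from their own draw: the before/after bin
  # comparison must cross a divider whatever the later-estimated sigma is
  pre_sub <- sub[pre, ]
  anchor_map <- numeric()
  if (nrow(pre_sub) > 0) {
    anchor <- pre_sub[order(pre_sub$stay_id, pre_sub$time_h), ]
    anchor <- anchor[!duplicated(anchor$stay_id, fromLast = TRUE), ]
    anchor_map <- setNames(labs$value[anchor$rid], anchor$stay_id)
  }
  anchored <- sub$stay_id %in% names(anchor_map)
  offset <- c(increase = shift, decrease = -shift, no_change = 0)
  post <- !pre & anchored
  labs$value[sub$rid[post]] <- anchor_map[sub$stay_id[post]] +
    unname(offset[dirs[post]])
  list(labs = labs, exempt_rid = sub$rid)
}
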