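# shared fixture builders; everything is generated in code at test time

# hand-built three-stay dataset with known lab/event geometry
tiny_dataset <- function() {
  stays <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    stay_id = c("s1", "s2", "s3"),
    intime_h = 0,
    outtime_h = c(60, 50, 72),
    age_group = c("35-49", "70+", "18-34"),
    race = c("white", "black", "asian"),
    sex = c("male", "female", "male"),
    died = c(0L, 1L, 0L))
  labs <- tibble::tibble(
    stay_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    lab_name = "lactate",
    time_h = c(1, 3, 10, 2, 6, 5),
    value_raw = c("1.0", "3.0", "2.0", "1.5", "4.0", "2.5"))
  events <- tibble::tibble(
    stay_id = c("s1", "s2"),
    event_name = c("drug_a", "drug_a"),
    event_kind = "prescription",
    time_h = c(2, 4))
  ehr_dataset(stays, labs, events)
}

# small simulation config used across tests
quick_config <- function(seed = 1, n = 200, strength = 0.9, event_prob = 0.9,
                         n_null = 2, mortality = 0.49, noise = 0.02) {
  sim_config(
    n_patients = n,
    mortality_rate = mortality,
    textual_noise_rate = noise,
    labs = c(list(sim_lab("lactate", mean = 2, sd = 0.8)),
             lapply(seq_len(n_null), function(i) {
               sim_lab(paste0("null", i), mean = 5 * i, sd = i)
             })),
    events = list(sim_event("epinephrine", "prescription", event_prob),
                  sim_event("intubation", "procedure", 0.5)),
    planted_effects = list(
      planted_effect("lactate", "epinephrine", "increase", "decrease",
                     strength)),
    seed = seed)
}

# run the mining pipeline on a dataset with self-fitted default bins
mine_tables <- function(dataset, min_total = 11) {
  schemes <- fit_binning_schemes(dataset$labs)
  binned <- bin_lab_events(dataset$labs, schemes)
  instances <- extract_triplets(binned, dataset$events, dataset$stays)
  filter_by_support(cross_tabulate(instances, dataset$stays), min_total)
}

# independent brute-force mutual information: direct 6-term summation over
# integer count ratios, structured differently from the implementation
# (per-cell logs of integers rather than probability matrices)
mi_oracle <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  acc <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      nij <- counts[i, j]
      if (nij > 0) {
        acc <- acc + (nij / total) *
          (log(nij) + log(total) - log(sum(counts[i, ])) -
             log(sum(counts[, j])))
      }
    }
  }
  acc
}

# random non-degenerate 2x3 count table
random_table <- function() {
  repeat {
    counts <- matrix(sample(0:30, 6, replace = TRUE), nrow = 2)
    if (sum(counts) > 0) return(counts)
  }
}

# build a triplet-instance tibble realizing the given 2x3 counts
instances_from_counts <- function(counts, lab = "lab_a", event = "drug_c",
                                  kind = "prescription") {
  dirs <- c("no_change", "increasing", "decreasing")
  rows <- list()
  sid <- 0
  for (i in 1:2) {
    for (j in 1:3) {
      k <- counts[i, j]
      if (k > 0) {
        sid_new <- sid + seq_len(k)
        bin_before <- 3L
        bin_after <- switch(dirs[j], no_change = 3L, increasing = 5L,
                            decreasing = 1L)
        rows[[length(rows) + 1]] <- tibble::tibble(
          stay_id = sprintf("s%03d_%d", sid_new, i),
          lab_name = lab, event_name = event, event_kind = kind,
          t_event = 2, t_before = 1, bin_before = bin_before,
          t_after = 3, bin_after = bin_after, direction = dirs[j])
        sid <- sid + k
      }
    }
  }
  inst <- dplyr::bind_rows(rows)
  stays <- tibble::tibble(
    stay_id = inst$stay_id,
    died = as.integer(grepl("_2$", inst$stay_id)))
  list(instances = inst, stays = stays)
}
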