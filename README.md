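# triadml

Clinician-informed feature engineering for ICU mortality models:
**lab-event-lab triplet mining**, mutual-information ranking, expert
filtering, four nested feature encodings, and a model
complexity/accuracy/fidelity experiment harness — plus a synthetic ICU
cohort generator with plantable associations so the whole pipeline runs and
tests without access to any clinical database.

## What it computes

A *triplet* is a laboratory value captured immediately before and
immediately after a clinical event (prescription or procedure) within one
ICU stay. Lab values are discretized — expert bin boundaries where known,
otherwise six dividers at μ−2σ, μ−σ, μ−σ/2, μ+σ/2, μ+σ, μ+2σ — and each
triplet is categorized as *no change*, *increasing* or *decreasing* by
comparing the bin before and after the event. Per (lab, event) pair the
instances form a 2×3 contingency table against the in-hospital mortality
label, and tables with more than 10 instances are scored by mutual
information (natural log, maximum-likelihood frequencies):

    MI = Σ P(xy) · ln[ P(xy) / (P(x) P(y)) ]   ∈ [0, ln 2 ≈ 0.6931]

Triplets are ranked by MI per event kind; a laboratory's *composite
discriminative score* sums the MI of every triplet it appears in and ranks
the labs used as model features. Expert-labelled triplets define the
*filtered* lab set, and `precision_at_k()` measures how far MI ranking alone
agrees with the experts. The experiment harness builds the four nested
design matrices (Labs = f×48×5 hourly slot statistics; +demographics;
+event indicators; +an event-masked duplicate of the lab block) and fits
L1 logistic regression, gradient boosting, a neural network and
(un)weighted KNN under seeded cross-validated grids, reporting test AUC/ROC,
non-zero-coefficient complexity, signed fold changes and fidelity (ΔAUC
from the 42-feature baseline).

## Worked example

```r
library(triadml)

cfg <- sim_config(
  n_patients = 500,
  labs = c(list(sim_lab("lactate", mean = 2, sd = 0.8)),
           lapply(1:5, function(i) sim_lab(paste0("null", i), 10 * i, i))),
  events = list(sim_event("epinephrine", "prescription", 0.8),
                sim_event("intubation", "procedure", 0.4)),
  planted_effects = list(
    planted_effect("lactate", "epinephrine",
                   direction_if_died = "increase",
                   direction_if_survived = "decrease",
                   effect_strength = 0.9)),
  seed = 42)
d <- generate_cohort(cfg)
d
#> <ehr_dataset> 500 stays (253 died), 55560 lab events, 610 clinical events

binned <- bin_lab_events(d$labs, fit_binning_schemes(d$labs))
tables <- filter_by_support(
  cross_tabulate(extract_triplets(binned, d$events, d$stays), d$stays))
ranked <- rank_triplets(tables)
head(ranked[, c("lab_name", "event_name", "n_total", "mi_score", "rank")], 3)
#>   lab_name  event_name   n_total    mi_score rank
#> 1  lactate epinephrine       387 0.501999337    1
#> 2    null2 epinephrine       391 0.002999342    2
#> 3    null3 epinephrine       385 0.001884104    3

composite_lab_scores(ranked)[1:2, ]
#>   lab_name composite_score rank
#> 1  lactate     0.540981840    1
#> 2    null2     0.016232216    2
```

The planted lactate/epinephrine association dominates the ranking
(MI ≈ 0.50 against a null floor of ≈ 0.002–0.003), and lactate tops the
composite lab ranking — exactly the behaviour the MI score is meant to
deliver on a real cohort. Downstream:

```r
sp <- split_cohort(d, test_fraction = 0.2, seed = 1)
spec <- experiment_spec("logistic_regression",
                        labs = c("lactate", "null1"), subset = "Labs",
                        seed = 1)
run_experiment(spec, sp$train, sp$test)
#> <experiment_result> logistic_regression / Labs: AUC 0.847 (480 coefficients, 89 non-zero)
```

A command-line front end for the data pipeline ships in `inst/cli/triadml`
(`simulate`, `mine`, `rank` subcommands over CSV/YAML files).

## Documentation

The methods vignette (`vignettes/triplet-mining.Rmd`) describes the model,
its conventions (binning, tie-breaks, degenerate slots), the synthetic
generator's design and its limits, and the problem sizes the test suite
uses.
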