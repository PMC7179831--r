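#' Canonicalize laboratory result names with a synonym map
#'
#' Clinical sources record the same measurement under name variations,
#' abbreviations and misspellings ("pulse rate", "HR", "heat rate" for heart
#' rate). A synonym map collapses these onto one canonical name. Unmapped
#' names pass through unchanged, so the record count never changes.
#'
#' @param labs Lab-events tibble (`stay_id`, `lab_name`, `time_h`,
#'   `value_raw`).
#' @param synonym_map Named character vector or 2-column data frame
#'   (`raw_name`, `canonical_name`). Canonical names must be fixed points of
#'   the map.
#' @return `labs` with `lab_name` replaced by its canonical form.
#' @export
merge_lab_names <- function(labs, synonym_map) {
  map <- as_synonym_map(synonym_map)
  if (length(map) == 0) return(labs)
  hit <- match(labs$lab_name, names(map))
  labs$lab_name <- ifelse(is.na(hit), labs$lab_name, unname(map[hit]))
  labs
}

as_synonym_map <- function(synonym_map) {
  if (is.data.frame(synonym_map)) {
    check_columns(synonym_map, c("raw_name", "canonical_name"), "synonym map")
    map <- setNames(as.character(synonym_map$canonical_name),
                    as.character(synonym_map$raw_name))
  } else {
    map <- synonym_map
  }
  if (length(map) == 0) return(character())
  # canonical names must map to themselves (or be absent from the map)
  tgt <- unname(map[match(unname(map), names(map))])
  bad <- !is.na(tgt) & tgt != unname(map)
  if (any(bad)) {
    abort(sprintf("synonym map is not idempotent for canonical name(s): %s",
                  paste(unique(unname(map)[bad]), collapse = ", ")))
  }
  map
}

#' Read a synonym map from a 2-column CSV
#'
#' @param path CSV with columns `raw_name`, `canonical_name`.
#' @return Named character vector usable by [merge_lab_names()].
#' @export
read_synonym_map <- function(path) {
  df <- read_checked(path, readr::cols(raw_name = readr::col_character(),
                                       canonical_name = readr::col_character()),
                     c("raw_name", "canonical_name"), "synonym map")
  as_synonym_map(df)
}

#' Coerce raw laboratory value strings to numbers
#'
#' Plain numerals parse to their value; comparator-prefixed strings
#' (`"≤1"`, `"≥5"`, `"<0.2"`, `">300"`, `"<=1"`, `">=5"`) parse to
#' their numeral; anything else non-numeric (e.g. `"error"`) becomes `NA` and
#' is ignored downstream. Total function: never raises.
#'
#' @param value_raw Character vector of raw values.
#' @return Numeric vector with `NA` for unconvertible entries.
#' @export
coerce_lab_values <- function(value_raw) {
  x <- trimws(as.character(value_raw))
  x <- sub("^(≤|≥|<=|>=|<|>)\\s*", "", x)
  suppressWarnings(as.numeric(x))
}

#' Binning scheme for one laboratory test
#'
#' A set of strictly increasing dividers cutting the real line into
#' `length(dividers) + 1` bins. Schemes come either from a clinical expert
#' (known normal ranges) or from the default mean/SD construction of
#' [default_dividers()].
#'
#' @param lab_name Laboratory name the scheme applies to.
#' @param dividers Strictly increasing numeric boundaries.
#' @param source `"expert"` or `"default"`.
#' @param mu,sigma Sample mean/SD backing a default scheme (optional for
#'   expert schemes).
#' @return Object of class `binning_scheme`.
#' @export
binning_scheme <- function(lab_name, dividers, source = c("expert", "default"),
                           mu = NA_real_, sigma = NA_real_) {
  source <- match.arg(source)
  dividers <- as.numeric(dividers)
  if (length(dividers) < 1 || any(diff(dividers) <= 0)) {
    abort(sprintf("dividers for lab `%s` must be strictly increasing", lab_name))
  }
  structure(list(lab_name = lab_name, dividers = dividers, source = source,
                 mu = mu, sigma = sigma),
            class = "binning_scheme")
}

#' @exportS3Method base::print
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %s (%s): %s\n", x$lab_name, x$source,
              paste(signif(x$dividers, 4), collapse = ", ")))
  invisible(x)
}

#' Default mean/SD dividers for a laboratory test
#'
#' When no expert normal ranges are known, six dividers are placed at
#' mu - 2s, mu - s, mu - s/2, mu + s/2, mu + s, mu + 2s, giving seven bins.
#' `sigma` uses the unbiased (n-1) estimator.
#'
#' @param values Numeric sample of cleaned values (at least two distinct).
#' @param lab_name Laboratory name recorded on the scheme.
#' @return A [binning_scheme()] with `source = "default"`.
#' @export
default_dividers <- function(values, lab_name = "lab") {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort(sprintf("lab `%s`: need at least 2 values to place default dividers",
                  lab_name))
  }
  mu <- mean(values)
  sigma <- sd(values)
  if (!is.finite(sigma) || sigma == 0) {
    abort(sprintf("lab `%s`: degenerate sample (sd = 0), cannot place dividers",
                  lab_name))
  }
  binning_scheme(lab_name,
                 mu + sigma * c(-2, -1, -0.5, 0.5, 1, 2),
                 source = "default", mu = mu, sigma = sigma)
}

#' Assign values to bins
#'
#' Bins are half-open, closed on the left: a value equal to a divider falls
#' in the upper bin. Indices are 0-based, 0 below the first divider up to
#' `length(dividers)` above the last; the assignment is non-decreasing in the
#' value.
#'
#' @param values Numeric vector (no `NA`).
#' @param scheme A [binning_scheme()] or a plain numeric vector of dividers.
#' @return Integer vector of 0-based bin indices.
#' @export
assign_bin <- function(values, scheme) {
  dividers <- if (inherits(scheme, "binning_scheme")) scheme$dividers else scheme
  findInterval(values, dividers)
}

#' Fit binning schemes for every laboratory in a lab-events table
#'
#' Expert schemes take precedence per lab; labs without an expert entry fall
#' back to [default_dividers()] computed on their cleaned numeric values
#' (typically of the training split, to avoid leaking test information).
#'
#' @param labs Lab-events tibble; `value_raw` is coerced via
#'   [coerce_lab_values()] and `NA`s dropped.
#' @param expert Optional list of [binning_scheme()]s (e.g. from
#'   [read_expert_bins()]).
#' @return Named list of [binning_scheme()]s, one per lab present.
#' @export
fit_binning_schemes <- function(labs, expert = NULL) {
  expert_names <- vapply(expert, function(s) s$lab_name, character(1))
  values <- coerce_lab_values(labs$value_raw)
  out <- list()
  for (lab in sort(unique(labs$lab_name))) {
    if (lab %in% expert_names) {
      out[[lab]] <- expert[[match(lab, expert_names)]]
    } else {
      out[[lab]] <- default_dividers(values[labs$lab_name == lab & !is.na(values)],
                                     lab_name = lab)
    }
  }
  out
}

#' Read expert bin boundaries from CSV
#'
#' Variable-width format: `lab_name, divider_1, divider_2, ...`; trailing
#' empty cells allowed so labs may have different bin counts.
#'
#' @param path CSV path.
#' @return List of [binning_scheme()]s with `source = "expert"`.
#' @export
read_expert_bins <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    lab_name = readr::col_character(), .default = readr::col_double()),
    show_col_types = FALSE)
  check_columns(df, "lab_name", "expert bins")
  lapply(seq_len(nrow(df)), function(i) {
    dividers <- as.numeric(df[i, -1])
    binning_scheme(df$lab_name[i], dividers[!is.na(dividers)], source = "expert")
  })
}

#' Clean, coerce and bin a lab-events table
#'
#' The standard preparation pass before triplet mining: names merged, raw
#' values coerced, unconvertible entries dropped, and each value assigned its
#' bin under the per-lab scheme.
#'
#' @param labs Lab-events tibble.
#' @param schemes Named list of [binning_scheme()]s (see
#'   [fit_binning_schemes()]); every lab in `labs` must have a scheme.
#' @param synonym_map Optional synonym map applied first.
#' @return `labs` with added numeric `value` and integer `bin` columns,
#'   unconvertible rows removed.
#' @export
bin_lab_events <- function(labs, schemes, synonym_map = NULL) {
  if (!is.null(synonym_map)) labs <- merge_lab_names(labs, synonym_map)
  labs$value <- coerce_lab_values(labs$value_raw)
  labs <- labs[!is.na(labs$value), ]
  missing <- setdiff(unique(labs$lab_name), names(schemes))
  if (length(missing) > 0) {
    abort(sprintf("no binning scheme for lab(s): %s",
                  paste(missing, collapse = ", ")))
  }
  labs$bin <- NA_integer_
  for (lab in unique(labs$lab_name)) {
    idx <- labs$lab_name == lab
    labs$bin[idx] <- assign_bin(labs$value[idx], schemes[[lab]])
  }
  labs
}
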