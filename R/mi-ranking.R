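#' Mutual-information score of an outcome-by-direction table
#'
#' Measures the marginal association between the binary mortality outcome and
#' the three-way direction category of a triplet, as the mutual information
#' of the 2x3 contingency table under maximum-likelihood cell frequencies:
#' the sum over cells of P(xy) * ln(P(xy) / (P(x) P(y))), with the usual
#' convention that empty cells contribute 0. Natural logarithm, so the score
#' is bounded by ln 2 (~0.6931), attained when the direction column
#' determines the outcome row exactly at balanced margins. No smoothing is
#' applied.
#'
#' @param counts 2x3 (or generally r x c) non-negative count matrix, rows =
#'   outcome groups, columns = direction categories.
#' @return Mutual information in nats.
#' @export
mi_score <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) abort("all-zero contingency table")
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  expected <- outer(px, py)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / expected[pos]))
}

# vectorized MI over the 6 count columns of a cross-tabulation tibble
mi_score_rows <- function(tables) {
  if (nrow(tables) == 0) return(numeric())
  m <- as.matrix(tables[, cell_cols()])
  vapply(seq_len(nrow(m)),
         function(i) mi_score(matrix(m[i, ], nrow = 2, byrow = TRUE)),
         numeric(1))
}

#' Rank triplet tables by MI score
#'
#' Scores every table and ranks descending separately within each event kind
#' (prescriptions and procedures are reviewed as separate lists). Ties are
#' broken by (lab_name, event_name) lexicographic order, so rankings are
#' deterministic across runs.
#'
#' @param tables Cross-tabulation tibble, typically after
#'   [filter_by_support()].
#' @return `tables` with added `mi_score` and within-kind 1-based `rank`,
#'   ordered by kind then rank.
#' @export
rank_triplets <- function(tables) {
  tables$mi_score <- mi_score_rows(tables)
  tables <- dplyr::arrange(tables, .data$event_kind,
                           dplyr::desc(.data$mi_score),
                           .data$lab_name, .data$event_name)
  dplyr::mutate(dplyr::group_by(tables, .data$event_kind),
                rank = dplyr::row_number()) |> dplyr::ungroup()
}

#' Composite discriminative score per laboratory
#'
#' A laboratory's score is the sum of MI scores over every triplet in which
#' it appears, pooled across both event kinds (the score feeds a single
#' feature ranking). Sorted descending, ties broken by lab name.
#'
#' @param ranked Ranked triplets from [rank_triplets()] (any tibble with
#'   `lab_name` and `mi_score`).
#' @return Tibble `lab_name`, `composite_score`, `rank`.
#' @export
composite_lab_scores <- function(ranked) {
  if (nrow(ranked) == 0) {
    return(tibble::tibble(lab_name = character(), composite_score = numeric(),
                          rank = integer()))
  }
  out <- dplyr::summarise(dplyr::group_by(ranked, .data$lab_name),
                          composite_score = sum(.data$mi_score),
                          .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$composite_score),
                        .data$lab_name)
  out$rank <- seq_len(nrow(out))
  out
}

#' Expert relevance labels for mined triplets
#'
#' The set of (lab_name, event_name) keys that clinical experts marked as
#' meaningful for the case study. Keys must reference mined triplets.
#'
#' @param labels Tibble/data frame with columns `lab_name`, `event_name`.
#' @param tables Mined cross-tabulation tibble the labels must refer to.
#' @return Validated tibble of keys, class `expert_labels`.
#' @export
expert_labels <- function(labels, tables) {
  labels <- tibble::as_tibble(labels)
  check_columns(labels, c("lab_name", "event_name"), "expert labels")
  labels <- dplyr::distinct(labels[, c("lab_name", "event_name")])
  key <- function(df) paste(df$lab_name, df$event_name, sep = "\r")
  unknown <- !key(labels) %in% key(tables)
  if (any(unknown)) {
    abort(sprintf("expert label(s) reference unmined triplet(s): %s",
                  paste(paste(labels$lab_name[unknown],
                              labels$event_name[unknown], sep = " / "),
                        collapse = "; ")))
  }
  class(labels) <- c("expert_labels", class(labels))
  labels
}

#' Read expert triplet-relevance labels from CSV
#'
#' @param path CSV with columns `lab_name`, `event_name`.
#' @param tables Mined tables the labels must refer to.
#' @return An [expert_labels()] tibble.
#' @export
read_expert_labels <- function(path, tables) {
  df <- read_checked(path, readr::cols(lab_name = readr::col_character(),
                                       event_name = readr::col_character()),
                     c("lab_name", "event_name"), "expert labels")
  expert_labels(df, tables)
}

#' Filter triplets and laboratories by expert relevance
#'
#' Keeps only the expert-labelled triplets and reports the distinct
#' laboratories represented among them — the "filtered features" used by the
#' clinical-input-informed models.
#'
#' @param tables Mined cross-tabulation tibble (may carry `mi_score`).
#' @param labels An [expert_labels()] set.
#' @return List with `triplets` (subset of `tables`) and `labs` (sorted
#'   character vector of distinct laboratory names).
#' @export
apply_expert_filter <- function(tables, labels) {
  labels <- expert_labels(labels, tables)
  key <- paste(tables$lab_name, tables$event_name, sep = "\r")
  keep <- key %in% paste(labels$lab_name, labels$event_name, sep = "\r")
  filtered <- tables[keep, ]
  list(triplets = filtered, labs = sort(unique(filtered$lab_name)))
}

#' Precision of the MI ranking at depth k
#'
#' Fraction of the top-k MI-ranked triplets that experts marked clinically
#' meaningful: |top-k intersect labels| / k.
#'
#' @param ranked One event kind's ranked list from [rank_triplets()] (must
#'   carry a single, complete `rank` sequence).
#' @param labels An [expert_labels()] set (or tibble of keys).
#' @param k Depth, between 1 and `nrow(ranked)`.
#' @return Precision in `[0, 1]`.
#' @export
precision_at_k <- function(ranked, labels, k) {
  if (length(k) != 1 || k < 1 || k > nrow(ranked)) {
    abort(sprintf("k must be in [1, %d]", nrow(ranked)))
  }
  if (length(unique(ranked$event_kind)) > 1) {
    abort("precision_at_k expects a single event kind's ranked list")
  }
  top <- ranked[order(ranked$rank), ][seq_len(k), ]
  key <- paste(top$lab_name, top$event_name, sep = "\r")
  lab_key <- paste(labels$lab_name, labels$event_name, sep = "\r")
  sum(key %in% lab_key) / k
}
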