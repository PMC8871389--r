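# Partition of the proteome into aggregation fractions and
# cross-experiment overlap summaries.

fraction_levels <- c("increased", "decreased", "baseline",
                     "other_aggregate", "nia")

#' Proteins not identified as aggregating (NIA)
#'
#' The NIA background consists of every protein identified only in the
#' whole-cell lysate and never in any SDS-insoluble aggregate fraction.
#'
#' @param wcl_ids Identifiers detected in the WCL.
#' @param aggregate_ids Identifiers detected in any aggregate-fraction
#'   experiment.
#' @return Character vector of NIA identifiers.
#' @export
define_nia <- function(wcl_ids, aggregate_ids) {
  assert_that(length(wcl_ids) > 0, "WCL identifier set is empty",
              "invalid_input")
  out <- setdiff(wcl_ids, aggregate_ids)
  if (length(out) == 0) rlang::warn("NIA set is empty: aggregate covers WCL")
  out
}

#' Baseline-aggregating fraction
#'
#' Aggregating proteins unchanged by the treatment: detected in at least
#' `min_reps` replicates of both treated and untreated aggregate fractions
#' and with a BH-adjusted p-value above `alpha`.
#'
#' @param results A called differential tibble (see [call_differential()]).
#' @param min_reps Minimum detections per condition (default 2).
#' @param alpha Adjusted-p cutoff; baseline requires `p_adjusted > alpha`
#'   (default 0.05).
#' @return Character vector of baseline identifiers.
#' @export
define_baseline <- function(results, min_reps = 2, alpha = 0.05) {
  keep <- results$n_detected_case >= min_reps &
    results$n_detected_control >= min_reps &
    results$p_adjusted > alpha
  results$id[keep]
}

#' Classify the proteome into aggregation fractions
#'
#' Labels every protein seen in the experiment: `increased` / `decreased`
#' from the differential calls (calls take precedence over the baseline
#' rule), `baseline` per [define_baseline()] minus called proteins,
#' `other_aggregate` for aggregate-detected proteins matching neither rule,
#' and `nia` for WCL-only proteins. The labels partition the union of WCL
#' and aggregate identifiers.
#'
#' @param results A called differential tibble for the aggregate fraction.
#' @param wcl_ids Identifiers detected in the WCL.
#' @param min_reps,alpha Passed to [define_baseline()].
#' @param aggregate_ids All identifiers ever detected in an aggregate
#'   fraction (default: the tested proteins). Supply the full detection list
#'   when the differential stage prefiltered proteins seen in only one
#'   replicate, so those still count as aggregate-detected rather than NIA.
#' @return A tibble `id`, `label` (factor), classed `"fraction_labels"`.
#' @export
classify_fractions <- function(results, wcl_ids, min_reps = 2,
                               alpha = 0.05,
                               aggregate_ids = results$id) {
  agg_ids <- unique(c(results$id, aggregate_ids))
  assert_that(!anyDuplicated(agg_ids),
              "duplicate identifiers in differential results",
              "invalid_input")
  up <- results$id[results$call == "up"]
  down <- results$id[results$call == "down"]
  base <- setdiff(define_baseline(results, min_reps, alpha), c(up, down))
  other <- setdiff(agg_ids, c(up, down, base))
  nia <- setdiff(wcl_ids, agg_ids)
  out <- tibble(
    id = c(up, down, base, other, nia),
    label = factor(rep(fraction_levels,
                       times = c(length(up), length(down), length(base),
                                 length(other), length(nia))),
                   levels = fraction_levels)
  )
  if (anyDuplicated(out$id)) {
    stop_agg("internal error: protein assigned two fraction labels",
             "internal")
  }
  class(out) <- c("fraction_labels", class(out))
  out
}

#' Overlap between two identifier sets
#'
#' @param a,b Character vectors of reconciled identifiers.
#' @return One-row tibble: `size_a`, `size_b`, `intersection_size`,
#'   `fraction_of_a`, `fraction_of_b`.
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  tibble(size_a = length(a), size_b = length(b), intersection_size = i,
         fraction_of_a = if (length(a) > 0) i / length(a) else 0,
         fraction_of_b = if (length(b) > 0) i / length(b) else 0)
}

#' Cross-replicate consistency of identifier sets
#'
#' Mean, over all ordered pairs of sets, of the fraction of the first set
#' recovered in the second — a directional overlap summarising how
#' consistently the same proteins are recovered across repeat experiments.
#'
#' @param replicate_sets List of at least two non-empty identifier vectors.
#' @return A number in `[0, 1]`.
#' @export
consistency_metric <- function(replicate_sets) {
  assert_that(length(replicate_sets) >= 2, "need at least 2 sets",
              "invalid_input")
  assert_that(all(lengths(replicate_sets) > 0), "empty set supplied",
              "invalid_input")
  sets <- lapply(replicate_sets, unique)
  pairs <- expand.grid(i = seq_along(sets), j = seq_along(sets))
  pairs <- pairs[pairs$i != pairs$j, ]
  mean(mapply(function(i, j) {
    length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
  }, pairs$i, pairs$j))
}
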