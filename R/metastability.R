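# Sequence propensity scoring, supersaturation against the WCL-median
# threshold, and per-fraction score summaries.
#
# The shipped residue scales are deliberately simple, versioned
# approximations: the aggregation scale rewards hydrophobic/beta-prone
# residues and penalises charge; the LLPS scale rewards disorder-promoting
# composition and R/G/Y/F (pi-pi and cation-pi) content. Imported predictor
# outputs (TANGO, CamSol, catGRANULE, PScore) supplied via a score table are
# always authoritative over these built-ins.

scale_checksums <- c(
  aggregation = "b5a9f64fe0c72ef93074d0d17fd4978e",
  llps = "437430d2647f0249726bc77a2a2be202"
)

#' Load a shipped residue propensity scale
#'
#' @param name `"aggregation"` or `"llps"`.
#' @return Named numeric vector, one value per residue (including `X` = 0).
#' @export
propensity_scale <- function(name = c("aggregation", "llps")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scales", paste0(name, "_scale.tsv"),
                      package = "aggregomics", mustWork = TRUE)
  sum_ok <- is.na(scale_checksums[name]) ||
    unname(tools::md5sum(path)) == scale_checksums[name]
  if (!isTRUE(sum_ok)) {
    rlang::warn(sprintf("checksum mismatch for shipped scale '%s'", name))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  setNames(tab$value, tab$residue)
}

#' Sliding-window propensity profile
#'
#' Scores a sequence with a per-residue scale using a sliding-window mean,
#' and summarises the profile as
#' `mean(positive window scores) * (number of positive windows / number of
#' windows)` — rewarding both the intensity and the extent of high-scoring
#' regions. A profile with no positive window summarises to 0.
#'
#' @param seq Amino-acid sequence (single string).
#' @param scale Named numeric vector residue -> value; unknown residues
#'   score 0 with a warning.
#' @param window Window length (default 7).
#' @return List with `scores` (window scores, length
#'   `nchar(seq) - window + 1`), `summary`, and `window`.
#' @export
windowed_propensity <- function(seq, scale, window = 7) {
  assert_that(window >= 1, "window must be >= 1", "config")
  res <- strsplit(toupper(seq), "")[[1]]
  assert_that(length(res) >= window, "sequence shorter than window",
              "invalid_input")
  v <- unname(scale[res])
  if (anyNA(v)) {
    rlang::warn(sprintf("%d residue(s) not in scale; scored 0",
                        sum(is.na(v))))
    v[is.na(v)] <- 0
  }
  cs <- c(0, cumsum(v))
  nw <- length(res) - window + 1
  scores <- (cs[(window + 1):(length(res) + 1)] - cs[1:nw]) / window
  pos <- scores > 0
  summary <- if (any(pos)) mean(scores[pos]) * mean(pos) else 0
  list(scores = scores, summary = summary, window = window)
}

#' Built-in aggregation propensity
#'
#' Simplified sequence aggregation propensity (hydrophobic/beta-prone
#' stretches, charge penalised). A stand-in scored on the shipped scale;
#' import real predictor outputs via [read_score_table()] when available.
#'
#' @param seq Amino-acid sequence.
#' @param window Window length (default 7).
#' @return A single numeric score.
#' @export
aggregation_propensity_builtin <- function(seq, window = 7) {
  windowed_propensity(seq, propensity_scale("aggregation"), window)$summary
}

#' Built-in liquid-liquid phase separation propensity
#'
#' Simplified LLPS propensity emphasising disorder-promoting composition
#' and R/G/Y/F content.
#'
#' @inheritParams aggregation_propensity_builtin
#' @return A single numeric score.
#' @export
llps_propensity_builtin <- function(seq, window = 7) {
  windowed_propensity(seq, propensity_scale("llps"), window)$summary
}

#' Score a set of sequences
#'
#' @param seqs Named character vector of sequences (see
#'   [read_sequences()]).
#' @param type `"aggregation"` or `"llps"`.
#' @param window Window length (default 7).
#' @return Tibble `id`, `score`.
#' @export
propensity_scores <- function(seqs, type = c("aggregation", "llps"),
                              window = 7) {
  type <- match.arg(type)
  scale <- propensity_scale(type)
  tibble(id = names(seqs),
         score = vapply(seqs, function(s) {
           windowed_propensity(s, scale, window)$summary
         }, numeric(1), USE.NAMES = FALSE))
}

#' Z-standardise scores against a reference set
#'
#' Centres and scales all scores by the mean and SD computed over the
#' reference identifiers only (typically the whole-cell lysate proteome),
#' placing propensity and abundance on one comparable axis.
#'
#' @param scores Named numeric vector id -> score.
#' @param reference_ids Identifiers defining the reference distribution
#'   (default: all ids).
#' @return Named numeric vector of z-scores.
#' @export
zscore_normalize <- function(scores, reference_ids = names(scores)) {
  ref <- scores[names(scores) %in% reference_ids]
  assert_that(length(ref) >= 2, "reference set must have >= 2 scores",
              "invalid_input")
  s <- sd(ref)
  assert_that(is.finite(s) && s > 0, "reference scores have zero variance",
              "invalid_input")
  (scores - mean(ref)) / s
}

#' Supersaturation score
#'
#' A protein is supersaturated when it is abundant relative to its intrinsic
#' aggregation propensity. The score combines the two on a common axis:
#' `sigma = log10(abundance + pseudocount) + z_propensity`.
#'
#' @param z_propensity Standardised aggregation propensity.
#' @param transcript_abundance Nonnegative abundance (e.g. CPM).
#' @param pseudocount Positive pseudocount (default 1).
#' @return Numeric sigma (vectorised).
#' @export
supersaturation <- function(z_propensity, transcript_abundance,
                            pseudocount = 1) {
  assert_that(pseudocount > 0, "pseudocount must be > 0", "config")
  assert_that(all(transcript_abundance >= 0),
              "abundance must be nonnegative", "invalid_input")
  log10(transcript_abundance + pseudocount) + z_propensity
}

#' Median saturation threshold
#'
#' The iso-sigma diagonal above which proteins are called relatively
#' supersaturated: the median sigma of the reference (WCL) proteome.
#'
#' @param sigma_values Numeric vector of reference sigma values.
#' @return The median (even-length ties by midpoint).
#' @export
saturation_threshold <- function(sigma_values) {
  v <- sigma_values[is.finite(sigma_values)]
  assert_that(length(v) >= 1, "no finite sigma values", "invalid_input")
  median(v)
}

#' Per-protein supersaturation against the WCL median
#'
#' Standardises propensity over the reference set, combines it with
#' transcript abundance into sigma, computes the reference-median threshold
#' tau, and flags proteins with `sigma > tau` as supersaturated.
#'
#' @param propensity Tibble `id`, `score` (built-in or imported propensity).
#' @param abundance Tibble `id`, `abundance` on a normalised scale (e.g.
#'   mean CPM).
#' @param reference_ids Identifiers of the reference (WCL) proteome used for
#'   both the z-standardisation and the median threshold.
#' @param pseudocount Abundance pseudocount (default 1).
#' @return Tibble `id`, `z_propensity`, `log_abundance`, `sigma`,
#'   `supersaturated`, with the threshold attached as attribute `"tau"`.
#' @export
supersaturation_scores <- function(propensity, abundance,
                                   reference_ids = propensity$id,
                                   pseudocount = 1) {
  joined <- dplyr::inner_join(propensity, abundance, by = "id")
  assert_that(nrow(joined) > 0, "no shared identifiers", "invalid_input")
  z <- zscore_normalize(setNames(joined$score, joined$id), reference_ids)
  sigma <- supersaturation(z, joined$abundance, pseudocount)
  tau <- saturation_threshold(sigma[joined$id %in% reference_ids])
  out <- tibble(id = joined$id,
                z_propensity = unname(z),
                log_abundance = log10(joined$abundance + pseudocount),
                sigma = unname(sigma),
                supersaturated = unname(sigma) > tau)
  attr(out, "tau") <- tau
  out
}

#' Summarise scores per aggregation fraction
#'
#' Per-fraction mean and median of a score, and — when a threshold is given
#' (e.g. the high-LLPS PScore cutoff of 4) — the fraction of proteins above
#' it.
#'
#' @param scores Named numeric vector id -> score.
#' @param labels A [classify_fractions()] tibble.
#' @param threshold Optional score cutoff.
#' @return Tibble per fraction: `label`, `n`, `mean`, `median`, and
#'   `fraction_above` when a threshold is given. Fractions with no scored
#'   protein are omitted with a warning.
#' @export
fraction_score_summary <- function(scores, labels, threshold = NULL) {
  tab <- labels
  tab$score <- unname(scores[match(tab$id, names(scores))])
  missing_frac <- setdiff(unique(as.character(tab$label)),
                          unique(as.character(tab$label[!is.na(tab$score)])))
  if (length(missing_frac) > 0) {
    rlang::warn(paste0("fraction(s) with no scored proteins omitted: ",
                       paste(missing_frac, collapse = ", ")))
  }
  tab <- tab[!is.na(tab$score), , drop = FALSE]
  out <- tab %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     median = median(.data$score), .groups = "drop")
  if (!is.null(threshold)) {
    above <- tab %>%
      dplyr::group_by(.data$label) %>%
      dplyr::summarise(fraction_above = mean(.data$score > threshold),
                       .groups = "drop")
    out <- dplyr::left_join(out, above, by = "label")
    attr(out, "threshold") <- threshold
  }
  out
}
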