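# Differential aggregation from label-free quantification:
# log2 transform -> detection prefilter -> averaged downshifted-Gaussian
# imputation -> per-protein t-tests -> BH correction -> replicate-gated calls.

#' Log2-transform LFQ intensities and count detections
#'
#' @param table A filtered protein-group tibble (see
#'   [filter_contaminants_reverse()]).
#' @param design A [sample_design()] tibble naming the intensity columns to
#'   use (typically the aggregate-fraction samples of one experiment).
#' @return A tibble `id`, `n_detected_case`, `n_detected_control` plus one
#'   log2-intensity column per sample (`NA` = not detected), with the design
#'   attached as attribute `"design"`.
#' @export
log2_transform <- function(table, design = attr(table, "design")) {
  assert_that(!is.null(design), "a sample design is required", "design")
  assert_that(all(design$sample %in% names(table)),
              "design samples missing from table", "design")
  m <- as.matrix(table[, design$sample, drop = FALSE])
  if (any(m == 0, na.rm = TRUE)) {
    stop_agg("intensity of exactly 0 reached log2_transform; zeros must be NA",
             "internal")
  }
  lm <- log2(m)
  case_cols <- design$sample[design$condition == "case"]
  ctrl_cols <- design$sample[design$condition == "control"]
  out <- tibble(
    id = table$id,
    n_detected_case = as.integer(
      rowSums(!is.na(lm[, case_cols, drop = FALSE]))),
    n_detected_control = as.integer(
      rowSums(!is.na(lm[, ctrl_cols, drop = FALSE])))
  )
  for (s in design$sample) out[[s]] <- lm[, s]
  attr(out, "design") <- design
  out
}

#' Keep proteins identified in enough replicates
#'
#' Retains proteins detected in at least `min_repeats` replicates of either
#' condition (the "identified in >1 repeats" volcano-plot gate).
#'
#' @param matrix A [log2_transform()] tibble.
#' @param min_repeats Minimum detections in case OR control (default 2).
#' @return The filtered tibble.
#' @export
prefilter_identified <- function(matrix, min_repeats = 2) {
  keep <- matrix$n_detected_case >= min_repeats |
    matrix$n_detected_control >= min_repeats
  out <- matrix[keep, , drop = FALSE]
  attr(out, "design") <- attr(matrix, "design")
  out
}

#' Impute missing log2 intensities by averaged downshifted Gaussians
#'
#' Missing (non-detected) values are assumed missing-not-at-random: low
#' intensities fall below the detection limit. Each missing cell in sample
#' *j* is drawn from `Normal(mu_j - downshift * sd_j, (width * sd_j)^2)`
#' where `mu_j`, `sd_j` are the observed mean and SD of sample *j*; this is
#' repeated `n_draws` times and the completed matrices are averaged
#' cell-wise. Observed values are never altered.
#'
#' Each draw `d` re-seeds the generator from `seed + d` and draws a value
#' for every cell of the matrix, so the value imputed into cell `(i, j)` is
#' a pure function of `(seed, d, i, j)` — independent of the missingness
#' pattern and of iteration order.
#'
#' @param matrix A [log2_transform()] tibble (optionally prefiltered).
#' @param n_draws Number of imputation draws to average (default 100).
#' @param downshift Downshift of the imputation distribution, in units of
#'   the per-sample SD (default 1.8).
#' @param width Width of the imputation distribution in per-sample SD units
#'   (default 0.3).
#' @param seed Integer seed.
#' @return The completed tibble (no `NA` intensities); which cells were
#'   imputed is retained in the detection-count columns.
#' @export
impute_missing <- function(matrix, n_draws = 100, downshift = 1.8,
                           width = 0.3, seed = 1L) {
  assert_that(n_draws >= 1, "n_draws must be >= 1", "config")
  assert_that(width > 0, "width must be > 0", "config")
  design <- attr(matrix, "design")
  assert_that(!is.null(design), "a sample design is required", "design")
  m <- as.matrix(matrix[, design$sample, drop = FALSE])
  miss <- is.na(m)
  if (!any(miss)) return(matrix)

  n_obs <- colSums(!miss)
  mu <- colMeans(m, na.rm = TRUE)
  sig <- apply(m, 2, sd, na.rm = TRUE)
  thin <- n_obs < 2
  if (any(thin)) {
    rlang::warn(sprintf(
      "%d sample(s) with <2 observed values; using global mean/SD",
      sum(thin)))
    g_mu <- mean(m, na.rm = TRUE)
    g_sd <- sd(as.vector(m), na.rm = TRUE)
    mu[thin] <- g_mu
    sig[thin] <- g_sd
  }

  np <- nrow(m); ns <- ncol(m)
  centre <- matrix(mu - downshift * sig, np, ns, byrow = TRUE)
  scale_ <- matrix(width * sig, np, ns, byrow = TRUE)
  acc <- matrix(0, np, ns)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (d in seq_len(n_draws)) {
    set.seed(as_seed(seed + d))
    acc <- acc + matrix(rnorm(np * ns), np, ns)
  }
  imputed <- centre + scale_ * (acc / n_draws)
  m[miss] <- imputed[miss]
  out <- matrix
  for (k in seq_len(ns)) out[[design$sample[k]]] <- m[, k]
  attr(out, "design") <- design
  out
}

# vectorised per-row two-sample t-test (matches stats::t.test)
row_t_test <- function(x, y, var_equal = FALSE) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  if (var_equal) {
    sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(mx))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  t[se == 0 & mx == my] <- 0
  df[se == 0] <- nx + ny - 2
  p <- 2 * pt(-abs(t), df)
  p[is.na(p) & !is.na(t)] <- 1
  list(mean_x = mx, mean_y = my, t = t, df = df, p = p)
}

#' Per-protein t-tests on a complete log2 matrix
#'
#' Two-sided t-test per protein, case vs control, on the (imputation
#' averaged) log2 LFQ intensities. `log2fc` is the mean case intensity minus
#' the mean control intensity. Welch's unequal-variance test is the default;
#' `var_equal = TRUE` gives the classical Student test.
#'
#' @param matrix A complete [impute_missing()] tibble.
#' @param design Sample design (defaults to the attached one).
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @return A tibble: `id`, `mean_case`, `mean_control`, `log2fc`,
#'   `t_statistic`, `p_value`, `n_detected_case`, `n_detected_control`.
#' @export
differential_test <- function(matrix, design = attr(matrix, "design"),
                              var_equal = FALSE) {
  assert_that(!is.null(design), "a sample design is required", "design")
  case_cols <- design$sample[design$condition == "case"]
  ctrl_cols <- design$sample[design$condition == "control"]
  assert_that(length(case_cols) >= 2 && length(ctrl_cols) >= 2,
              "at least 2 replicates per condition are required", "design")
  x <- as.matrix(matrix[, case_cols, drop = FALSE])
  y <- as.matrix(matrix[, ctrl_cols, drop = FALSE])
  assert_that(!anyNA(x) && !anyNA(y),
              "matrix must be complete (impute first)", "internal")
  tt <- row_t_test(x, y, var_equal = var_equal)
  tibble(
    id = matrix$id,
    mean_case = tt$mean_x,
    mean_control = tt$mean_y,
    log2fc = tt$mean_x - tt$mean_y,
    t_statistic = tt$t,
    p_value = tt$p,
    n_detected_case = matrix$n_detected_case,
    n_detected_control = matrix$n_detected_control
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving with
#' the input indexing and clipped to 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]", "invalid_input")
  p.adjust(p_values, method = "BH")
}

#' Call differential aggregation
#'
#' Applies the replicate-gated significance rule: a protein is called `up`
#' when its BH-adjusted p-value is at most `alpha`, its log2 fold change is
#' at least `lfc_threshold`, and it was detected (non-imputed) in at least
#' `min_nonimputed` case replicates; `down` is the mirror rule on the
#' control side. Everything else is `ns`. The detection gate mitigates
#' imputation-induced artifacts among significant proteins.
#'
#' @param results A [differential_test()] tibble.
#' @param alpha Significance level on the adjusted p-value (default 0.05,
#'   inclusive).
#' @param lfc_threshold Log2 fold-change threshold (default 1, inclusive).
#' @param min_nonimputed Minimum replicates with non-imputed data (default
#'   2).
#' @return The tibble with `p_adjusted` and `call` (`up`/`down`/`ns`) added.
#' @export
call_differential <- function(results, alpha = 0.05, lfc_threshold = 1,
                              min_nonimputed = 2) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)", "config")
  assert_that(lfc_threshold >= 0 && min_nonimputed >= 0,
              "thresholds must be >= 0", "config")
  res <- results
  if (!("p_adjusted" %in% names(res))) {
    res$p_adjusted <- adjust_bh(res$p_value)
  }
  res$call <- dplyr::case_when(
    res$p_adjusted <= alpha & res$log2fc >= lfc_threshold &
      res$n_detected_case >= min_nonimputed ~ "up",
    res$p_adjusted <= alpha & res$log2fc <= -lfc_threshold &
      res$n_detected_control >= min_nonimputed ~ "down",
    TRUE ~ "ns"
  )
  res
}

#' Full differential-aggregation analysis
#'
#' Runs the complete label-free differential stage on one experiment:
#' contaminant-filtered intensities are log2-transformed, proteins detected
#' in fewer than `min_identified_repeats` replicates of both conditions are
#' dropped, missing values are imputed `n_draws` times with a downshifted
#' Gaussian and averaged, per-protein t-tests are BH-corrected, and
#' replicate-gated up/down calls are made.
#'
#' @inheritParams log2_transform
#' @inheritParams impute_missing
#' @inheritParams differential_test
#' @inheritParams call_differential
#' @param min_identified_repeats Detection prefilter (default 2 = "identified
#'   in >1 repeats" of either condition).
#' @return An object of class `"aggdiff"`; use [tidy()] for the per-protein
#'   table, [glance()] for a one-row summary, [autoplot()] for a volcano
#'   plot.
#' @examples
#' sim <- simulate_experiment(n_proteins = 200, n_planted = 20, seed = 7)
#' fit <- differential_aggregation(sim$protein_groups, sim$design_aggregate,
#'                                 seed = 7)
#' glance(fit)
#' @export
differential_aggregation <- function(table,
                                     design = attr(table, "design"),
                                     min_identified_repeats = 2,
                                     n_draws = 100, downshift = 1.8,
                                     width = 0.3, seed = 1L,
                                     alpha = 0.05, lfc_threshold = 1,
                                     min_nonimputed = 2,
                                     var_equal = FALSE) {
  if (any(table$contaminant %||% FALSE) || any(table$reverse %||% FALSE)) {
    table <- filter_contaminants_reverse(table)
  }
  mat <- log2_transform(table, design)
  mat <- prefilter_identified(mat, min_repeats = min_identified_repeats)
  mat <- impute_missing(mat, n_draws = n_draws, downshift = downshift,
                        width = width, seed = seed)
  res <- differential_test(mat, design, var_equal = var_equal)
  res <- call_differential(res, alpha = alpha,
                           lfc_threshold = lfc_threshold,
                           min_nonimputed = min_nonimputed)
  structure(
    list(result = res,
         config = list(min_identified_repeats = min_identified_repeats,
                       n_draws = n_draws, downshift = downshift,
                       width = width, seed = seed, alpha = alpha,
                       lfc_threshold = lfc_threshold,
                       min_nonimputed = min_nonimputed,
                       var_equal = var_equal)),
    class = "aggdiff")
}

#' @method tidy aggdiff
#' @export
tidy.aggdiff <- function(x, ...) x$result

#' @method glance aggdiff
#' @export
glance.aggdiff <- function(x, ...) {
  r <- x$result
  tibble(n_tested = nrow(r),
         n_up = sum(r$call == "up"),
         n_down = sum(r$call == "down"),
         alpha = x$config$alpha,
         lfc_threshold = x$config$lfc_threshold,
         n_draws = x$config$n_draws,
         seed = x$config$seed)
}

#' @export
print.aggdiff <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<aggdiff> %d proteins tested: %d up, %d down (padj <= %.3g, |log2FC| >= %.3g)\n",
    g$n_tested, g$n_up, g$n_down, g$alpha, g$lfc_threshold))
  invisible(x)
}
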