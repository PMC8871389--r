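# Simplified RNA-seq differential expression: count filtering, prior-damped
# logCPM, a common-dispersion negative-binomial likelihood-ratio test with
# library-size offsets, and the strict fold-change / FDR call rule.
#
# This stage deliberately replaces gene-wise dispersion machinery with a
# single method-of-moments common dispersion so it stays self-contained and
# testable; an externally computed DE table can be supplied as a drop-in
# wherever a DEResult is consumed.

#' Filter genes by minimum counts
#'
#' Keeps genes with at least `min_count` reads in at least `min_samples`
#' samples (defaults implement ">1 counts in at least two samples").
#'
#' @param counts Integer gene-by-sample matrix.
#' @param min_count Minimum count (default 2).
#' @param min_samples Minimum number of samples reaching it (default 2).
#' @return The filtered count matrix.
#' @export
filter_min_counts <- function(counts, min_count = 2, min_samples = 2) {
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!any(keep)) stop_agg("no genes pass the count filter", "degenerate")
  counts[keep, , drop = FALSE]
}

#' Prior-damped log2 counts per million
#'
#' `logcpm_gj = log2( (y_gj + p_j) / (L_j + 2 p_j) * 1e6 )` with the prior
#' count scaled proportionally to library size,
#' `p_j = prior_count * L_j / mean(L)` — the standard prior-damped CPM
#' convention.
#'
#' @param counts Gene-by-sample count matrix.
#' @param prior_count Prior count damping low counts (default 2).
#' @param lib_size Library sizes (default: column sums).
#' @return Numeric matrix of log2 CPM values, same dimnames.
#' @export
logcpm <- function(counts, prior_count = 2, lib_size = colSums(counts)) {
  assert_that(all(lib_size > 0), "library sizes must be positive",
              "invalid_input")
  pc <- prior_count * lib_size / mean(lib_size)
  t(log2(t(counts) + pc) - log2(lib_size + 2 * pc)) + log2(1e6)
}

#' Method-of-moments common dispersion
#'
#' Per gene, the pooled within-group sample variance `s2` and within-group
#' mean `m` give a moment estimate `max(0, (s2 - m) / m^2)` of the
#' negative-binomial dispersion; the common dispersion is the average over
#' genes with nonzero mean.
#'
#' @param counts Gene-by-sample count matrix.
#' @param groups Sample group labels (>= 2 replicates in some group).
#' @return A single dispersion estimate (>= 0).
#' @export
estimate_common_dispersion <- function(counts, groups) {
  groups <- as.factor(groups)
  ns <- table(groups)
  assert_that(any(ns >= 2), "need >= 2 replicates in at least one group",
              "invalid_input")
  centred2 <- matrix(0, nrow(counts), 0)
  ss <- rep(0, nrow(counts)); dfree <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- counts[, idx, drop = FALSE]
    mg <- rowMeans(sub)
    ss <- ss + rowSums((sub - mg)^2)
    dfree <- dfree + length(idx) - 1
  }
  s2 <- ss / dfree
  m <- rowMeans(counts)
  ok <- m > 0
  assert_that(any(ok), "all-zero count matrix", "degenerate")
  mean(pmax(0, (s2[ok] - m[ok]) / m[ok]^2))
}

# NB log-likelihood for mean q * L (q per gene), fixed dispersion phi.
# y, L vectors over samples; q vector over genes. Returns per-gene loglik.
nb_loglik_rows <- function(y, lib, q, phi) {
  mu <- outer(q, lib)
  if (phi == 0) {
    return(rowSums(stats::dpois(y, pmax(mu, 1e-300), log = TRUE)))
  }
  r <- 1 / phi
  rowSums(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
            r * log(r / (r + mu)) + y * log(pmax(mu, 1e-300) / (r + mu)))
}

# MLE of the per-gene rate q with offsets lib and fixed dispersion phi.
# Newton-Raphson on log(q), vectorised over genes; for phi = 0 (Poisson)
# the closed form sum(y) / sum(lib) is exact and is also the start value.
nb_fit_rate <- function(y, lib, phi, tol = 1e-10, max_iter = 50) {
  q <- rowSums(y) / sum(lib)
  if (phi == 0) return(q)
  r <- 1 / phi
  lq <- log(pmax(q, 1e-12))
  active <- q > 0
  for (it in seq_len(max_iter)) {
    q_a <- exp(lq)
    mu <- outer(q_a, lib)
    # score and information wrt log q
    w <- (y + r) * mu / (mu + r)
    score <- rowSums(y - w)
    info <- rowSums(w * r / (mu + r))
    step <- ifelse(active & info > 0, score / info, 0)
    step <- pmax(pmin(step, 2), -2)
    lq <- lq + step
    if (max(abs(step)) < tol) break
  }
  out <- exp(lq)
  out[!active] <- 0
  out
}

#' Negative-binomial likelihood-ratio test
#'
#' Per gene, the NB log-likelihood with a fixed common dispersion and
#' library-size offsets is maximised under the null (a single rate across
#' all samples) and the alternative (one rate per group); twice the
#' log-likelihood difference is referred to a chi-square with 1 degree of
#' freedom. `logFC` is the unshrunk log2 ratio of fitted group rates
#' (case over control). With `dispersion = 0` the test reduces exactly to a
#' Poisson likelihood-ratio test. All-zero genes get `p = 1`, `logFC = 0`.
#'
#' @param counts Gene-by-sample count matrix.
#' @param groups Two-level sample labels; the first level alphabetically is
#'   taken as control unless a factor with explicit levels
#'   `c(control, case)` is given.
#' @param dispersion Common NB dispersion (>= 0); see
#'   [estimate_common_dispersion()].
#' @param lib_size Library sizes (default: column sums).
#' @return Tibble: `id`, `logFC`, `lr_statistic`, `p`, `mean_logcpm`.
#' @export
nb_lrt <- function(counts, groups, dispersion,
                   lib_size = colSums(counts)) {
  groups <- as.factor(groups)
  assert_that(nlevels(groups) == 2, "exactly two groups are required",
              "invalid_input")
  assert_that(dispersion >= 0, "dispersion must be >= 0", "config")
  ctrl <- levels(groups)[1]; case <- levels(groups)[2]
  y <- as.matrix(counts)
  i_ctrl <- groups == ctrl; i_case <- groups == case
  q0 <- nb_fit_rate(y, lib_size, dispersion)
  qc <- nb_fit_rate(y[, i_ctrl, drop = FALSE], lib_size[i_ctrl], dispersion)
  qt <- nb_fit_rate(y[, i_case, drop = FALSE], lib_size[i_case], dispersion)
  ll0 <- nb_loglik_rows(y, lib_size, q0, dispersion)
  ll1 <- nb_loglik_rows(y[, i_ctrl, drop = FALSE], lib_size[i_ctrl], qc,
                        dispersion) +
    nb_loglik_rows(y[, i_case, drop = FALSE], lib_size[i_case], qt,
                   dispersion)
  lr <- unname(pmax(0, 2 * (ll1 - ll0)))
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  logfc <- unname(log2(qt) - log2(qc))
  zero <- rowSums(y) == 0
  lr[zero] <- 0; p[zero] <- 1; logfc[zero] <- 0
  tibble(id = rownames(counts) %||% as.character(seq_len(nrow(y))),
         logFC = logfc, lr_statistic = lr, p = p,
         mean_logcpm = rowMeans(logcpm(y, lib_size = lib_size)))
}

#' Call differentially expressed genes
#'
#' Strict cutoffs: `up` requires `logFC > lfc_cut` and `fdr < fdr_cut`;
#' `down` is the mirror. Idempotent.
#'
#' @param result An [nb_lrt()] tibble.
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1, strict).
#' @param fdr_cut BH-adjusted p cutoff (default 0.05, strict).
#' @return The tibble with `fdr` and `call` columns.
#' @export
call_de <- function(result, lfc_cut = 1, fdr_cut = 0.05) {
  res <- result
  if (!("fdr" %in% names(res))) res$fdr <- adjust_bh(res$p)
  res$call <- dplyr::case_when(
    res$logFC > lfc_cut & res$fdr < fdr_cut ~ "up",
    res$logFC < -lfc_cut & res$fdr < fdr_cut ~ "down",
    TRUE ~ "ns"
  )
  res
}

#' Count differentially expressed members of a gene set
#'
#' @param result A called DE tibble.
#' @param set Identifier vector (e.g. the chaperone/co-chaperone list).
#' @return List: `n_up`, `n_down`, `members` (tibble of set members with
#'   their calls).
#' @export
annotate_gene_set_de <- function(result, set) {
  members <- result[match_ids(result$id, set), , drop = FALSE]
  list(n_up = sum(members$call == "up"),
       n_down = sum(members$call == "down"),
       members = members)
}

#' Full RNA-seq differential-expression stage
#'
#' Filters low-count genes, estimates a common dispersion, runs the NB
#' likelihood-ratio test and applies the strict call cutoffs.
#'
#' @inheritParams nb_lrt
#' @inheritParams filter_min_counts
#' @inheritParams call_de
#' @param dispersion Optional fixed dispersion; estimated from the data when
#'   `NULL`.
#' @return An object of class `"aggde"`; `tidy()` gives the per-gene table,
#'   `glance()` a one-row summary, `autoplot()` a volcano plot.
#' @export
rnaseq_de <- function(counts, groups, dispersion = NULL, min_count = 2,
                      min_samples = 2, lfc_cut = 1, fdr_cut = 0.05) {
  counts <- filter_min_counts(counts, min_count, min_samples)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, groups)
  }
  res <- nb_lrt(counts, groups, dispersion)
  res <- call_de(res, lfc_cut = lfc_cut, fdr_cut = fdr_cut)
  structure(list(result = res,
                 config = list(dispersion = dispersion,
                               min_count = min_count,
                               min_samples = min_samples,
                               lfc_cut = lfc_cut, fdr_cut = fdr_cut)),
            class = "aggde")
}

#' @method tidy aggde
#' @export
tidy.aggde <- function(x, ...) x$result

#' @method glance aggde
#' @export
glance.aggde <- function(x, ...) {
  r <- x$result
  tibble(n_genes = nrow(r), n_up = sum(r$call == "up"),
         n_down = sum(r$call == "down"),
         dispersion = x$config$dispersion,
         lfc_cut = x$config$lfc_cut, fdr_cut = x$config$fdr_cut)
}

#' @export
print.aggde <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<aggde> %d genes tested (common dispersion %.3g): %d up, %d down\n",
    g$n_genes, g$dispersion, g$n_up, g$n_down))
  invisible(x)
}

#' Mean abundance (CPM) per gene
#'
#' Convenience accessor feeding supersaturation scoring: the mean
#' counts-per-million across samples (optionally one condition).
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Optional column subset.
#' @return Tibble `id`, `abundance`.
#' @export
mean_cpm <- function(counts, samples = colnames(counts)) {
  sub <- counts[, samples, drop = FALSE]
  cpm <- t(t(sub) / colSums(sub)) * 1e6
  tibble(id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
         abundance = rowMeans(cpm))
}
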