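# Figure-level statistics: 2x2 chi-square membership enrichment,
# Kruskal-Wallis with Dunn's post-hoc, Wilcoxon matched-pairs signed-rank,
# and Bonferroni-corrected t-tests.

#' Build a 2x2 membership contingency table
#'
#' Counts annotation-set membership in an aggregation fraction against a
#' disjoint background (by default the NIA set): `a` = fraction members in
#' the set, `b` = fraction members outside it, `c`/`d` likewise for the
#' background.
#'
#' @param fraction Identifier set of the fraction of interest.
#' @param annotation Identifier set of the annotation (e.g. heat-sensitive
#'   proteins, stress-granule constituents, chaperone clients).
#' @param background Identifier set disjoint from `fraction`.
#' @return One-row tibble `a`, `b`, `c`, `d`.
#' @export
build_membership_table <- function(fraction, annotation, background) {
  fraction <- unique(fraction); background <- unique(background)
  assert_that(length(intersect(fraction, background)) == 0,
              "fraction and background sets overlap", "invalid_input")
  in_f <- match_ids(fraction, annotation)
  in_b <- match_ids(background, annotation)
  tibble(a = sum(in_f), b = sum(!in_f), c = sum(in_b), d = sum(!in_b))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with one
#' degree of freedom, computed from the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param table One-row tibble or named vector with counts `a`, `b`, `c`,
#'   `d`.
#' @return Tibble `statistic`, `df`, `p`.
#' @export
chi_square <- function(table) {
  a <- as.numeric(table[["a"]]); b <- as.numeric(table[["b"]])
  cc <- as.numeric(table[["c"]]); d <- as.numeric(table[["d"]])
  assert_that(all(c(a, b, cc, d) >= 0), "counts must be nonnegative",
              "invalid_input")
  n <- a + b + cc + d
  assert_that(n > 0, "empty table", "invalid_input")
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    stop_agg("a table margin is zero (expected count 0); use an exact test",
             "degenerate")
  }
  stat <- n * (a * d - b * cc)^2 / prod(margins)
  tibble(statistic = stat, df = 1, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Annotation-set enrichment across fractions
#'
#' Convenience wrapper running [build_membership_table()] +- [chi_square()]
#' for every combination of fraction and annotation set.
#'
#' @param labels A [classify_fractions()] tibble.
#' @param gene_sets A [read_gene_sets()] collection (or named list of id
#'   vectors).
#' @param fractions Fraction labels to test (default: all except the
#'   background).
#' @param background Label used as background (default `"nia"`).
#' @return Tibble: `fraction`, `set`, `a`, `b`, `c`, `d`, `statistic`, `p`,
#'   `p_adjusted` (BH across all tests).
#' @export
enrichment_analysis <- function(labels, gene_sets,
                                fractions = setdiff(fraction_levels,
                                                    background),
                                background = "nia") {
  bg_ids <- labels$id[labels$label == background]
  grid <- expand.grid(fraction = fractions, set = names(gene_sets),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(fraction, set) {
    fr_ids <- labels$id[labels$label == fraction]
    tab <- build_membership_table(fr_ids, gene_sets[[set]], bg_ids)
    test <- tryCatch(chi_square(tab), aggregomics_degenerate = function(e) {
      tibble(statistic = NA_real_, df = 1, p = NA_real_)
    })
    dplyr::bind_cols(tibble(fraction = fraction, set = set), tab,
                     test[, c("statistic", "p")])
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- adjust_bh(out$p)
  out
}

kw_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  list(x = x, g = g, r = rank(x))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square approximation. When all
#' observations are identical, H is 0 and p is 1 by convention.
#'
#' @param groups Named list of numeric vectors (>= 2 non-empty groups).
#' @return Tibble `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  assert_that(length(groups) >= 2, "need >= 2 groups", "invalid_input")
  assert_that(all(lengths(groups) > 0), "empty group supplied",
              "invalid_input")
  x <- unlist(groups, use.names = FALSE)
  assert_that(length(x) >= 3, "need >= 3 observations in total",
              "invalid_input")
  if (length(unique(x)) == 1) {
    return(tibble(H = 0, df = length(groups) - 1, p = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z-statistics on the pooled ranks with tie correction, following
#' a Kruskal-Wallis omnibus test; family-wise adjustment by Bonferroni
#' (default) or Sidak over all pairs.
#'
#' @param groups Named list of numeric vectors.
#' @param method `"bonferroni"` or `"sidak"`.
#' @return Tibble per pair: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  assert_that(length(groups) >= 2, "need >= 2 groups", "invalid_input")
  assert_that(all(lengths(groups) > 0), "empty group supplied",
              "invalid_input")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  tie_tab <- table(x)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  rbar <- tapply(r, g, mean)[names(groups)]
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_sum / (12 * (N - 1))) *
                 (1 / ns[[i]] + 1 / ns[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    tibble(group1 = i, group2 = j, z = z,
           p_raw = 2 * pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  m <- nrow(out)
  out$p_adjusted <- switch(method,
    bonferroni = pmin(1, out$p_raw * m),
    sidak = 1 - (1 - out$p_raw)^m)
  out
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test on paired observations. Zero differences are dropped; the
#' p-value is exact (signed-rank enumeration) for up to `exact_max`
#' remaining pairs without ties, and a normal approximation otherwise.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return Tibble `statistic` (V, rank sum of positive differences), `p`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_max = 25) {
  assert_that(length(paired_a) == length(paired_b),
              "paired vectors must have equal length", "invalid_input")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0) {
    rlang::warn("all paired differences are zero")
    return(tibble(statistic = 0, p = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = use_exact, correct = !use_exact))
  tibble(statistic = unname(wt$statistic), p = min(1, wt$p.value),
         method = if (use_exact) "exact" else "normal_approximation")
}

#' Pairwise Student t-tests with Bonferroni correction
#'
#' Two-sided, two-sample pooled-variance t-tests for the requested group
#' pairs; `p_adjusted = min(1, p_raw * n_comparisons)`. Degenerate pairs
#' (zero variance on both sides, equal means) return t = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param comparisons List of 2-element character vectors naming the pairs
#'   to compare (default: all pairs).
#' @return Tibble per pair: `group1`, `group2`, `t`, `p_raw`, `p_adjusted`.
#' @export
ttest_bonferroni <- function(groups,
                             comparisons = utils::combn(names(groups), 2,
                                                        simplify = FALSE)) {
  assert_that(all(lengths(groups) >= 2), "each group needs n >= 2",
              "invalid_input")
  rows <- purrr::map(comparisons, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (sd(x) == 0 && sd(y) == 0) {
      if (mean(x) == mean(y)) {
        return(tibble(group1 = pr[1], group2 = pr[2], t = 0, p_raw = 1))
      }
      return(tibble(group1 = pr[1], group2 = pr[2],
                    t = sign(mean(x) - mean(y)) * Inf, p_raw = 0))
    }
    tt <- t.test(x, y, var.equal = TRUE)
    tibble(group1 = pr[1], group2 = pr[2], t = unname(tt$statistic),
           p_raw = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out
}
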