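test_that("membership tables count fraction and background against a set", {
  tab <- build_membership_table(c("A", "B"), "A", c("C", "D"))
  expect_equal(unlist(tab), c(a = 1, b = 1, c = 0, d = 2))
  all_in <- build_membership_table(c("A", "B"), c("A", "B", "C", "D"),
                                   c("C", "D"))
  expect_equal(all_in$b + all_in$d, 0)
  none <- build_membership_table(c("A", "B"), character(0), c("C", "D"))
  expect_equal(none$a + none$c, 0)
  expect_error(build_membership_table(c("A", "B"), "A", c("B", "C")),
               class = "aggregomics_invalid_input")
})

test_that("2x2 chi-square equals the closed form and chisq.test", {
  r <- chi_square(tibble::tibble(a = 10, b = 90, c = 30, d = 70))
  expect_equal(r$statistic, 12.5)
  expect_equal(r$df, 1)
  expect_equal(r$p, pchisq(12.5, 1, lower.tail = FALSE))

  flat <- chi_square(tibble::tibble(a = 20, b = 80, c = 20, d = 80))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  # swapping rows leaves the statistic unchanged
  expect_equal(chi_square(tibble::tibble(a = 30, b = 70, c = 10, d = 90))$
                 statistic, 12.5)

  expect_error(chi_square(tibble::tibble(a = 0, b = 0, c = 5, d = 5)),
               class = "aggregomics_degenerate")

  set.seed(12)
  for (i in 1:25) {
    tb <- tibble::tibble(a = rpois(1, 20) + 1, b = rpois(1, 50) + 1,
                         c = rpois(1, 20) + 1, d = rpois(1, 50) + 1)
    mine <- chi_square(tb)
    expect_equal(mine$statistic, chi2_oracle(tb$a, tb$b, tb$c, tb$d),
                 tolerance = 1e-9)
    ref <- suppressWarnings(chisq.test(matrix(unlist(tb), 2, byrow = TRUE),
                                       correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis H matches a first-principles rank computation", {
  const <- kruskal_wallis(list(g1 = c(2, 2), g2 = c(2, 2)))
  expect_equal(const$H, 0)
  expect_equal(const$p, 1)

  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  mine <- kruskal_wallis(g)
  expect_equal(mine$H, kw_oracle(g), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:10) {
    gs <- lapply(1:3, function(k) sample(1:8, sample(3:6, 1),
                                         replace = TRUE))
    names(gs) <- paste0("g", 1:3)
    expect_equal(kruskal_wallis(gs)$H, kw_oracle(gs), tolerance = 1e-10)
    # permuting group order leaves H unchanged
    expect_equal(kruskal_wallis(rev(gs))$H, kruskal_wallis(gs)$H)
  }
  expect_error(kruskal_wallis(list(a = 1, b = numeric(0))),
               class = "aggregomics_invalid_input")
})

test_that("Dunn post-hoc z matches pooled-rank hand computation", {
  two <- dunn_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(nrow(two), 1)
  expect_equal(two$p_adjusted, two$p_raw)

  same <- dunn_posthoc(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_true(all(same$z == 0))

  g <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(7, 8, 9))
  out <- dunn_posthoc(g)
  # independent computation of the a-vs-c comparison
  x <- unlist(g); r <- rank(x); N <- length(x)
  rbar <- tapply(r, rep(names(g), lengths(g)), mean)
  se <- sqrt((N * (N + 1) / 12) * (1 / 3 + 1 / 3))
  z_ac <- (rbar[["a"]] - rbar[["c"]]) / se
  row <- out[out$group1 == "a" & out$group2 == "c", ]
  expect_equal(row$z, z_ac, tolerance = 1e-12)
  expect_equal(row$p_raw, 2 * pnorm(-abs(z_ac)), tolerance = 1e-12)
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 3))
  # Sidak never exceeds Bonferroni
  sid <- dunn_posthoc(g, method = "sidak")
  expect_true(all(sid$p_adjusted <= out$p_adjusted + 1e-12))
})

test_that("signed-rank test is exact for small n and matches enumeration", {
  expect_warning(same <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(same$p, 1)

  # n = 5, all differences positive: p = 2/32
  r5 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5) - 0:4)
  d5 <- c(2, 3, 4, 5, 6) - (c(1, 2, 3, 4, 5) - 0:4)
  expect_true(all(d5 > 0))
  expect_equal(r5$p, 0.0625)

  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    mine <- wilcoxon_signed_rank(a, b)
    if (mine$method == "exact") {
      expect_equal(mine$p, wilcox_exact_oracle(a - b), tolerance = 1e-12)
    }
  }

  # large n falls back to the normal approximation
  set.seed(29)
  big <- wilcoxon_signed_rank(rnorm(40), rnorm(40))
  expect_equal(big$method, "normal_approximation")
  expect_true(big$p >= 0 && big$p <= 1)
})

test_that("pairwise t-tests apply Bonferroni with clipping", {
  g <- list(a = c(1, 2, 3), b = c(1.2, 2.1, 3.3), c = c(5, 6, 7))
  one <- ttest_bonferroni(g, comparisons = list(c("a", "b")))
  expect_equal(one$p_adjusted, one$p_raw)
  ref <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(one$p_raw, ref$p.value, tolerance = 1e-12)

  all3 <- ttest_bonferroni(g)
  expect_equal(nrow(all3), 3)
  expect_true(all(all3$p_adjusted <= 1))
  expect_true(all(all3$p_adjusted >= all3$p_raw))
  lax <- all3$p_raw[1]
  expect_equal(all3$p_adjusted[1], min(1, lax * 3))

  ident <- ttest_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_raw, 1)

  const <- ttest_bonferroni(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(const$p_raw, 1)
})

test_that("enrichment analysis runs sets against the NIA background", {
  labels <- structure(
    tibble::tibble(
      id = sprintf("P%03d", 1:120),
      label = factor(rep(c("increased", "baseline", "nia"), times = c(30, 30, 60)),
                     levels = aggregomics:::fraction_levels)),
    class = c("fraction_labels", class(tibble::tibble())))
  sets <- list(hot = sprintf("P%03d", 1:25),
               cold = sprintf("P%03d", 101:120))
  out <- enrichment_analysis(labels, sets,
                             fractions = c("increased", "baseline"))
  expect_equal(nrow(out), 4)
  expect_true(all(out$a + out$b == 30))
  expect_true(all(out$p_adjusted >= out$p, na.rm = TRUE))
  hot_inc <- out[out$fraction == "increased" & out$set == "hot", ]
  expect_equal(hot_inc$a, 25)
  expect_lt(hot_inc$p, 1e-6)
})
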