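test_that("log2 transform converts intensities and counts detections", {
  path <- write_tiny_protein_groups()
  tab <- suppressMessages(
    filter_contaminants_reverse(read_protein_groups(path, tiny_design())))
  mat <- log2_transform(tab)
  expect_equal(mat$c1[1], log2(1e6))
  # detection counts per condition, bounded by replicate numbers
  expect_equal(mat$n_detected_case, c(2L, 1L))
  expect_equal(mat$n_detected_control, c(2L, 1L))
  expect_true(all(mat$n_detected_case + mat$n_detected_control <= 4))

  # intensity 8 -> 3
  tab$c1[1] <- 8
  expect_equal(log2_transform(tab)$c1[1], 3)

  # an all-missing row is retained with 0/0 counts
  tab2 <- tab
  for (s in tiny_design()$sample) tab2[[s]][2] <- NA_real_
  m2 <- log2_transform(tab2)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$n_detected_case[2], 0L)

  # a true zero reaching this stage is an internal error
  tab$c1[1] <- 0
  expect_error(log2_transform(tab), class = "aggregomics_internal")
})

test_that("detection prefilter keeps proteins seen in enough replicates of either side", {
  vals <- rbind(c(20, NA, 21, NA),   # 1 control + 1 case
                c(20, 21, NA, NA),   # 2 control, 0 case
                c(NA, NA, 20, 21))   # 0 control, 2 case
  mat <- complete_log_matrix(vals)
  kept <- prefilter_identified(mat, min_repeats = 2)
  expect_setequal(kept$id, c("P002", "P003"))
  expect_equal(nrow(prefilter_identified(mat, min_repeats = 0)), 3)
})

test_that("downshifted imputation is seeded, centred and leaves observed cells alone", {
  set.seed(99)
  vals <- matrix(rnorm(80, 22, 1.5), 20, 4)
  miss <- vals
  miss[3, 2] <- NA
  mat <- complete_log_matrix(miss)

  imp1 <- impute_missing(mat, n_draws = 100, seed = 7)
  imp2 <- impute_missing(mat, n_draws = 100, seed = 7)
  expect_identical(imp1, imp2)
  # observed values untouched
  expect_equal(imp1$c1, miss[, 1])

  # averaged value concentrates at mu_j - 1.8 sd_j (Monte Carlo bound)
  obs <- miss[-3, 2]
  target <- mean(obs) - 1.8 * sd(obs)
  tol <- 3 * (0.3 * sd(obs)) / sqrt(100)
  expect_lt(abs(imp1$c2[3] - target), tol)

  # a complete matrix passes through unchanged for any seed
  full <- complete_log_matrix(vals)
  expect_identical(impute_missing(full, seed = 1),
                   impute_missing(full, seed = 2))
  expect_identical(impute_missing(full, seed = 1), full)
})

test_that("imputation falls back to global moments for nearly empty samples", {
  # column 2 has a single observed value -> global-moment fallback
  mat <- complete_log_matrix(matrix(c(20, NA, 20,
                                      21, NA, NA,
                                      22, NA, 22,
                                      23, 21, 20), 3, 4))
  expect_warning(out <- impute_missing(mat, seed = 1), "global")
  expect_false(anyNA(as.matrix(out[, tiny_design()$sample])))
})

test_that("per-protein t-tests match t.test and behave symmetrically", {
  # identical case and control values
  r <- differential_test(complete_log_matrix(
    matrix(c(5, 6, 5, 6), 1, 4)))
  expect_equal(r$log2fc, 0)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  # near-exact fold change of 2
  set.seed(3)
  vals <- matrix(c(3, 3, 5, 5), 10, 4, byrow = TRUE) +
    matrix(rnorm(40, 0, 1e-4), 10, 4)
  r2 <- differential_test(complete_log_matrix(vals))
  expect_true(all(abs(r2$log2fc - 2) < 0.01))

  # agreement with stats::t.test (Welch and Student)
  set.seed(11)
  vv <- matrix(rnorm(24, 20, 1), 3, 8)
  d8 <- sample_design(paste0("s", 1:8),
                      rep(c("control", "case"), each = 4),
                      rep(1:4, 2))
  m8 <- complete_log_matrix(vv, d8)
  for (ve in c(FALSE, TRUE)) {
    mine <- differential_test(m8, var_equal = ve)
    for (i in 1:3) {
      ref <- t.test(vv[i, 5:8], vv[i, 1:4], var.equal = ve)
      expect_equal(mine$p_value[i], ref$p.value, tolerance = 1e-12)
      expect_equal(mine$t_statistic[i], unname(ref$statistic),
                   tolerance = 1e-12)
    }
  }

  # swapping condition labels negates log2fc and t, keeps p
  d_swap <- d8
  d_swap$condition <- rev(d_swap$condition)
  m_swap <- complete_log_matrix(vv, d_swap)
  a <- differential_test(m8)
  b <- differential_test(m_swap)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("BH adjustment matches a brute-force step-up implementation", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "aggregomics_invalid_input")

  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("replicate-gated calls follow the inclusive thresholds", {
  res <- tibble::tibble(
    id = c("a", "b", "c", "d", "e"),
    log2fc = c(1.5, 1.5, 3, -2, 1),
    p_value = c(0.001, 0.001, 0.15, 0.001, 0.001),
    p_adjusted = c(0.04, 0.04, 0.2, 0.04, 0.05),
    n_detected_case = c(3L, 1L, 4L, 0L, 2L),
    n_detected_control = c(0L, 0L, 4L, 3L, 2L)
  )
  out <- call_differential(res)
  expect_equal(out$call, c("up", "ns", "ns", "down", "up"))
})

test_that("with no missing data the full pipeline ignores seed and draw count", {
  set.seed(21)
  n <- 30
  vals <- 2^matrix(rnorm(n * 8, 22, 1), n, 8)
  d8 <- sample_design(paste0("s", 1:8),
                      rep(c("case", "control"), each = 4), rep(1:4, 2))
  tab <- tibble::tibble(id = sprintf("P%03d", 1:n),
                        contaminant = FALSE, reverse = FALSE)
  for (k in 1:8) tab[[d8$sample[k]]] <- vals[, k]
  f1 <- differential_aggregation(tab, d8, seed = 1, n_draws = 5)
  f2 <- differential_aggregation(tab, d8, seed = 999, n_draws = 100)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("exchanging case and control swaps the up and down call sets", {
  sim <- simulate_experiment(n_proteins = 400, n_planted = 40, seed = 13)
  d <- sim$design_aggregate
  d_swap <- d
  d_swap$condition <- ifelse(d$condition == "case", "control", "case")
  f1 <- suppressMessages(
    differential_aggregation(sim$protein_groups, d, seed = 13))
  f2 <- suppressMessages(
    differential_aggregation(sim$protein_groups, d_swap, seed = 13))
  r1 <- tidy(f1); r2 <- tidy(f2)
  expect_setequal(r1$id[r1$call == "up"], r2$id[r2$call == "down"])
  expect_setequal(r1$id[r1$call == "down"], r2$id[r2$call == "up"])
})
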