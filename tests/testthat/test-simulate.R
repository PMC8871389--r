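test_that("the threshold model drives condition-specific aggregation", {
  cfg <- simulation_config(n_proteins = 3000, seed = 5)
  truth <- simulate_proteome(cfg)
  expect_identical(truth, simulate_proteome(cfg))
  expect_equal(truth$sigma, log10(truth$abundance + 1) + truth$propensity_z)

  # equal thresholds give (binomially) equal aggregator counts
  cfg_eq <- simulation_config(n_proteins = 3000, tau_treated = 4, seed = 5)
  t_eq <- simulate_proteome(cfg_eq)
  n_c <- sum(t_eq$aggregates_control); n_t <- sum(t_eq$aggregates_treated)
  expect_lt(abs(n_c - n_t), 4 * sqrt(n_c + n_t + 1))

  # lowering the treated threshold increases treated aggregation
  expect_gt(sum(truth$aggregates_treated), sum(truth$aggregates_control))

  # near-zero steepness approaches the deterministic indicator
  cfg_sharp <- simulation_config(n_proteins = 2000,
                                 aggregation_steepness = 1e-6, seed = 6)
  t_sharp <- simulate_proteome(cfg_sharp)
  expect_equal(t_sharp$aggregates_control, t_sharp$sigma > 4)
})

test_that("LFQ simulation is seeded and detection tracks intensity", {
  cfg <- simulation_config(n_proteins = 500, seed = 7)
  truth <- simulate_proteome(cfg)
  l1 <- simulate_lfq(truth, cfg)
  l2 <- simulate_lfq(truth, cfg)
  expect_identical(l1$table, l2$table)
  expect_equal(nrow(l1$design), 12)

  # WCL detection frequency is nondecreasing in abundance (binned)
  wcl_cols <- l1$design$sample[l1$design$fraction == "WCL"]
  det <- rowMeans(!is.na(as.matrix(
    l1$table[seq_len(nrow(truth)), wcl_cols])))
  bins <- cut(log10(truth$abundance), quantile(log10(truth$abundance),
                                               0:4 / 4),
              include.lowest = TRUE)
  freq <- tapply(det, bins, mean)
  expect_true(all(diff(freq) > -0.02))

  # decoy rows carry contaminant/reverse flags for the ingest filter
  expect_gt(sum(l1$table$contaminant | l1$table$reverse), 0)
})

test_that("a null effect size leaves case and control exchangeable", {
  cfg <- simulation_config(n_proteins = 800, effect_size = 0,
                           tau_treated = 4, seed = 9)
  truth <- simulate_proteome(cfg)
  lfq <- simulate_lfq(truth, cfg)
  agg <- lfq$design[lfq$design$fraction == "aggregate", ]
  m <- log2(as.matrix(lfq$table[seq_len(nrow(truth)), agg$sample]))
  case <- as.vector(m[, agg$condition == "case"])
  ctrl <- as.vector(m[, agg$condition == "control"])
  expect_equal(mean(is.na(case)), mean(is.na(ctrl)), tolerance = 0.02)
  expect_equal(mean(case, na.rm = TRUE), mean(ctrl, na.rm = TRUE),
               tolerance = 0.05)
})

test_that("transcript counts follow the NB observation model", {
  cfg <- simulation_config(n_proteins = 2000, seed = 10,
                           nb_dispersion = 0)
  truth <- simulate_proteome(cfg)
  counts <- simulate_counts(truth, cfg, n_samples = 4)
  expect_identical(counts, simulate_counts(truth, cfg, n_samples = 4))
  # Poisson limit: variance tracks the mean
  m <- rowMeans(counts); v <- apply(counts, 1, var)
  ok <- m > 20
  expect_equal(mean(v[ok] / m[ok]), 1, tolerance = 0.1)

  # doubling the library size doubles the expected column totals
  big <- simulate_counts(truth, cfg, n_samples = 2,
                         lib_size = c(5e6, 1e7))
  expect_equal(sum(big[, 2]) / sum(big[, 1]), 2, tolerance = 0.05)
})

test_that("annotation sets plant the requested enrichment", {
  cfg <- simulation_config(n_proteins = 2000, seed = 12)
  truth <- simulate_proteome(cfg)
  sets <- simulate_annotations(truth, enrichment_odds = 1,
                               set_size = 300, seed = 12)
  expect_length(sets[[1]], 300)
  expect_equal(attr(sets, "realized_odds_ratio"), 1, tolerance = 0.9)
  rich <- simulate_annotations(truth, enrichment_odds = 5,
                               set_size = 300, seed = 12)
  expect_gt(attr(rich, "realized_odds_ratio"),
            attr(sets, "realized_odds_ratio"))
  expect_error(simulate_annotations(truth, set_size = 5000),
               class = "aggregomics_config")
})

test_that("recovery metrics follow their conventions", {
  truth <- tibble::tibble(id = c("a", "b", "c", "d"),
                          aggregates_control = c(FALSE, FALSE, TRUE, FALSE),
                          aggregates_treated = c(TRUE, TRUE, TRUE, FALSE))
  perfect <- tibble::tibble(id = truth$id,
                            call = c("up", "up", "ns", "ns"))
  r <- evaluate_recovery(perfect, truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$empirical_fdr, 0)

  none <- tibble::tibble(id = truth$id, call = "ns")
  r0 <- evaluate_recovery(none, truth)
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$empirical_fdr, 0)

  # random calls on a null truth are all false discoveries
  null_truth <- tibble::tibble(id = sprintf("P%02d", 1:50),
                               aggregates_control = FALSE,
                               aggregates_treated = FALSE)
  rand <- tibble::tibble(id = null_truth$id,
                         call = ifelse(seq_len(50) <= 5, "up", "ns"))
  expect_equal(evaluate_recovery(rand, null_truth)$empirical_fdr, 1)
})

test_that("written simulations round-trip through the readers", {
  sim <- simulate_experiment(n_proteins = 60, n_planted = 10, seed = 19)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))

  back <- read_protein_groups(paths[["protein_groups"]], sim$design)
  orig <- sim$protein_groups
  expect_equal(back$id, orig$id)
  expect_equal(back$contaminant, orig$contaminant)
  for (s in sim$design$sample) {
    expect_equal(back[[s]], orig[[s]], tolerance = 1e-12)
  }

  counts <- read_count_matrix(paths[["counts"]])
  expect_equal(unname(counts), unname(sim$counts))

  sets <- read_gene_sets(paths[["gene_sets"]])
  expect_equal(sets$planted, sim$gene_sets$planted)

  # exported manifest records the seed
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, 19)
})
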