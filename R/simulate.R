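# Ground-truth simulator: a threshold model of protein aggregation in which
# genotoxic stress lowers the cell-intrinsic aggregation threshold, plus the
# observation layers (LFQ with MNAR missingness, NB transcript counts,
# annotation sets with planted enrichment) needed to test every pipeline
# stage against a recoverable truth.

#' Simulation configuration
#'
#' Bundles the generative parameters of the synthetic experiment. Defaults
#' describe a 4-vs-4 label-free design: log-normal transcript abundances
#' (log10 CPM scale), standard-normal intrinsic aggregation propensities,
#' supersaturation `sigma = log10(abundance + 1) + z`, and aggregation drawn
#' with probability `plogis((sigma - tau) / steepness)` — treatment lowers
#' the threshold `tau`. Aggregating proteins gain `effect_size` log2 units
#' of aggregate-fraction intensity; detection of each LFQ cell is logistic
#' in its log2 intensity (missing-not-at-random).
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Replicates per condition and fraction (default 4).
#' @param abundance_logmean,abundance_logsd Log10-CPM abundance
#'   distribution (defaults 1.5, 1).
#' @param propensity_mean,propensity_sd Propensity distribution (0, 1).
#' @param tau_control,tau_treated Aggregation thresholds in sigma units
#'   (defaults 4 and 3; the lowered treated threshold drives induced
#'   aggregation).
#' @param aggregation_steepness Logistic steepness of the threshold
#'   (default 0.25; smaller = sharper).
#' @param effect_size Log2 aggregate-intensity gain of an aggregating
#'   protein (default 2).
#' @param wcl_offset Log2 intensity of a 0-CPM protein in the WCL fraction
#'   (default 18).
#' @param aggregate_base Log2 aggregate-fraction background intensity of a
#'   non-aggregating protein; set below the detection midpoint so
#'   non-aggregators are mostly absent from aggregate fractions
#'   (default 18.3).
#' @param aggregate_abundance_slope Dependence of an aggregating protein's
#'   pellet log2 intensity on its log2 transcript abundance (default 0.5):
#'   the amount of a protein recovered in the pellet scales with how much
#'   of it the cell expresses, giving aggregate samples a realistic dynamic
#'   range. Non-aggregating proteins contribute only flat background.
#' @param intensity_noise_sd Replicate log2 intensity noise SD (default
#'   0.3, a typical LFQ replicate CV).
#' @param missing_logistic_midpoint,missing_logistic_slope Detection
#'   probability `plogis((log2 intensity - midpoint) / slope)` (defaults
#'   19.3 and 0.3: a fairly sharp detection limit just above the
#'   non-aggregator baseline).
#' @param nb_dispersion NB dispersion of the transcript counts (default
#'   0.15).
#' @param seed Integer seed.
#' @return A classed list of parameters.
#' @export
simulation_config <- function(n_proteins = 2000, n_replicates = 4,
                              abundance_logmean = 1.5,
                              abundance_logsd = 1,
                              propensity_mean = 0, propensity_sd = 1,
                              tau_control = 4, tau_treated = 3,
                              aggregation_steepness = 0.25,
                              effect_size = 2,
                              wcl_offset = 18, aggregate_base = 18.3,
                              aggregate_abundance_slope = 0.5,
                              intensity_noise_sd = 0.3,
                              missing_logistic_midpoint = 19.3,
                              missing_logistic_slope = 0.3,
                              nb_dispersion = 0.15, seed = 1L) {
  assert_that(n_proteins >= 1, "n_proteins must be >= 1", "config")
  assert_that(aggregation_steepness > 0, "steepness must be > 0", "config")
  assert_that(abundance_logsd > 0 && propensity_sd > 0 &&
                intensity_noise_sd > 0, "sds must be > 0", "config")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a ground-truth proteome
#'
#' Draws abundances, propensities and condition-specific aggregation flags
#' under the lowered-threshold model: `P(aggregate in condition c) =
#' plogis((sigma - tau_c) / steepness)`.
#'
#' @param cfg A [simulation_config()].
#' @return Tibble: `id`, `abundance` (CPM), `propensity_z`, `sigma`,
#'   `aggregates_control`, `aggregates_treated`.
#' @export
simulate_proteome <- function(cfg = simulation_config()) {
  set.seed(as_seed(cfg$seed))
  n <- cfg$n_proteins
  abundance <- 10^rnorm(n, cfg$abundance_logmean, cfg$abundance_logsd)
  z <- rnorm(n, cfg$propensity_mean, cfg$propensity_sd)
  sigma <- log10(abundance + 1) + z
  p_ctrl <- plogis((sigma - cfg$tau_control) / cfg$aggregation_steepness)
  p_trt <- plogis((sigma - cfg$tau_treated) / cfg$aggregation_steepness)
  tibble(
    id = sprintf("P%05d", seq_len(n)),
    abundance = abundance,
    propensity_z = z,
    sigma = sigma,
    aggregates_control = runif(n) < p_ctrl,
    aggregates_treated = runif(n) < p_trt
  )
}

#' Simulate LFQ intensity tables with MNAR missingness
#'
#' Builds a proteinGroups-style table for the aggregate fraction (case and
#' control) plus a whole-cell-lysate fraction. WCL log2 intensity tracks
#' abundance; aggregate-fraction intensity is a low flat background plus,
#' for proteins aggregating in that condition, `effect_size` and an
#' abundance-scaled pellet amount. Each cell is
#' detected with probability logistic in its realised log2 intensity;
#' undetected cells are `NA`. A few flagged contaminant/reverse rows are
#' appended so ingestion filters have work to do.
#'
#' @param truth A [simulate_proteome()] tibble.
#' @param cfg The matching [simulation_config()].
#' @param n_decoys Number of appended contaminant/reverse rows (default 4).
#' @return List: `table` (protein-group tibble with intensity columns),
#'   `design` (all samples), `design_aggregate` (the case-vs-control
#'   aggregate subset used for differential testing).
#' @export
simulate_lfq <- function(truth, cfg = simulation_config(), n_decoys = 4) {
  set.seed(as_seed(cfg$seed + 7919))
  n <- nrow(truth); reps <- cfg$n_replicates
  design <- dplyr::bind_rows(
    sample_design(paste0("agg_case_", seq_len(reps)), "case",
                  seq_len(reps), "aggregate", "simulated"),
    sample_design(paste0("agg_ctrl_", seq_len(reps)), "control",
                  seq_len(reps), "aggregate", "simulated"),
    sample_design(paste0("wcl_ctrl_", seq_len(reps)), "control",
                  seq_len(reps), "WCL", "simulated")
  )
  mu_wcl <- cfg$wcl_offset + log2(truth$abundance + 1)
  l2a <- log2(truth$abundance + 1)
  tilt <- cfg$aggregate_abundance_slope * (l2a - mean(l2a))
  agg_level <- function(flag) {
    cfg$aggregate_base + flag * (cfg$effect_size + tilt)
  }
  mu_agg_case <- agg_level(truth$aggregates_treated)
  mu_agg_ctrl <- agg_level(truth$aggregates_control)
  draw_block <- function(mu) {
    x <- matrix(rnorm(n * reps, mean = mu, sd = cfg$intensity_noise_sd),
                n, reps)
    p_det <- plogis((x - cfg$missing_logistic_midpoint) /
                      cfg$missing_logistic_slope)
    x[matrix(runif(n * reps), n, reps) >= p_det] <- NA_real_
    2^x
  }
  blocks <- cbind(draw_block(mu_agg_case), draw_block(mu_agg_ctrl),
                  draw_block(mu_wcl))
  colnames(blocks) <- design$sample
  table <- tibble(id = truth$id, group_id = truth$id, genes = truth$id,
                  razor_unique_peptides = NA_integer_,
                  contaminant = FALSE, reverse = FALSE)
  table <- dplyr::bind_cols(table, as_tibble(blocks))
  if (n_decoys > 0) {
    set.seed(as_seed(cfg$seed + 104729))
    decoys <- tibble(
      id = sprintf("DECOY%02d", seq_len(n_decoys)),
      group_id = sprintf("DECOY%02d", seq_len(n_decoys)),
      genes = NA_character_, razor_unique_peptides = NA_integer_,
      contaminant = seq_len(n_decoys) %% 2 == 1,
      reverse = seq_len(n_decoys) %% 2 == 0
    )
    dint <- matrix(2^rnorm(n_decoys * nrow(design), 22, 1), n_decoys)
    colnames(dint) <- design$sample
    table <- dplyr::bind_rows(table, dplyr::bind_cols(decoys,
                                                      as_tibble(dint)))
  }
  attr(table, "design") <- design
  list(table = table, design = design,
       design_aggregate = design[design$fraction == "aggregate", ,
                                 drop = FALSE])
}

#' Simulate transcript counts
#'
#' Negative-binomial counts per gene with mean proportional to abundance
#' times library size; a dispersion of 0 gives Poisson counts.
#'
#' @param truth A [simulate_proteome()] tibble.
#' @param cfg The matching [simulation_config()].
#' @param n_samples Number of samples (default 4).
#' @param lib_size Library sizes (default 5e6 each).
#' @return Integer gene-by-sample count matrix.
#' @export
simulate_counts <- function(truth, cfg = simulation_config(),
                            n_samples = 4,
                            lib_size = rep(5e6, n_samples)) {
  set.seed(as_seed(cfg$seed + 15485863))
  n <- nrow(truth)
  mu <- outer(truth$abundance / 1e6, lib_size)
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(rnbinom(n * n_samples, mu = mu, size = 1 / cfg$nb_dispersion),
           n, n_samples)
  } else {
    matrix(rpois(n * n_samples, lambda = mu), n, n_samples)
  }
  rownames(counts) <- truth$id
  colnames(counts) <- paste0("rna_", seq_len(n_samples))
  counts
}

#' Simulate an annotation set with planted enrichment
#'
#' Samples `set_size` members without replacement, weighting
#' treatment-induced aggregators (`aggregates_treated & !aggregates_control`)
#' by `enrichment_odds`; odds 1 gives a null (random) set.
#'
#' @param truth A [simulate_proteome()] tibble.
#' @param enrichment_odds Sampling-odds multiplier for induced aggregators
#'   (> 0).
#' @param set_size Number of members (<= `n_proteins`).
#' @param seed Integer seed.
#' @param name Set name.
#' @return A `gene_set_collection` of one set, with the realised odds ratio
#'   attached as attribute `"realized_odds_ratio"`.
#' @export
simulate_annotations <- function(truth, enrichment_odds = 5,
                                 set_size = 200, seed = 1L,
                                 name = "planted") {
  assert_that(enrichment_odds > 0, "enrichment_odds must be > 0", "config")
  assert_that(set_size <= nrow(truth), "set_size exceeds n_proteins",
              "config")
  set.seed(as_seed(seed + 32452843))
  gain <- truth$aggregates_treated & !truth$aggregates_control
  w <- ifelse(gain, enrichment_odds, 1)
  members <- sample(truth$id, set_size, prob = w)
  a <- sum(members %in% truth$id[gain])
  b <- set_size - a
  c_ <- sum(gain) - a
  d <- sum(!gain) - b
  or <- if (b > 0 && c_ > 0) (a / b) / (c_ / d) else Inf
  out <- structure(setNames(list(members), name),
                   class = c("gene_set_collection", "list"))
  attr(out, "realized_odds_ratio") <- or
  out
}

#' Recovery of planted differential aggregation
#'
#' Compares up-calls against the simulated truth: sensitivity is the
#' fraction of true treatment-induced aggregators called up; the empirical
#' FDR is the fraction of up-calls that are not true induced aggregators
#' (0 when nothing is called).
#'
#' @param calls A called differential tibble (or `aggdiff` object).
#' @param truth A [simulate_proteome()] tibble.
#' @return One-row tibble: `sensitivity`, `empirical_fdr`, `n_true`,
#'   `n_called`.
#' @export
evaluate_recovery <- function(calls, truth) {
  if (inherits(calls, "aggdiff")) calls <- tidy(calls)
  gainers <- truth$id[truth$aggregates_treated & !truth$aggregates_control]
  called_up <- calls$id[calls$call == "up"]
  tp <- length(intersect(called_up, gainers))
  tibble(
    sensitivity = if (length(gainers) > 0) tp / length(gainers) else NA_real_,
    empirical_fdr = if (length(called_up) > 0) {
      (length(called_up) - tp) / length(called_up)
    } else 0,
    n_true = length(gainers),
    n_called = length(called_up)
  )
}

#' Simulate a complete synthetic experiment
#'
#' One call generating every input the pipeline consumes: ground truth with
#' an exact number of planted treatment-induced aggregators, LFQ tables with
#' MNAR missingness, transcript counts, a propensity score table (the truth
#' propensity observed with noise, standing in for an imported predictor),
#' and a planted annotation set.
#'
#' Control aggregation flags are drawn from the logistic threshold model;
#' the treated condition then gains exactly `n_planted` additional
#' aggregators sampled among non-control-aggregators with probability
#' proportional to the lowered-threshold logistic weight, so high-sigma
#' proteins aggregate preferentially and the planted count is exact.
#' `n_planted = 0` with `tau_treated = tau_control` gives a true null.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param n_planted Number of planted treatment-induced aggregators
#'   (default 150).
#' @param seed Integer seed.
#' @param propensity_noise_sd SD of the observation noise on the score-table
#'   propensity (default 0.3).
#' @param enrichment_odds,set_size Planted annotation set parameters
#'   (the set size shrinks with small proteomes).
#' @param ... Overrides passed to [simulation_config()].
#' @return A list of class `"agg_simulation"`: `truth`, `protein_groups`,
#'   `design`, `design_aggregate`, `counts`, `score_table`, `gene_sets`,
#'   `config`.
#' @export
simulate_experiment <- function(n_proteins = 2000, n_planted = 150,
                                seed = 1L, propensity_noise_sd = 0.3,
                                enrichment_odds = 5,
                                set_size = min(200, n_proteins %/% 5),
                                ...) {
  cfg <- simulation_config(n_proteins = n_proteins, seed = seed, ...)
  truth <- simulate_proteome(cfg)
  # exact-count planting: treated = control + n_planted weighted gainers
  set.seed(as_seed(seed + 49979687))
  candidates <- which(!truth$aggregates_control)
  assert_that(n_planted <= length(candidates),
              "n_planted exceeds available non-aggregating proteins",
              "config")
  truth$aggregates_treated <- truth$aggregates_control
  if (n_planted > 0) {
    w <- plogis((truth$sigma[candidates] - cfg$tau_treated) /
                  cfg$aggregation_steepness)
    w <- pmax(w, 1e-9)
    planted <- sample(candidates, n_planted, prob = w)
    truth$aggregates_treated[planted] <- TRUE
  }
  lfq <- simulate_lfq(truth, cfg)
  counts <- simulate_counts(truth, cfg, n_samples = cfg$n_replicates)
  set.seed(as_seed(seed + 86028121))
  score_table <- tibble(
    id = truth$id,
    tango = truth$propensity_z + rnorm(nrow(truth), 0, propensity_noise_sd)
  )
  sets <- simulate_annotations(truth, enrichment_odds = enrichment_odds,
                               set_size = set_size, seed = seed)
  structure(list(truth = truth, protein_groups = lfq$table,
                 design = lfq$design,
                 design_aggregate = lfq$design_aggregate,
                 counts = counts, score_table = score_table,
                 gene_sets = sets, config = cfg),
            class = "agg_simulation")
}

#' Write a simulated experiment to disk
#'
#' Emits proteinGroups-style TSV (zeros for non-detections), a design TSV,
#' a counts TSV, a score TSV, a GMT file, a truth TSV and a JSON manifest
#' with the configuration and seed.
#'
#' @param sim An [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    protein_groups = file.path(dir, "proteinGroups.tsv"),
    design = file.path(dir, "design.tsv"),
    counts = file.path(dir, "counts.tsv"),
    scores = file.path(dir, "scores.tsv"),
    gene_sets = file.path(dir, "sets.gmt"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  pg <- sim$protein_groups
  out <- tibble(
    `Majority protein IDs` = pg$group_id,
    `Gene names` = pg$genes,
    `Razor + unique peptides` = pg$razor_unique_peptides,
    `Potential contaminant` = ifelse(pg$contaminant, "+", ""),
    Reverse = ifelse(pg$reverse, "+", "")
  )
  for (s in sim$design$sample) {
    v <- pg[[s]]
    v[is.na(v)] <- 0
    out[[paste("LFQ intensity", s)]] <- v
  }
  readr::write_tsv(out, paths["protein_groups"], progress = FALSE)
  readr::write_tsv(sim$design, paths["design"], progress = FALSE)
  readr::write_tsv(dplyr::bind_cols(tibble(gene = rownames(sim$counts)),
                                    as_tibble(sim$counts)),
                   paths["counts"], progress = FALSE)
  readr::write_tsv(sim$score_table, paths["scores"], progress = FALSE)
  writeLines(vapply(names(sim$gene_sets), function(nm) {
    paste(c(nm, "simulated", sim$gene_sets[[nm]]), collapse = "\t")
  }, character(1)), paths["gene_sets"])
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  jsonlite::write_json(
    list(config = sim$config[setdiff(names(sim$config), "")],
         seed = sim$config$seed),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
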