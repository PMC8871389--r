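# End-to-end orchestration: differential aggregation -> fraction
# classification -> metastability -> enrichment (-> RNA-seq DE when counts
# and groups are supplied), with seeded reproducibility and a checksummed
# run manifest.

default_config <- function() {
  list(
    inputs = list(protein_groups = NULL, design = NULL, counts = NULL,
                  scores = NULL, gene_sets = NULL),
    differential = list(min_identified_repeats = 2, n_draws = 100,
                        downshift = 1.8, width = 0.3, alpha = 0.05,
                        lfc_threshold = 1, min_nonimputed = 2,
                        var_equal = FALSE),
    fractions = list(min_reps = 2, alpha = 0.05),
    metastability = list(pseudocount = 1, propensity_score = "tango",
                         pscore_threshold = 4),
    enrichment = list(background = "nia"),
    rnaseq = list(groups = NULL, min_count = 2, min_samples = 2,
                  lfc_cut = 1, fdr_cut = 0.05),
    seed = 1L,
    out_dir = NULL
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path",
              "config")
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop_agg(paste0("unknown config key(s): ",
                    paste(unknown, collapse = ", ")), "config")
  }
  utils::modifyList(default_config(), config)
}

#' Run the full aggregation analysis
#'
#' Executes the pipeline end-to-end from a structured configuration (a list
#' or a YAML file): proteinGroups ingestion and contaminant filtering,
#' differential aggregation, fraction classification, supersaturation and
#' per-fraction score summaries (when counts and a score table are given),
#' annotation-set enrichment (when gene sets are given), and the RNA-seq DE
#' stage (when counts plus `rnaseq$groups` are given). All result tables
#' are written as TSV under `out_dir` together with a JSON manifest listing
#' the configuration, the seed and an md5 checksum per output.
#'
#' @param config A config list or path to a YAML file. Recognised keys:
#'   `inputs` (paths: `protein_groups`, `design`, optional `counts`,
#'   `scores`, `gene_sets`), `differential`, `fractions`, `metastability`,
#'   `enrichment`, `rnaseq`, `seed`, `out_dir`.
#' @param seed Optional seed overriding the config.
#' @return The run manifest (list of class `"run_manifest"`), invisibly
#'   containing config, seed, per-stage summaries, output paths and
#'   checksums.
#' @export
run_full_analysis <- function(config, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  assert_that(!is.null(cfg$out_dir), "config needs an out_dir", "config")
  for (key in c("protein_groups", "design")) {
    path <- cfg$inputs[[key]]
    assert_that(!is.null(path), paste0("config input '", key,
                                       "' is required"), "config")
    assert_that(file.exists(path),
                paste0("input file not found: ", path), "config")
  }
  for (key in c("counts", "scores", "gene_sets")) {
    path <- cfg$inputs[[key]]
    if (!is.null(path) && !file.exists(path)) {
      stop_agg(paste0("input file not found: ", path), "config")
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    write_tsv_out(x, path)
    outputs[[name]] <<- path
  }

  design <- readr::read_tsv(cfg$inputs$design, show_col_types = FALSE,
                            progress = FALSE)
  design <- sample_design(design$sample, design$condition,
                          design$replicate, design$fraction,
                          design$cell_line %||% "unknown")
  pg <- read_protein_groups(cfg$inputs$protein_groups, design)
  pg <- filter_contaminants_reverse(pg)

  agg_design <- design[design$fraction == "aggregate", , drop = FALSE]
  wcl_design <- design[design$fraction == "WCL", , drop = FALSE]
  d <- cfg$differential
  fit <- differential_aggregation(
    pg, agg_design,
    min_identified_repeats = d$min_identified_repeats,
    n_draws = d$n_draws, downshift = d$downshift, width = d$width,
    seed = cfg$seed, alpha = d$alpha, lfc_threshold = d$lfc_threshold,
    min_nonimputed = d$min_nonimputed, var_equal = d$var_equal)
  emit(tidy(fit), "differential_aggregation.tsv")

  agg_mat <- as.matrix(pg[, agg_design$sample, drop = FALSE])
  aggregate_detected <- pg$id[rowSums(!is.na(agg_mat)) >= 1]
  wcl_ids <- character(0)
  if (nrow(wcl_design) > 0) {
    wcl_mat <- as.matrix(pg[, wcl_design$sample, drop = FALSE])
    wcl_ids <- pg$id[rowSums(!is.na(wcl_mat)) >= 1]
  }
  labels <- classify_fractions(tidy(fit), wcl_ids,
                               min_reps = cfg$fractions$min_reps,
                               alpha = cfg$fractions$alpha,
                               aggregate_ids = aggregate_detected)
  emit(labels, "fraction_labels.tsv")

  stage_summaries <- list(differential = glance(fit),
                          fractions = as.list(table(labels$label)))

  if (!is.null(cfg$inputs$counts) && !is.null(cfg$inputs$scores)) {
    counts <- read_count_matrix(cfg$inputs$counts)
    scores <- read_score_table(cfg$inputs$scores)
    score_col <- cfg$metastability$propensity_score
    assert_that(score_col %in% names(scores),
                paste0("score column '", score_col,
                       "' absent from score table"), "config")
    propensity <- tibble(id = scores$id, score = scores[[score_col]])
    abundance <- mean_cpm(counts)
    ref_ids <- if (length(wcl_ids) > 0) wcl_ids else propensity$id
    ss <- supersaturation_scores(propensity, abundance,
                                 reference_ids = ref_ids,
                                 pseudocount = cfg$metastability$pseudocount)
    emit(ss, "supersaturation.tsv")
    sigma <- setNames(ss$sigma, ss$id)
    emit(suppressWarnings(fraction_score_summary(sigma, labels)),
         "sigma_by_fraction.tsv")
    stage_summaries$metastability <- list(tau = attr(ss, "tau"))
  }

  if (!is.null(cfg$inputs$gene_sets)) {
    sets <- read_gene_sets(cfg$inputs$gene_sets)
    enr <- enrichment_analysis(labels, sets,
                               background = cfg$enrichment$background)
    emit(enr, "enrichment.tsv")
    stage_summaries$enrichment <- list(n_tests = nrow(enr))
  }

  if (!is.null(cfg$inputs$counts) && !is.null(cfg$rnaseq$groups)) {
    counts <- read_count_matrix(cfg$inputs$counts)
    r <- cfg$rnaseq
    de <- rnaseq_de(counts, r$groups, min_count = r$min_count,
                    min_samples = r$min_samples, lfc_cut = r$lfc_cut,
                    fdr_cut = r$fdr_cut)
    emit(tidy(de), "rnaseq_de.tsv")
    stage_summaries$rnaseq <- glance(de)
  }

  manifest <- structure(
    list(config = cfg, seed = cfg$seed,
         timestamp = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("aggregomics")),
         stages = stage_summaries,
         outputs = outputs,
         checksums = vapply(outputs, function(p) unname(tools::md5sum(p)),
                            character(1)),
         input_checksums = vapply(
           Filter(Negate(is.null), cfg$inputs),
           function(p) unname(tools::md5sum(p)), character(1))),
    class = "run_manifest")
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest[setdiff(names(manifest), "config")],
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %s; %d output(s) in %s\n",
              x$seed, length(x$outputs), x$config$out_dir))
  invisible(x)
}
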