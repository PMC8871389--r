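# Ingestion of external inputs: MaxQuant proteinGroups tables, gene sets,
# sequences, count matrices and precomputed per-protein score tables.

score_registry <- c("tango", "camsol", "catgranule", "pscore", "nsaf")

#' Read a MaxQuant proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` produced by MaxQuant into a
#' tidy per-protein-group table. LFQ intensities of exactly 0 denote
#' non-detection and are converted to `NA` (they are later imputed, never
#' treated as true zeros). Contaminant and reverse-decoy flags follow the
#' MaxQuant `"+"` convention.
#'
#' @param path Path to a tab-separated proteinGroups file.
#' @param design A [sample_design()] tibble; every `sample` label must have a
#'   matching `LFQ intensity <label>` column in the file.
#' @return A tibble with one row per protein group: `id` (first accession of
#'   the majority-protein list), `group_id` (full semicolon-separated list),
#'   `genes`, `razor_unique_peptides`, logical `contaminant` and `reverse`
#'   flags, and one numeric intensity column per design sample. The design is
#'   attached as attribute `"design"`.
#' @export
read_protein_groups <- function(path, design) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         name_repair = "minimal", progress = FALSE)
  nm <- names(raw)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    stop_agg(paste0("duplicated column(s) in proteinGroups file: ",
                    paste(unique(dup), collapse = ", ")), "format")
  }
  required <- c("Majority protein IDs", "Gene names",
                "Potential contaminant", "Reverse")
  missing_col <- setdiff(required, nm)
  if (length(missing_col) > 0) {
    stop_agg(paste0("missing required column(s): ",
                    paste(missing_col, collapse = ", ")), "format")
  }
  lfq_cols <- paste("LFQ intensity", design$sample)
  no_match <- design$sample[!(lfq_cols %in% nm)]
  if (length(no_match) > 0) {
    stop_agg(paste0("design sample(s) with no matching LFQ column: ",
                    paste(no_match, collapse = ", ")), "design")
  }
  out <- tibble(
    group_id = as.character(raw[["Majority protein IDs"]]),
    genes = as.character(raw[["Gene names"]]),
    razor_unique_peptides =
      if ("Razor + unique peptides" %in% nm)
        as.integer(raw[["Razor + unique peptides"]]) else NA_integer_,
    contaminant = !is.na(raw[["Potential contaminant"]]) &
      raw[["Potential contaminant"]] == "+",
    reverse = !is.na(raw[["Reverse"]]) & raw[["Reverse"]] == "+"
  )
  out$id <- first_accession(out$group_id)
  out <- dplyr::relocate(out, "id")
  for (i in seq_len(nrow(design))) {
    v <- suppressWarnings(as.numeric(raw[[lfq_cols[i]]]))
    if (any(v < 0, na.rm = TRUE)) {
      stop_agg("negative LFQ intensity encountered", "format")
    }
    v[!is.na(v) & v == 0] <- NA_real_
    out[[design$sample[i]]] <- v
  }
  attr(out, "design") <- design
  out
}

#' Remove contaminant and reverse-decoy protein groups
#'
#' @param table A protein-group tibble with logical `contaminant` and
#'   `reverse` columns.
#' @return The table without flagged rows (row order preserved); the number
#'   of removed rows is attached as attribute `"n_removed"` and reported.
#' @export
filter_contaminants_reverse <- function(table) {
  assert_that(all(c("contaminant", "reverse") %in% names(table)),
              "flag columns 'contaminant' and 'reverse' are required",
              "format")
  drop <- table$contaminant | table$reverse
  out <- table[!drop, , drop = FALSE]
  attr(out, "design") <- attr(table, "design")
  attr(out, "n_removed") <- sum(drop)
  rlang::inform(sprintf("filtered %d contaminant/reverse protein group(s)",
                        sum(drop)))
  out
}

first_accession <- function(group_id) {
  vapply(strsplit(as.character(group_id), ";", fixed = TRUE),
         function(x) trimws(x[[1]]), character(1))
}

#' Read annotation gene sets
#'
#' Supports the GMT dialect (tab-separated: set name, description, then
#' members; no header) and a headed two/three-column table
#' (`set`, `member`, optional numeric `evidence`). With `min_evidence`,
#' members whose evidence count falls below the cutoff are excluded — e.g.
#' chaperone clients kept only when identified in at least two of three
#' replicate pull-downs.
#'
#' @param path File path.
#' @param min_evidence Optional integer; members with evidence below this are
#'   dropped (only meaningful for the columnar dialect with an evidence
#'   column).
#' @return A named list of unique member identifier vectors, classed
#'   `"gene_set_collection"`.
#' @export
read_gene_sets <- function(path, min_evidence = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "gene-set file is empty", "format")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1]]))
  if (header[1] == "set") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(tab) <- tolower(names(tab))
    assert_that(all(c("set", "member") %in% names(tab)),
                "columnar gene-set file needs 'set' and 'member' columns",
                "format")
    all_sets <- unique(as.character(tab$set))
    if (!is.null(min_evidence) && "evidence" %in% names(tab)) {
      tab <- tab[is.na(tab$evidence) | tab$evidence >= min_evidence, ,
                 drop = FALSE]
    }
    sets <- split(as.character(tab$member), tab$set)
    # sets emptied by the evidence filter are retained as empty
    for (nm in setdiff(all_sets, names(sets))) sets[[nm]] <- character(0)
    sets <- sets[all_sets]
  } else {
    assert_that(all(lengths(fields) >= 3),
                "GMT lines need at least 3 tab-separated fields", "format")
    sets <- lapply(fields, function(f) trimws(f[-c(1, 2)]))
    names(sets) <- vapply(fields, `[[`, character(1), 1)
  }
  assert_that(!anyDuplicated(names(sets)), "gene-set names must be unique",
              "format")
  sets <- lapply(sets, function(m) unique(m[nzchar(m)]))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    rlang::warn(paste0("gene set(s) empty after filtering: ",
                       paste(empty, collapse = ", ")))
  }
  structure(sets, class = c("gene_set_collection", "list"))
}

#' Reconcile protein/gene identifiers
#'
#' Resolves semicolon-separated protein-group identifiers to their first
#' accession, then applies an optional user-supplied mapping (e.g. accession
#' to gene symbol, or cross-species homolog tables). Gene-symbol matching is
#' case-insensitive after whitespace stripping; identifiers absent from the
#' mapping pass through unchanged and are counted.
#'
#' @param ids Character vector of identifiers.
#' @param mapping Optional named character vector (`names` = source id,
#'   values = target id).
#' @return A unique character vector with attribute `"n_unmapped"`.
#' @export
map_identifiers <- function(ids, mapping = NULL) {
  out <- first_accession(trimws(ids))
  n_unmapped <- 0L
  if (!is.null(mapping)) {
    key <- toupper(trimws(names(mapping)))
    hit <- match(toupper(out), key)
    n_unmapped <- sum(is.na(hit))
    out[!is.na(hit)] <- unname(mapping[hit[!is.na(hit)]])
  }
  out <- unique(out)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# case-insensitive membership for symbol-keyed sets
match_ids <- function(x, table) toupper(trimws(x)) %in% toupper(trimws(table))

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A named character vector of amino-acid sequences (20-letter
#'   alphabet plus `X`); residues outside the alphabet are replaced with `X`
#'   with a warning.
#' @export
read_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1)
  assert_that(!anyDuplicated(names(seqs)), "duplicate sequence identifiers",
              "format")
  assert_that(all(nchar(seqs) > 0), "empty sequence in FASTA", "format")
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  bad <- vapply(strsplit(seqs, ""),
                function(s) any(!(s %in% alphabet)), logical(1))
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d sequence(s) contain non-standard residues; mapped to X", sum(bad)))
    seqs[bad] <- vapply(strsplit(seqs[bad], ""), function(s) {
      s[!(s %in% alphabet)] <- "X"
      paste(s, collapse = "")
    }, character(1))
  }
  seqs
}

#' Read a gene-by-sample count matrix
#'
#' @param path Tab-separated file: first column gene identifiers, remaining
#'   columns nonnegative integer counts per sample.
#' @return An integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(ncol(tab) >= 2, "count file needs gene ids plus >=1 sample",
              "format")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) ||
      any(m != floor(m))) {
    stop_agg("counts must be nonnegative integers", "format")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read a precomputed per-protein score table
#'
#' Imports externally computed predictor outputs (TANGO, CamSol, catGRANULE,
#' PScore, NSAF abundance). Imported scores are authoritative over the
#' built-in simplified predictors when supplied.
#'
#' @param path Tab-separated file with an `id` column plus one or more score
#'   columns named from the registry
#'   (`tango`, `camsol`, `catgranule`, `pscore`, `nsaf`).
#' @return A tibble `id` + numeric score columns.
#' @export
read_score_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  assert_that("id" %in% names(tab), "score table needs an 'id' column",
              "format")
  unknown <- setdiff(names(tab), c("id", score_registry))
  if (length(unknown) > 0) {
    stop_agg(paste0("unknown score column(s): ",
                    paste(unknown, collapse = ", "),
                    " (registry: ", paste(score_registry, collapse = ", "),
                    ")"), "format")
  }
  assert_that(!anyDuplicated(tab$id), "duplicate identifiers in score table",
              "format")
  tab$id <- as.character(tab$id)
  as_tibble(tab)
}

#' Write a tibble as TSV (round-trip safe)
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
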