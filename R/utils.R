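# shared internal helpers

# stop with a classed condition so callers can test on error class
stop_agg <- function(msg, class) {
  rlang::abort(msg, class = paste0("aggregomics_", class))
}

assert_that <- function(ok, msg, class = "invalid_input") {
  if (!isTRUE(ok)) stop_agg(msg, class)
}

# seeds must stay valid 32-bit integers whatever arithmetic produced them
as_seed <- function(x) {
  as.integer(abs(x) %% (.Machine$integer.max - 1L)) + 1L
}

# design accessors ------------------------------------------------------

#' Build a sample design table
#'
#' Describes the columns of an LFQ intensity table: which experimental
#' condition, replicate and fraction (SDS-insoluble aggregate or whole-cell
#' lysate) each sample belongs to.
#'
#' @param sample Character vector of unique sample labels; these must match
#'   the `LFQ intensity <label>` columns of the proteinGroups file.
#' @param condition `"case"` or `"control"` per sample.
#' @param replicate Positive integer replicate index per sample.
#' @param fraction `"aggregate"` or `"WCL"` per sample.
#' @param cell_line Cell line label (single string or per sample).
#' @return A tibble with one row per sample.
#' @export
sample_design <- function(sample, condition, replicate,
                          fraction = "aggregate", cell_line = "unknown") {
  assert_that(!anyDuplicated(sample), "sample labels must be unique",
              "design")
  assert_that(all(condition %in% c("case", "control")),
              "condition must be 'case' or 'control'", "design")
  assert_that(all(fraction %in% c("aggregate", "WCL")),
              "fraction must be 'aggregate' or 'WCL'", "design")
  assert_that(all(replicate >= 1 & replicate == as.integer(replicate)),
              "replicate must be a positive integer", "design")
  tibble(sample = as.character(sample),
         condition = as.character(condition),
         replicate = as.integer(replicate),
         fraction = as.character(fraction),
         cell_line = as.character(cell_line))
}

design_samples <- function(design, condition = NULL) {
  x <- design
  if (!is.null(condition)) x <- x[x$condition == condition, , drop = FALSE]
  x$sample
}
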