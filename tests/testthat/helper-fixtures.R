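# programmatic fixtures; everything is built in code at test time

tiny_design <- function() {
  sample_design(c("c1", "c2", "t1", "t2"),
                condition = c("control", "control", "case", "case"),
                replicate = c(1, 2, 1, 2))
}

# MaxQuant-style proteinGroups file with 3 rows (one reverse-flagged) and
# one zero intensity
write_tiny_protein_groups <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    paste("Majority protein IDs", "Gene names", "Razor + unique peptides",
          "Potential contaminant", "Reverse",
          "LFQ intensity c1", "LFQ intensity c2",
          "LFQ intensity t1", "LFQ intensity t2", sep = "\t"),
    paste("P11111;Q22222", "GENA", 5, "", "", 1e6, 2e6, 4e6, 8e6,
          sep = "\t"),
    paste("P33333", "GENB", 3, "", "+", 1e5, 1e5, 1e5, 1e5, sep = "\t"),
    paste("P44444", "GENC", 2, "", "", 0, 3e6, 3e6, 0, sep = "\t")
  )
  writeLines(lines, path)
  path
}

write_tiny_gmt <- function(path = tempfile(fileext = ".gmt")) {
  writeLines(c(
    "setA\tdesc\tP11111\tP44444\tP11111",
    "setB\tdesc\tX1\tX2\tX3"
  ), path)
  path
}

write_tiny_set_table <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "set\tmember\tevidence",
    "clients\tHSPB1\t3",
    "clients\tDNAJA1\t2",
    "clients\tWEAK1\t1",
    "clients\tHSPB1\t3"
  ), path)
  path
}

write_tiny_fasta <- function(path = tempfile(fileext = ".fa")) {
  writeLines(c(">P1 some description", "MKVLAAGG", ">P2", "RRGGYYFF"),
             path)
  path
}

write_tiny_counts <- function(path = tempfile(fileext = ".tsv"),
                              bad = FALSE) {
  writeLines(c(
    "gene\ts1\ts2",
    "g1\t10\t20",
    paste0("g2\t", if (bad) "-1" else "5", "\t0")
  ), path)
  path
}

# a complete (no missing) log-intensity tibble for differential tests
complete_log_matrix <- function(values, design = tiny_design()) {
  stopifnot(ncol(values) == nrow(design))
  out <- tibble::tibble(
    id = sprintf("P%03d", seq_len(nrow(values))),
    n_detected_case = as.integer(
      rowSums(!is.na(values[, design$condition == "case", drop = FALSE]))),
    n_detected_control = as.integer(
      rowSums(!is.na(values[, design$condition == "control",
                            drop = FALSE])))
  )
  for (k in seq_len(ncol(values))) out[[design$sample[k]]] <- values[, k]
  attr(out, "design") <- design
  out
}

# independent brute-force BH (sort, step-up, cumulative min)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# closed-form 2x2 chi-square
chi2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Kruskal-Wallis H from first principles (pooled ranks, tie correction)
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  h <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
wilcox_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  lo <- mean(v_all <= v_obs)
  hi <- mean(v_all >= v_obs)
  min(1, 2 * min(lo, hi))
}

# Poisson likelihood-ratio test oracle (closed-form rate MLEs)
poisson_lrt_oracle <- function(y, lib, grp) {
  ll <- function(yy, ll_) {
    q <- sum(yy) / sum(ll_)
    sum(stats::dpois(yy, pmax(q * ll_, 1e-300), log = TRUE))
  }
  i1 <- grp == levels(factor(grp))[1]
  vapply(seq_len(nrow(y)), function(i) {
    2 * (ll(y[i, i1], lib[i1]) + ll(y[i, !i1], lib[!i1]) -
           ll(y[i, ], lib))
  }, numeric(1))
}
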