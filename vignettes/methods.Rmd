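---
title: "Models and methods behind aggregomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aggregomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggregomics)
```

This vignette documents the statistical models the package implements,
the tunable parameters and their defaults, the design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Differential aggregation from label-free proteomics

The experiment contrasts SDS-insoluble (aggregate) fractions of treated
("case") and untreated ("control") cells, typically 4 replicates per
condition, quantified by MaxQuant LFQ intensities. The model of the data
is deliberately simple:

* log2 LFQ intensities are approximately normal within a sample;
* an intensity of exactly 0 is a non-detection, not a true zero;
* non-detections are missing-not-at-random (MNAR): a cell's value is
  missing preferentially when the underlying intensity is low, because it
  fell below the instrument's detection limit.

### Imputation

Because missingness is MNAR, mean- or kNN-style imputation would be
biased upward. Instead each missing cell in sample $j$ is drawn from a
*downshifted Gaussian*,

$$x_{ij}^{(d)} \sim N\!\left(\mu_j - \delta\,\sigma_j,\; (w\,\sigma_j)^2\right),$$

where $\mu_j$ and $\sigma_j$ are the mean and SD of the *observed* values
in sample $j$, the downshift is $\delta = 1.8$ and the width $w = 0.3$
(the de-facto community defaults for this family of imputations, exposed
in `ImputationConfig`-style arguments of `impute_missing()`). The draw is
repeated `n_draws = 100` times and the completed matrices averaged
cell-wise; observed values are never altered.

Two numerical details matter:

* **Determinism.** Draw $d$ re-seeds the generator at `seed + d` and
  draws a value for *every* cell of the matrix, so the value imputed into
  cell $(i, j)$ is a pure function of `(seed, d, i, j)` — independent of
  the missingness pattern, of row filtering upstream, and of iteration
  order. Identical seeds give bit-identical pipelines.
* **Degenerate samples.** A sample with fewer than two observed values
  has no usable $\mu_j, \sigma_j$; the implementation falls back to the
  global mean/SD across all samples, with a warning.

Averaging 100 draws makes imputed values nearly deterministic (SD
$w\sigma_j/10$). This is intentional — it mirrors the upstream analysis
convention of testing the averaged matrix — but it means imputed cells
carry artificially small variance. The replicate gate below exists
precisely to keep that artifact out of the calls.

### Testing and calling

Per protein, a two-sided t-test compares case and control columns of the
completed matrix, and `log2fc` is mean(case) − mean(control). The test
variant was an open choice: Welch's unequal-variance test is the default
(robust when one side is mostly imputed and hence nearly constant), with
the classical pooled-variance Student test available via
`var_equal = TRUE`. P-values are Benjamini–Hochberg adjusted.

A protein is called `up` when

* $p_\text{adj} \le 0.05$ (inclusive),
* $\log_2 FC \ge 1$ (inclusive), and
* it was detected — not imputed — in at least 2 case replicates;

`down` is the mirror rule on the control side. Where prose conventions
disagree on strict vs inclusive comparison at the boundary, the inclusive
rule is implemented for this stage (and the strict rule for the RNA-seq
stage, whose cutoffs are conventionally strict); boundary cases are rare
in practice but the tests pin the behaviour down.

## 2. Fraction classification

Labels partition the union of WCL- and aggregate-detected proteins:

| label | rule |
|---|---|
| `increased` / `decreased` | differential call |
| `baseline` | detected ≥ 2 replicates in *both* conditions, $p_\text{adj} > 0.05$ |
| `other_aggregate` | pellet-detected, matching neither rule |
| `nia` | detected only in the WCL |

When a protein satisfies both a call and the baseline rule, the call wins
— baseline is by definition the aggregation *unchanged* by treatment.
Proteins seen in only one pellet replicate are excluded from testing but
remain `other_aggregate` rather than `nia`; pass the full detection list
via `aggregate_ids` so the partition is over everything ever seen in a
pellet.

The cross-replicate `consistency_metric()` is the mean over ordered pairs
of $|A \cap B| / |A|$ — a directional overlap chosen because it reads
directly as "what fraction of one experiment's hits recur in another";
Jaccard would conflate recall with set-size imbalance.

## 3. Supersaturation and LLPS propensity

A protein can aggregate either because its sequence is intrinsically
aggregation-prone or because it is expressed near its solubility limit.
The supersaturation score puts both on one axis:

$$\sigma_i = \log_{10}(a_i + 1) + z_i,$$

with $a_i$ the transcript abundance (CPM; mean across samples by
default, protein-level abundance accepted by supplying a different
abundance table) and $z_i$ the aggregation propensity z-standardised
over the reference (WCL) proteome. The pseudocount defaults to 1 so that
$a = 0$ contributes nothing. The threshold $\tau$ is the *median* σ of
the WCL reference; `sigma > tau` flags a protein as relatively
supersaturated, and the iso-σ line through the median is the diagonal in
`plot_supersaturation()`. Standardising propensity before combining, and
using CPM rather than TPM, were open choices; both are parameters
(`reference_ids`, the abundance table) rather than hard-coded.

Imported predictor outputs (TANGO, CamSol, catGRANULE, PScore, NSAF) via
`read_score_table()` are always authoritative. The built-in predictors
are simplified, clearly-labelled approximations: a sliding-window mean
(window 7, roughly two β-strands wide) over shipped residue scales — the
aggregation scale rewards hydrophobic/β-prone residues and penalises
charged ones; the LLPS scale rewards disorder-promoting composition and
R/G/Y/F (π-π, cation-π) content. The per-protein summary is
mean(positive window scores) × fraction of windows positive, rewarding
both intensity and extent of high-scoring regions; an all-negative
profile scores 0. Unknown residues score 0 with a warning. The scales are
shipped as TSVs with checksums verified at load.

## 4. Enrichment and figure-level statistics

Annotation-set enrichment uses a 2×2 Pearson chi-square without
continuity correction (the large-sample use case; a zero margin raises an
error recommending an exact test). The background defaults to the NIA
set — proteins demonstrably expressed but never pellet-detected — which
is the conservative contrast for "is this set over-represented among
aggregators".

One calibration subtlety: the 2×2 statistic is discrete, so its null
p-values are *nearly* but never exactly uniform — a Kolmogorov–Smirnov
test against the continuous uniform will reject at large replicate
counts purely from the CDF jumps, whatever the implementation.
Calibration is therefore asserted as rejection-rate matching
($|\hat{P}(p \le \alpha) - \alpha|$ within three binomial standard
errors at $\alpha \in \{0.01, 0.05, 0.2\}$), which is the operative
meaning of "calibrated"; the acceptance script reports the raw KS
p-value alongside for transparency.

Kruskal–Wallis uses the tie-corrected H with the $\chi^2_{k-1}$
approximation (all-tied input returns $H = 0$, $p = 1$ by convention).
Dunn's post-hoc z-statistics are computed on the pooled ranks with tie
correction; the family-wise adjustment is Bonferroni by default (Šidák
via `method = "sidak"`) — the conventional reading when "Dunn's
correction" is stated without qualification. The Wilcoxon matched-pairs
signed-rank test drops zero differences, is exact (signed-rank
distribution) up to n = 25 without ties, and falls back to the
continuity-corrected normal approximation otherwise.

## 5. RNA-seq differential expression

The DE stage is intentionally minimal: genes with more than 1 count in
at least two samples are kept; logCPM uses the prior-damped convention
$\log_2\!\big((y_{gj} + p_j) / (L_j + 2p_j) \cdot 10^6\big)$ with
$p_j = 2 \cdot L_j / \bar{L}$; and the test is a negative-binomial
likelihood-ratio test with a single *common* dispersion and library-size
offsets. The dispersion is a method-of-moments estimate,
$\mathrm{mean}_g\,\max\!\big(0, (s^2_g - m_g)/m_g^2\big)$ over genes with
nonzero mean, using the pooled within-group variance. Rate MLEs are
fitted by a vectorised Newton iteration on $\log q$; at dispersion 0 the
closed-form Poisson MLE is exact and the test reduces to a Poisson LRT
(pinned to an independent oracle in the tests). Calls are strict:
|logFC| > 1 and FDR < 0.05.

This replaces gene-wise dispersion machinery on purpose — it keeps the
stage self-contained and its calibration testable (type-I error within
[0.04, 0.06] at $\alpha = 0.05$ under a matched-dispersion null). For
production RNA-seq analyses an externally computed DE table can be used
as a drop-in wherever a DE result is consumed. No TMM normalisation is
applied: 3′-end counting makes length normalisation unnecessary and
library-size offsets suffice for the simulated designs. Reported logFC
is the unshrunk fitted ratio; genes expressed in only one group can
therefore have infinite logFC, which the strict call rule handles
naturally.

## 6. The synthetic-data generator

`simulate_experiment()` operationalises a threshold model of
aggregation: treatment *lowers the cell-intrinsic aggregation
threshold*, so the most supersaturated proteins aggregate first. Per
protein: abundance $a \sim 10^{N(1.5, 1)}$ CPM (median ≈ 30 CPM, a
realistic transcript distribution), propensity $z \sim N(0,1)$,
$\sigma = \log_{10}(a+1) + z$, and

$$P(\text{aggregates in condition } c) =
  \mathrm{logistic}\!\big((\sigma - \tau_c)/s\big),$$

with $\tau_\text{control} = 4$, $\tau_\text{treated} = 3$ and steepness
$s = 0.25$. Aggregation is probabilistic rather than a hard threshold so
borderline proteins exist. For scenarios that need an exact planted
count, control flags are drawn from the model and the treated condition
then gains exactly `n_planted` extra aggregators sampled among
non-aggregators with the lowered-threshold logistic weights —
high-σ proteins aggregate preferentially and the count is exact;
`n_planted = 0` with equal thresholds is a true null.

The observation layer is where most design care went. The first-draft
model (flat per-class pellet intensities, shallow detection curve)
failed its own purpose: nearly every protein was pellet-detected
somewhere, collapsing the NIA background, and induced aggregators were
half-present in untreated pellets, contradicting the biology being
emulated. The frozen model is mechanistic:

* **WCL intensity** tracks abundance: $\log_2 I = 18 + \log_2(a+1)$,
  replicate noise SD 0.3 (a typical LFQ replicate spread).
* **Pellet intensity**: non-aggregating proteins contribute only a flat
  background (18.3 log2 units), well below the detection
  limit — a protein that does not aggregate leaves at most trace
  background in a pellet regardless of its expression. Aggregating
  proteins add `effect_size = 2` log2 units plus an abundance-scaled
  pellet amount (slope 0.5 per log2 CPM): the amount recovered in the
  pellet scales with how much of the protein the cell contains. This
  gives pellet samples a realistic dynamic range, which in turn gives
  the downshifted imputation a genuine low tail.
* **Detection** of each cell is logistic in its realised log2 intensity
  with midpoint 19.3 and slope 0.3 — a fairly sharp detection limit just
  above the background, so non-aggregators are mostly *absent* from
  pellets (the presence/absence structure the classifier relies on) and
  MNAR is intensity-driven by construction.
* **Transcripts** are negative-binomial with mean ∝ abundance × library
  size and dispersion 0.15 (typical for replicate cell-line RNA-seq);
  dispersion 0 gives Poisson counts.
* **Annotation sets** sample members with odds multiplied by
  `enrichment_odds` for treatment-induced aggregators; odds 1 is a null
  set. The propensity "score table" is the true z observed with N(0,
  0.3²) noise, standing in for an imported predictor.

What the generator does **not** emulate: peptide-level effects and
shared peptides, between-run normalisation drift, per-sample variation
in the detection curve (a single global midpoint/slope is used for test
stability), correlated missingness, batch structure, and any coupling
between transcript and protein noise. Tests passing on this generator
therefore demonstrate that the pipeline recovers a planted
lowered-threshold signal under MNAR missingness — not that it is robust
to every artifact of real LFQ data.

### Null-calibration caveat

Under the null with MNAR missingness, raw p-values are checked for
uniformity on the subset of proteins with complete observations. This is
deliberate: for partially imputed proteins the averaged imputation
shrinks one side's variance and biases its mean toward
$\mu_j - 1.8\sigma_j$, so their t-test p-values are not expected to be
uniform — that is exactly the artifact the detection gate exists to keep
out of the *calls* (the ≤ 1 % call-rate check runs on everything). On
complete observations the Welch p-values are as uniform as the
Welch–Satterthwaite approximation allows, which at n = 4 vs 4 is well
within Kolmogorov–Smirnov resolution.

## 7. Problem sizes and runtime

The test suite and acceptance script use 2 000-protein proteomes with
4 + 4 replicates (150 planted gainers; 5 seeds for recovery), 5 000
null genes for NB-LRT calibration, 2 000 replicate null sets for
enrichment calibration, and a 300-protein end-to-end determinism run —
sizes chosen so the full suite completes in well under a minute per
property while keeping Monte-Carlo error comfortably inside the asserted
bands.

## 8. Known limitations

* The built-in propensity scales are composition heuristics; they rank
  poly-charged vs hydrophobic sequences sensibly but are no substitute
  for the dedicated predictors they approximate.
* The common-dispersion NB test is anti-conservative for genes whose
  true dispersion exceeds the common estimate; with real data prefer an
  imported DE table from a gene-wise-dispersion tool.
* Identifier reconciliation is intentionally dumb (first accession,
  case-insensitive symbols, user-supplied mapping tables); no online ID
  mapping is attempted.
* `run_full_analysis()` recomputes all stages on every call; with fixed
  seeds the pipeline is deterministic, so reruns are byte-identical
  rather than cached.
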