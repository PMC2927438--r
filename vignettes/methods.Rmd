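---
title: "Methods: paired multi-omic integration in miRpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired multi-omic integration in miRpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRpair)
```

# The study design

miRpair analyzes matched tumor/normal cohorts — the motivating system is
uterine leiomyoma against patient-matched myometrium — in which every
statistic is computed within patient. The paired design removes
between-patient baseline variation, which dominates bulk expression arrays,
and it defines the natural permutation group for significance testing:
sign flips of the per-case differences.

The pipeline chains five analyses: (1) paired SAM differential expression
for mRNA and miRNA matrices; (2) selection of the top up- and down-regulated
miRNAs and integration against two target-prediction tables; (3)
hypergeometric enrichment, per-pair correlation and box-plot summaries of
the inverse-association sets; (4) aCGH loss/gain segment calling with
cross-patient minimal common regions annotated by miRNA loci; and (5) net
immunoscore analysis of ordinal IHC scores against miRNA levels.

# Paired SAM

For feature $i$ with differences $z_{ij} = \text{tumor}_{ij} -
\text{normal}_{ij}$ over $n$ pairs,
$$\bar d_i = \tfrac1n \sum_j z_{ij},\qquad
  s_i = \sqrt{\frac{\sum_j (z_{ij}-\bar d_i)^2}{n(n-1)}},\qquad
  d_i = \frac{\bar d_i}{s_i + s_0}.$$

* **$s_0$ (exchangeability/fudge factor).** Default is the
  coefficient-of-variation rule: candidate $s_0$ values are the 5%-spaced
  quantiles of $s$; for each candidate the spread (MAD) of $d$ is computed
  inside percentile windows of $s$, and the candidate minimizing the
  coefficient of variation of those spreads wins. When the search is
  degenerate (e.g. all-zero data) the 5th percentile of $s$ is used, and
  `s0_rule = "percentile:p"` selects a fixed percentile directly. With a
  percentile rule the whole call set is invariant to positive rescaling of
  the data.
* **Permutations.** The null is built from sign-flip vectors applied to the
  per-case differences: exhaustive ($2^n$, allowed up to $n = 12$, making
  small cohorts fully deterministic) or seeded sampling. Because
  $\sum_j z_{ij}^2$ is flip-invariant, permuted $\bar d$, $s$ and $d$ are
  computed by one matrix product per cohort.
* **Calling.** Observed order statistics of $d$ are compared with their
  permutation-expected values; for each $\Delta$ in a 50-point grid of
  $|d|$ quantiles, the asymmetric cutoffs are the first order statistics
  deviating by $\ge \Delta$, and
  $\widehat{\mathrm{FDR}}(\Delta) = \mathrm{median}_b\,\#\{|d^{*b}| \text{
  beyond cutoffs}\} / \#\text{called}$ with $\pi_0$ fixed at 1
  (conservative). The reported call set is the $\Delta$ that maximizes
  calls subject to $\widehat{\mathrm{FDR}} \le$ `fdr_target` (default 5%).
  A rule of the form "largest $\Delta$ passing" degenerates — arbitrarily
  large $\Delta$s call nothing and trivially pass — so maximal calls under
  FDR control is the operative definition; it is also standard SAM
  practice. Per-feature $q$ is the smallest estimated FDR at which the
  feature enters a call set.
* **Degenerate inputs.** Missing values are a hard error (no imputation);
  fewer than 3 pairs is an error; a zero-variance feature with nonzero
  effect combined with $s_0 = 0$ raises a degenerate-scale error, while
  all-zero data yield $d = 0$ and no calls.
* **Small-sample caveat.** A permutation-estimated FDR can be 0 for the
  single most extreme feature of a pure-noise cohort (the median exceedance
  count at its own cutoff is 0), so occasional isolated null calls are
  expected behavior of the estimator, at a rate well inside the FDR
  tolerance; the suite asserts a $\le 1\%$ null call rate rather than an
  impossible exact zero.

`top_k_mirnas()` picks the $k$ called-up features with largest $d$ and the
$k$ called-down with smallest $d$, ties broken by $|\bar d|$ then id; when
fewer are available it returns what exists and flags the shortage.

# Target integration

A gene is a **consensus target** of a miRNA set when at least one miRNA of
the set predicts it in source P1 *and* at least one does in source P2 —
union over miRNAs, intersection over sources, mirroring the
two-predictor-agreement filter. **Inverse sets** then intersect consensus
targets of the up-set with significantly down genes and vice versa;
a gene landing in both inverse sets is kept in both and flagged.
`coverage_percent()` reports $100\,|A \cup B| / n_{\text{dysregulated}}$.

Open choices, resolved as follows:

* **Enrichment test**: one-sided hypergeometric tail
  $p = \sum_{i\ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$, summed
  via `lchoose` in log space; it is the standard exact test for set
  overlap. The gene universe $N$ is the expression matrix after filtering
  (the array's population), not the genome.
* **Correlation**: Pearson by default (Spearman via `method=`), undefined —
  flagged, not numeric — when a vector is constant; quartiles use linear
  interpolation of order statistics (`type = 7`).
* **Clustering**: average-linkage on $1 - r$ distance; constant rows get
  the maximal distance 2 to everything; the ordering is deterministic for
  a fixed input.

# aCGH segment calling

Probe noise is estimated robustly from lag-1 differences within
chromosomes, $\hat\sigma = 1.4826\,\mathrm{median}|\Delta v|/\sqrt2$ —
insensitive to true copy-number steps, which contribute only two large
differences per segment. Candidate regions are seeded where the moving
average over a `window_bp` (default 1 Mb) window exceeds
$2\hat\sigma/\sqrt{m}$ ($m$ probes in the window), grown to the maximal run
of consecutive probes sharing the candidate's sign that are individually
noise-significant ($|v| > 2\hat\sigma$), and trimmed to the contiguous
sub-run maximizing the interval score $|{\sum v}|/\sqrt{n}$. The trimming
step is what pins boundaries at true breakpoints: a raw same-sign run
extension would absorb a geometric number of flanking noise probes, whereas
the score-optimal interval only admits a probe worth about half the running
mean or more. A candidate becomes a segment only when all three criteria
hold:

| criterion | default | meaning |
|---|---|---|
| `min_probes` | 10 | consecutive probes pointing in one direction |
| `min_fold` | 1.5 | $|\text{mean log}_2| \ge \log_2 1.5$ average fold difference |
| `score_threshold` | 6.0 | aberration score $|\text{mean}|\sqrt n/\hat\sigma$ |

Kept runs of one direction separated by fewer than 2 probes merge (and are
re-checked against the criteria). Negating a track exactly swaps loss and
gain. Coordinates are 0-based half-open throughout; BED in, BED out;
cytoband labels are deliberately never hard-coded because region sizes
depend on the genome build.

**Minimal common regions** use a sweep over the union of per-patient loss
intervals: elementary intervals between breakpoints are kept when covered
by at least `min_patients` patients and merged when contiguous, which
matches a per-coordinate coverage count (the test oracle). Locus annotation
uses `GenomicRanges::findOverlaps` with $\ge 1$ shared base; a brute-force
all-pairs scan is the oracle in tests.

# Net immunoscores

IHC scores live on a declared ordinal scale (default 0–4); making the scale
explicit allows validation. Per case and marker, net = tumor − normal;
records missing either half are dropped pairwise per marker (not listwise)
with a warning, maximizing $n$ per marker. Marker-versus-miRNA correlations
join on case id and reuse the same correlation routine as the expression
stage, so the two stages cannot drift apart.

# The synthetic cohort generator

`synth_config()` defines the reference simulation; `generate_cohort()`
draws everything from a single seeded stream (bit-identical per seed, and
the caller's RNG state is restored). What it emulates:

* **Expression**: Gaussian noise on the log2 scale (the standard model for
  normalized arrays), baselines per feature, 10 tumor/normal pairs by
  default — within the 5–36 range of the motivating studies and large
  enough for an exhaustive $2^{10}$ permutation null.
* **Repression**: 5 up and 5 down miRNAs, $|$shift$| \sim N(2, 0.25)$, each
  with 10 disjoint targets (100 true differential genes of shift magnitude
  about 2) and unit coupling `repression_beta`. A target's tumor value is
  depressed by $\beta$ times its regulator's *realized per-case* tumor
  deviation (expectation $-\beta\cdot$shift), so miRNA::target and
  miRNA::protein correlations carry genuine cross-case signal instead of a
  constant offset.
* **Predictors**: each source reports a true edge with probability 0.8 and
  uniform false edges at rate 0.01, making the precision gain of the
  two-source consensus measurable. Note the consequence: a true target
  enters the consensus with probability about $0.8^2$, so inverse-set
  recovery is assessed against the predictor-reachable targets.
* **aCGH**: 3 chromosomes × 500 probes at 50 kb spacing, probe noise sd
  0.1, heterozygous deletions at log2 ratio −1.0 (pure tumor; contamination
  would scale toward 0). Default deletions give one patient a large chr1
  loss, a second patient a contained smaller loss (a known minimal common
  region), and a third a private chr2 loss.
* **IHC**: marker genes are true targets of up-miRNAs; the ordinal score is
  a discretized linear readout of the marker's mRNA plus ±1 ordinal noise,
  clamped to the scale.

What it does **not** model: cross-study batch effects (the motivating
merged design is not simulated), dye bias, probe-level CEL artifacts,
correlated gene–gene noise, overlapping target sets, LOH or GC waves.
Passing tests therefore demonstrate correctness of the algorithms under the
stated statistical assumptions, not robustness to real-array artifacts.

# Problem sizes and determinism

The suite runs the reference cohort (2000 genes × 10 pairs, exhaustive 1024
sign flips) across 10 seeds for recovery properties, 1000-feature null
cohorts for calibration, exhaustive enumeration up to $N = 12$ for the
hypergeometric oracle, and $10^5$-bp tracks for the sweep-line oracle —
sizes chosen so each oracle is exact and the whole suite stays interactive.
`run_report()` re-run with the same configuration and seed writes
byte-identical summaries; `scripts/acceptance.R --seed N` reproduces every
reported quantity from scratch.

# Known limitations

* The permutation FDR is coarse below ~6 pairs (32 flips at $n=5$) and the
  single-most-extreme-feature artifact above applies.
* Prediction tables are consumed as given; no seed-match or conservation
  scoring is performed, and predictor scores are carried but not modeled.
* The interchange `probes.tsv` adds a leading `patient` column for
  multi-patient files; single-track files without it are accepted and
  assigned one anonymous patient.
* The pipeline consumes normalized log2 matrices; normalization of raw
  arrays is out of scope.
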