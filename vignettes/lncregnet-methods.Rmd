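---
title: "Methods: lncRNA-mRNA co-expression and regulatory network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA-mRNA co-expression and regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncregnet)
```

## The problem this package addresses

Custom expression microarrays that carry both mRNA and long non-coding RNA
(lncRNA) probes are a standard tool for asking how a treatment rewires a
cell's regulatory program. A typical design profiles a handful of patients
before and after treatment — here the motivating setting is fibroblast-like
synoviocytes (FLS) from rheumatoid arthritis patients, stimulated into an
inflammatory state and treated with an immunosuppressive compound. The
analysis questions are always the same:

1. Which probes (mRNA and lncRNA separately) change with treatment?
2. Which lncRNA-mRNA pairs are so strongly negatively correlated that the
   lncRNA plausibly represses the mRNA, and are those pairs *cis*
   (neighbouring loci) or *trans* (distant or on other chromosomes)?
3. What do the co-expression partners of a differential lncRNA say about
   its function (over-representation against functional gene sets)?
4. Which transcription factors (TFs) share targets with a lncRNA's
   co-expression neighbourhood, and what does the joint
   lncRNA-TF-target network look like?
5. Was the sample size adequate (bootstrap power)?

`lncregnet` implements this pipeline end to end, together with a
synthetic-data generator that plants recoverable ground truth so every
stage can be validated.

## Model and procedure

### Preprocessing

Raw intensities are log2-transformed (`log2_transform`, optional
pseudo-count) and quantile-normalized (`quantile_normalize`): the k-th
smallest value in each array is replaced by the mean of the k-th smallest
values across arrays, so that every array ends with the identical empirical
distribution. Ties within an array receive the mean of the reference values
of their tied ranks, which makes the result deterministic and independent
of probe order. Whether a vendor implementation ("quantile algorithm" in
array-analysis suites) matches this classic formulation exactly cannot be
established from the outside; the classic algorithm is what is implemented
and tested (including against `limma::normalizeQuantiles` on tie-free
input). Missing values are rejected rather than imputed: array scanners
emit complete matrices.

Detection-flag filtering keeps a probe when, in **at least one** of the two
conditions, at least a fraction `min_fraction_per_condition` (default 0.5)
of that condition's arrays call it present (`P`). The "at least one
condition" scope is the standard criterion for paired designs — a probe
switched fully off by treatment must survive the filter. What it means for
"a condition to have flag P" (any array, a majority, all arrays) is not
standardized; the default is a majority, and it is configurable. The fixed
pipeline order is log2 → quantile normalize → filter: normalization first
("initially") on the full matrix, filtering afterwards.

### Paired differential expression

With patients measured under both conditions, the correctly specified test
is the one-sample t-test on per-patient log2 differences
$d_i = y_{i,\mathrm{treated}} - y_{i,\mathrm{control}}$:

$$t = \frac{\bar d}{s_d/\sqrt n}, \qquad s_d^2 = \tfrac{1}{n-1}\sum_i (d_i-\bar d)^2,$$

two-sided P from $t_{n-1}$. Fold change is the anti-logged mean log-ratio,
$\mathrm{FC} = 2^{|\bar d|}$, reported with a separate up/down direction
(the ratio-of-arithmetic-means alternative is not used; the log-scale mean
is the quantity the t-test addresses). Benjamini-Hochberg step-up q-values
are computed over all tested probes. Selection defaults are
boundary-inclusive — FC ≥ 2.0 and P ≤ 0.05 — because methods-style wording
("fold change ≥ 2.0 and a P ≤ 0.05") and results-style wording
("p < 0.05, fold change > 2") conflict in this literature; the inclusive
reading is adopted and both thresholds are configurable. Probes with zero
variance of differences (which arise legitimately after quantile
normalization when a probe is rank-constant) are excluded with a logged
reason instead of being assigned P = 0, which would otherwise fabricate top
hits.

### Negative-pair screening and cis/trans classification

For every lncRNA × mRNA combination (by default restricted to the
differential lists), the Pearson correlation is computed across **all**
arrays — both conditions jointly, n = 10 at the default five patients. This
is deliberate: at n = 5 per condition a correlation of −0.9 has a two-sided
P of about 0.037, while published per-pair correlation P-values of order
10⁻⁴ at r = −0.9 are only attainable at n ≈ 10. A pair is retained when
`corr_p ≤ 0.05` and `r ≤ −0.9`. The r threshold is boundary-inclusive:
published pair tables print retained pairs at exactly R = −0.9 even where
the accompanying text says "r < −0.9"; inclusivity reconciles the two and
the boundary is configurable.

A retained pair is **cis** when (i) both loci are on the same chromosome,
(ii) the mRNA interval overlaps the lncRNA interval extended by 100 kb both
ways, and (iii) the correlation clears a stricter P ≤ 0.01; every other
retained pair is **trans**. Coordinates are 1-based inclusive throughout
(`chr9:2653919–2654254` spans 336 bp). The window is anchored on the
lncRNA's annotated transcript boundaries and *any* overlap of the mRNA
interval with the extended window counts — "within a window" is interval
language, and overlap is the least arbitrary reading. Strand is recorded
but ignored: "up- and down-stream" windows are applied symmetrically
without strand qualification. The genomic gap between non-overlapping
intervals is `max(0, start₂ − end₁ − 1)` — the count of bases strictly
between them (so intervals ending at 160,000 and starting at 200,000 are
39,999 bp apart).

### Over-representation and lncRNA function prediction

Enrichment uses the hypergeometric upper tail
$P = \sum_{j\ge k} \binom{K}{j}\binom{N-K}{n-j}/\binom{N}{n}$ with
universe N = the gene symbols surviving the flag filter on the array (not
the genome: standard ORA practice, and the least anti-conservative choice
available when the original universe is unstated). Sets with zero members
in the universe are dropped before BH correction — untestable hypotheses
must not inflate the correction — and one BH family is formed per query
list (per lncRNA). For function prediction, a differential lncRNA's query
list is the set of mRNAs whose correlation with it is significant at
P < 0.05 **in either direction** — unlike the repression screen, which
demands strong negative r; the two thresholds live in separate configs.

### TF association and networks

For each (lncRNA, TF) combination, the overlap between the lncRNA's
co-expressed gene list and the TF's target set is scored with the same
hypergeometric routine (single source of truth, asserted in tests), BH is
applied across all combinations tested, and associations are kept at
q ≤ 0.05. The bipartite lncRNA-TF graph carries −log10 P edge scores
(capped at 300 so exports stay finite); the tripartite graph adds TF→gene
edges only for targets that are *also* in the associated lncRNA's
co-expressed list — genes plausibly regulated by both. Exports are SIF
(edge list; isolated nodes are dropped because the format has none) and
GraphML with node-type and edge-score attributes, both loadable by
Cytoscape.

### Bootstrap power

The resampling unit is the patient (the pair), preserving the structure
the paired test assumes. For each candidate sample size m, patients are
drawn with replacement (duplicates retained as distinct observations), the
paired t-test and BH correction are rerun over the **full** probe set —
mirroring how the real analysis would be rerun on a smaller cohort — and a
target gene counts as detected when any of its probes passes the detection
rule (default q ≤ 0.5 with FC ≥ 2; the permissive q threshold follows the
convention of published minimum-sample-size analyses and is configurable).
Power is the detection fraction across replicates, with binomial standard
error $\sqrt{\hat p(1-\hat p)/B}$. Degenerate resamples (all draws the same
patient, probability $n^{1-n}$·n) hit the zero-variance rule and count as
non-detections.

## The synthetic-data generator

`simulate_dataset()` emits the full input bundle (expression + flags,
design, annotation, two GMT collections) plus a ground-truth manifest. The
generative model per probe g, patient i, condition c, in log2 space:

$$y_{gic} = \mathrm{baseline}_g + \alpha_{gi} + \Delta_g\,\mathbf 1[c = \mathrm{treated}] + \varepsilon_{gic}$$

with per-probe patient effects $\alpha_{gi} \sim N(0, 0.1^2)$ shared across
a patient's two arrays and residual noise
$\varepsilon \sim N(0, 0.15^2)$. Null probes have $\Delta_g = 0$; planted
differential probes draw $|\Delta_g|$ uniformly from `log2fc_range`
(default [1.0, 4.2], i.e. linear fold changes 2.0–18.4, the span reported
for arrays of this type) with random sign. Defaults: 5 patients, 2,000
mRNA + 1,000 lncRNA probes (a desk-scale stand-in for a 30,656 + 78,243
probe array; full scale is config-only), 3% of probes differential.

**Coupled pairs.** A planted pair (L, M) overwrites M's profile with an
affine negative transform of L's realized profile plus noise sized so the
expected across-array Pearson r equals `coupling_r_target` (default
−0.95): $y_M = b_M - (y_L - \bar y_L) + \eta$,
$\mathrm{sd}(\eta) = s_L\sqrt{1/r^2 - 1}$. Coupling on the mean structure
keeps every probe's marginal model unchanged and is trivial to calibrate;
no correlation matrix is constructed. Cis pairs are placed on one
chromosome at a gap drawn below `cis_max_gap` (default 80 kb, safely
inside the 100 kb window); trans pairs are forced onto different
chromosomes — so planted labels deterministically satisfy the
classifier's geometric predicate.

**TF modules.** Each module couples `tf_module_size` member mRNAs
positively to a driver lncRNA with weight jitter U(0.8, 1.2) and noise set
for a within-module driver-member correlation of 0.9; members therefore
share the driver's effect sign with jittered magnitude. The TF's target
set lists the members plus an equal number of null-gene decoys; per-module
function sets and decoy function sets are emitted alongside.

**Flags** are independent per cell (`A` with probability 0.02), with
options to force whole probes absent everywhere (removed by the filter) or
absent in one condition only (retained — exercising the "at least one
condition" rule). Planted-truth probes are always present so recovery
tests measure the statistics, not flag luck.

**What the generator does *not* emulate** — and hence what a green test
does not establish: optical/background noise, dye and batch effects, probe
sequence biases, realistic gene-length and chromosome occupancy, GO/KEGG
term hierarchy, and realistic between-patient heterogeneity. On that last
point a deliberate choice was made: with five patients measured twice, a
large patient effect makes each probe's 10-sample profile a 5-block
duplicate structure, which inflates the null rate of the n = 10
correlation test (it assumes exchangeable arrays). The generator's role is
to produce data with the statistical structure the analysis assumes, so
the default patient effect is kept small (sd 0.1, intra-class correlation
≈ 0.3); the measured null co-expression rate is then ≈ 5.8% at a nominal
5%. Real paired data has larger patient effects, and the correlation
screen applied to it is correspondingly anti-conservative — one reason
published pair counts from real arrays are not desk-scale reproducible.
Residual-sd defaults are likewise chosen for test power, not fidelity to
any particular deposited dataset.

## Numerical choices, tie-breaks, degenerate inputs

- Quantile-normalization ties: a tie group spanning ranks [lo, hi] gets
  `mean(ref[lo:hi])` — deterministic and order-independent.
- Enrichment result ordering: by P, then set name; equally-enriched sets
  (identical k, K, n, N) tie at identical P, and "top-ranked" in tests is
  therefore asserted as *attaining the minimum P*.
- Zero-variance probes: excluded from testing, logged (never P = 0).
- Constant vectors in correlations: `NA` with a logged reason, pair
  skipped; |r| = 1 reports the limiting P of 0.
- Edge scores: −log10 P capped at 300.
- BH with `NA` inputs: `NA` propagates and does not count toward m.
- Probes mapping to the same gene are **not** collapsed: records stay at
  probe level with gene symbols carried alongside, because no principled
  collapse rule is derivable from probe annotation alone. Gene identity is
  by case-sensitive symbol string, no alias resolution.

## Open design points, resolved

- **Screen order**: whether the genome-wide pair screen runs before or
  after restriction to differential probes is supported both ways
  (`restrict_to_differential`); the default restricts first, which is the
  order that makes the 618-of-9,666-style "also differential" subset the
  primary object.
- **Config format**: pipeline configs are YAML (one block per stage, all
  thresholds surfaced with the conventional defaults); the run manifest,
  ground-truth manifest and gene-set descriptions travel as JSON/GMT.
- **CLI**: `inst/cli/lncregnet` exposes
  `simulate|preprocess|de|coexpr|enrich|network|power|run`; each
  subcommand executes the pipeline up to its stage, so partial runs leave
  a manifest listing exactly the stages executed. Exit codes: 0 success,
  2 usage/config, 3 stage failure.

## Known limitations

- The hypergeometric universe choice materially changes ORA P-values;
  results are only comparable across runs sharing a universe.
- The correlation screen's P-values assume exchangeable arrays; with
  strong patient effects they are anti-conservative (see above).
- No moderated-variance (empirical Bayes) test is offered; at n = 5 a
  moderated test would be more powerful, but the plain paired t is the
  method being modelled.
- Acceptance-grade simulation checks in the test suite run at reduced
  replicate counts relative to the multi-hundred-rep versions described
  for each operation, to stay inside a desk-scale time budget; thresholds
  are unchanged.
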