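---
title: "protpair: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protpair: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpair)
```

## Scope and data model

`protpair` analyzes paired two-condition label-free proteomes: each of `n`
subjects contributes one sample per condition, and every protein carries a
non-negative intensity per sample, with 0 (or a blank cell) meaning "not
observed". Two containers carry the analysis: the `intensity_matrix`
(proteins × samples) and its binarization, the `appearance_matrix`, where a
bit is 1 iff the intensity is strictly positive. Treating NA, blank and 0
identically as "not observed" follows label-free MaxQuant-style output,
where undetected proteins are reported as zero intensity; any positive
value, however small, counts as an observation.

Semicolon-joined accession groups (e.g. `"Q6GTX8; Q6ISS4"`) are kept
verbatim as a single protein id: splitting them would silently change the
protein universe and the multiplicity of every downstream test.

## Condition-unique proteins and the proportion test

With per-condition presence counts `(k_A, k_B)` over `n` subjects, a
protein is *unique for A* when `k_A >= ceiling(f * n)` and `k_B == 0`
(default `f = 0.4`, i.e. at least 4 of 10 subjects). The ceiling form is
deliberate — a 0.4 threshold on 10 subjects must mean 4 subjects, and a
small numeric guard keeps `ceiling(0.4 * 10)` from landing on 5 through
floating-point representation.

Significance uses the pooled two-sample proportion z statistic with a
two-sided normal p-value and **no continuity correction**. This exact form
was fixed by verifying that it reproduces, to three significant figures,
the canonical printed values for presence in 9, 6, 5 and 4 of 10 subjects
versus 0 of 10 (5.23e-5, 3.41e-3, 9.82e-3, 2.53e-2); it is therefore
documented as reverse-engineered from those values rather than from a
formula citation. Two degeneracy rules keep ranking total: when the pooled
frequency is 0 or 1 (both groups all-absent or all-present) the test
returns `z = 0, p = 1`, and equal non-degenerate frequencies give `z = 0`
exactly.

The test treats the two condition groups as independent proportions even
though the design is paired. That is how the source analysis was run, and
`protpair` reproduces it rather than "fixing" it (a McNemar-style paired
alternative would condition on discordant pairs and is out of scope).

```{r unique}
fx <- build_tables_fixture()
u <- detect_unique_proteins(fx$appearance, fx$design, min_fraction = 0.4)
table(u$condition)
```

## Paired differential expression

Three tests run per protein, on paired per-subject values with missing
intensities entering as 0 (no imputation is modeled; a `log2(x + 1)`
transform is available as an explicit divergence knob, with raw intensities
the default):

* **Paired t**: `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p with
  `n - 1` degrees of freedom. Zero-variance differences are *undefined*
  rather than an error.
* **Wilcoxon signed rank**: zero differences dropped; exact two-sided p
  from the sign-pattern null (generating function of rank sums) when there
  are at most 12 untied nonzero differences, otherwise a normal
  approximation with tie correction and no continuity correction. Fewer
  than 3 nonzero differences gives the undefined marker, so a full
  proteome sweep never aborts.
* **Proportion test** on the appearance counts, as above. Inside the sweep,
  a protein observed in *neither* condition is marked undefined rather than
  `p = 1`: it carries no appearance evidence, and the undefined policy
  (below) puts it last.

P-values are Benjamini–Hochberg adjusted **within each test family**; the
source description does not state whether correction was joint, and
per-family is the conservative reading that keeps the three tests
interpretable separately.

Undefined p-values are excluded from BH's `m` and receive the maximum rank
`n_proteins`; defined p-values are ranked ascending with ties broken
lexicographically by protein id, so output is bit-reproducible. `min_rank`
is the smallest of the three ranks, and the min-rank list (ties by
ascending proportion p, then id) is the single ranked list handed to
enrichment.

### A note on BH idempotence

The step-up adjustment `q(i) = min_{j >= i} p(j) m / j` is *not* idempotent
in general: `p = (0.3, 0.9)` gives `q = (0.6, 0.9)` and `BH(q) = (0.9,
0.9)`. Exact idempotence holds only when the adjusted vector is constant
from each index up to its maximum (as in flat-tailed cases like
`(0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03)`). The suite asserts idempotence
on such cases and the true general relation `BH(BH(p)) >= BH(p)`.

## Overabundance and plug-in FDR

For threshold `alpha`, `observed = #{p <= alpha}` (inclusive comparison —
this reproduces both printed headline FDRs from their printed counts),
`expected = alpha * m` with `m` the number of *defined* p-values, and
`fdr = min(1, expected / observed)`. The identity
`ratio * fdr = 1` holds wherever the cap at 1 is idle; under the cap the
product drops below 1 by construction. The default grid is 50 log-spaced
thresholds in `[1e-4, 1]`.

Discreteness matters at this sample size: the exact signed-rank null with
10 pairs cannot produce a two-sided p below `2/2^10 ≈ 0.00195`, and the
largest attainable level at or below 0.05 is 0.0488 (0.0391 at 9 pairs).
Null calibration is therefore judged against the attainable discrete
levels, and the grid-mean calibration bound is evaluated on thresholds at
or above `2/2^10` — below it the null is structurally empty.

## PCA of appearance patterns

Samples are observations and proteins are features. Columns are centered
but not scaled: the variance of a Bernoulli feature is exactly the
information the embedding should use, and scaling would blow up
nearly-constant proteins. The SVD-based scores are sign-fixed so each
component's largest-magnitude loading is positive, making coordinates
reproducible across BLAS libraries. Explained-variance fractions are
relative to total variance across all components.

## mHG enrichment

For a set mapped onto the ranked list (absent members ignored; sets with
fewer than 3 in-list members skipped), the mHG score is the minimum
hypergeometric upper tail over prefixes `n = 1 .. N-1`; the full list is
excluded because its tail is identically 1. The exact p-value — the
probability that a uniformly random arrangement of the `K` member
positions attains an mHG score at least as small — is computed by a
dynamic program that walks the list rank by rank, carrying the probability
mass of arrangement paths over the `(n, b)` lattice and absorbing the mass
that first enters the rejection region `{tail(n, b) <= score}`. Summing
absorbed mass avoids the catastrophic cancellation of the survival form
`1 - P(never hit)` at small p. A relative tolerance of `1e-12` on the score
keeps the achieving cell inside its own region despite floating-point
noise. The p-value is clamped to `[score, 1]`; the union bound
`p <= N * score` is a test invariant, not an enforcement.

Terms are BH-adjusted across reported sets. This replaces the web-service
correction of ranked-list GO tools with a standard, reproducible one —
a documented divergence; q-values from such services additionally depend
on the ontology release and are not comparison targets. Gene sets arrive
as plain GMT; no ontology-graph propagation is performed — sets are taken
as given.

## The synthetic generator: a stated world

`generate_paired_proteome()` emulates the data *shape* the analysis
assumes: 10 subjects × 2 conditions, 2773 proteins, zero-inflated
intensities, planted condition-unique proteins at presence fractions
(9, 5, 4, 4, 4)/10 in condition A and (6×3, 5×8, 4×7)/10 in condition B,
and 50 proteins with an 8-fold condition-A intensity shift. Detected
intensities are `2^N(20, 2)` — log-normal on the log2 scale, typical of
reported label-free intensities.

Fixed choices, made once and a priori:

* `detection_prob = 0.8`. Background proteins are detected independently
  per sample with this probability. At 0.8 a background protein is absent
  from *all* 10 samples of one condition with probability `0.2^10 ≈ 1e-7`,
  so exclusivity false positives are essentially impossible and
  planted-unique recovery reflects the planted structure rather than luck;
  per-sample inventories sit near 80% of the panel, a realistic
  completeness for label-free data. Heavy zero-inflation remains: every
  protein is missing from ~20% of samples, and the planted uniques are
  missing from entire conditions.
* `shift_effect = 8` (3 log2 units): a strong but realistic tissue effect,
  large enough that shifted proteins concentrate at the top of the
  Wilcoxon ranking without being deterministic.
* The planted enriched annotation set takes the condition-unique proteins
  first (their proportion-test ranks are extreme by construction) and then
  shifted proteins, up to 15 members, plus 10 random 15-member decoy sets
  disjoint from the planted set.

What the generator does **not** emulate: intensity-dependent (MNAR)
dropout — missingness is independent Bernoulli, a stated simplification,
with real MS data censoring low-abundance proteins preferentially;
per-protein abundance structure (all proteins share one intensity
distribution); subject-level covariates; batch effects; and peptide-level
identification noise. A green test on synthetic data therefore establishes
that the *pipeline machinery* is correct under the stated statistical
model, not that the model captures every property of real label-free data.

`build_tables_fixture()` is the deterministic companion: 23 proteins at
the exact tabled presence counts (112 one-bits in total), presence
assigned to lowest-index subjects — immaterial for every count-based
statistic, and stated so the fixture is byte-stable.

## Pipeline

`run_pipeline()` chains the stages (binarize → per-sample counts → unique
detection → differential expression → overabundance + PCA → min-rank →
enrichment), writes each stage's TSV with `%.17g` floats (write-read round
trips are exact), plots as PDF, a JSON summary, and a `run.log` recording
seed, versions and flags. All randomness flows from the single root seed;
two runs with the same config and seed produce byte-identical tables.
Fixture mode is appearance-only: without intensities the t/Wilcoxon stages
are skipped and the summary reports the appearance results.

The CLI accepts a JSON key-value config for the generator (`simulate
--config`); JSON was chosen because the R stack ships `jsonlite` while no
YAML parser is a hard dependency of this package's environment.

## Known limitations

* The proportion test ignores the pairing (reproduced behavior, see
  above); its p-values at `n = 10` are normal approximations and should
  not be over-read at the third decimal.
* Missing-as-zero feeds the paired t-test raw intensity gaps; with heavy
  missingness the t family is noisy and the Wilcoxon/proportion families
  carry most of the signal. The presence-floor exclusion is available via
  the Wilcoxon `min_nonzero` policy only.
* The mHG DP is `O(N·K)` per set — ample for proteome-scale lists with
  ordinary set sizes, but quadratic-feeling for sets of thousands of
  members.
* No covariate adjustment, moderated variance, imputation models, or
  permutation FDR; these are out of scope by design.
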