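---
title: "Methods: genotype-by-diet variance partitioning and modular endophenotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-by-diet variance partitioning and modular endophenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxdmod)
```

# Scope

`gxdmod` analyzes factorial line × diet × replicate omics panels:
per-feature variance partitioning into genetic, dietary, and
genotype-by-diet components; correlation-module detection among
significant features; module summarization and trait mapping; minimal
predictor selection; and second-order conservation statistics for
trait-correlate profiles across traits, diets, and platforms.  This
vignette records the statistical model, the tunable parameters, the
numerical conventions, and the design decisions that were genuinely
open, together with what the synthetic generator does and does not
emulate.

# The analysis model

Every feature (transcript or metabolite abundance, assumed already
normalized to an approximately Gaussian scale) is fit with the
fixed-effects two-way model

$$Y_{ijm} = \mu + G_i + D_j + (G{\times}D)_{ij} + \varepsilon_{ijm}$$

for replicate $m$ of line $i$ on diet $j$.  Choices and consequences:

- **Fixed effects, no block term.**  The model carries no
  replicate-block main effect, matching the analysis model it
  implements; the generator nonetheless offers an optional block
  variance (`block_var`, default 0) so users can study the
  consequences of block confounding.  No mixed-model/REML machinery is
  used: lines and diets are treated as fixed.
- **Type III sums of squares** are computed by full-versus-reduced QR
  fits under sum-to-zero contrasts, so mildly unbalanced designs
  (e.g. a panel missing a handful of samples) are handled; on balanced
  data the decomposition equals the classical Type I one, which the
  test suite verifies against a textbook means-based oracle.
- **Per-feature missingness**: a feature whose missing values empty an
  entire line × diet cell cannot support the interaction term; it is
  excluded with a warning rather than silently imputed.  Design-level
  empty cells are a hard error (surfaced in advance by
  `validate_dataset`).
- **FDR per effect**: Benjamini–Hochberg q-values are computed
  separately within each effect across features (not pooled across
  effects), because significance lists are reported per effect.
  Default threshold `fdr_q = 0.05`.
- **Numerics**: p-values are floored at `1e-300` before the
  `NLP = -log10(p)` transform; features constant at their grand mean
  are reported with all sums of squares 0, F = 0, p = 1.

# Units of correlation: least-squares means

All correlation stages default to line × diet least-squares means
(`ls_means`), i.e. $n = L \times J$ units (80 for a 20-line,
four-diet panel), with per-diet analyses using the $L$ units of one
diet.  On balanced data these are arithmetic cell means; on unbalanced
data the saturated two-way model's cell predictions coincide with the
observed cell means wherever a cell is nonempty, which is what is
used.  A `line_diet_replicate` grouping is available by configuration
for workflows that correlate at replicate resolution; the package
default follows the coarser grouping because the downstream
sample-size bookkeeping (n = 80 pooled, n = L per diet) is then exact
and interpretable.  Correlation p-values come from the two-sided t
distribution with $n - 2$ df; raw thresholds (`corr_p_primary = 0.01`,
`corr_p_secondary = 0.05`) are used for correlate filtering without
multiplicity correction, and this choice is deliberate and logged —
correlate lists are screening devices here, not inferential claims.

# Module detection

`mmc` clusters a filtered feature set on the absolute pairwise
correlation matrix of LS-means.  The concrete algorithm is our
instantiation of modularity-based correlation clustering:

1. For each sharpness $s$ in a grid (default $1, 2, \ldots, 30$), map
   correlations to edge weights $w_{ij} = |r_{ij}|^s$ (a logistic
   transform $1/(1 + e^{-(|r|-\tau)/(\sigma/s)})$ is available as an
   alternative strategy).
2. Maximize weighted modularity
   $Q = \sum_c \left[ w^{in}_c/2W - (k_c/2W)^2 \right]$ by recursive
   leading-eigenvector bisection of the (generalized) modularity
   matrix, each bisection refined by greedy single-feature moves until
   no move increases $Q$; splitting stops when the best split's
   $\Delta Q \le 0$.
3. Keep the sharpness maximizing $Q$, ties resolved toward the
   smallest $s$; reindex modules by descending average within-module
   $|r|$ (the "average degree of correlation"), so module 1 is always
   the most coherent.

Absolute correlation is used so that strongly anti-correlated features
join the same module.  Sign conventions are fixed (the
largest-magnitude eigenvector component is made positive) so repeated
runs agree exactly.  Every feature is assigned to some module;
`order_and_filter_modules` then hides modules failing the size
(`module_min_size`, default 3) or coherence (`module_min_avg_corr`,
default 0.5) thresholds rather than leaving features unassigned.
Exact numerical replication of any particular external clustering
software is a non-goal; the contract is the modularity objective
itself, which the tests check against a brute-force evaluation of the
definition.

# Module summaries and trait mapping

`module_pc1` standardizes member profiles across units before the
eigen-decomposition — correlation-PCA rather than covariance-PCA — so
that high-variance members cannot dominate the module score; this is
the scale-free choice consistent with defining modules through
correlations.  Loadings are unit-norm with nonnegative sum (the
biological sign of an eigengene is arbitrary; the convention makes
reaction-norm plots reproducible).  `correlate_module_traits` reports
$r$, $p$, NLP, and, importantly, the exact $n$ for pooled versus
per-diet scopes, since the two differ by a factor of the diet count.

# Stepwise predictor selection

`forward_stepwise_bic` starts from the intercept-only model and adds,
at each step, the candidate minimizing
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ (with $k$ counting
slopes plus intercept), stopping when no addition lowers BIC.  Ties
break lexicographically by feature id; candidates numerically
collinear with the selected set are skipped with a warning; a
numerically perfect fit terminates the search.  Per the pipeline
contract, candidates should first be screened to the features
significantly correlated with the trait (`corr_p_primary`).  A known
property of forward-BIC with tens of candidates at $n \approx 80$
deserves note: the entry hurdle for one extra predictor is a partial
chi-square exceeding $\ln n \approx 4.4$, an event of probability
about 4% per null candidate, so with ~50 candidates the procedure
admits occasional spurious predictors even under screening.  The
package reports the full BIC trace so users can audit each entry.

# Conservation statistics

`co_correlation` is the Pearson correlation between two vectors of
feature–trait correlation coefficients over their common features —
the second-order statistic used to ask whether "what correlates with
the trait" is preserved across traits, diets, or platforms.  Its
analytic p-value treats features as independent (t with $n-2$ df,
$n$ = common feature count); because co-expression violates this, the
result carries an explicit `independence_caveat` flag and the p should
be read as descriptive.  Feature matching is by exact id only.
`chance_overlap_test` provides the complementary set-level null:
same-size significant sets redrawn uniformly from the universe, the
observed counts at each sharing multiplicity compared to the
permutation distribution, with one-sided
$p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)$ for excess sharing.
`cross_platform` builds per-(platform, diet) profiles on shared
features — optionally restricted to shared genetic lines — and
returns the full co-correlation matrix.

# The synthetic generator

`generate_dataset` draws, per feature,
$Y = \mu_f + g_{fi} + d_{fj} + \gamma_{fij} + \lambda_f M_{k(f),ij}
+ \varepsilon$, with all effects independent Gaussians (variances set
per feature class) and module factors $M_k$ sharing the same
line/diet/interaction decomposition.  Traits are driven **only**
through module factors plus noise, so "which features correlate with
the trait" has unambiguous ground truth: the members of loaded
modules.  Diet effects are random deviates per diet — only the
variance structure matters for recovery tests — with a fixed-effect
override available for reproducing stark, ordered diet responses.
All draws occur in a fixed order under R's Mersenne-Twister generator
seeded per stage (`substream_seed`), so identical spec + seed gives
bit-identical output.

Preset scenarios and their calibration:

- `main_panel`: 20 lines × 4 diets × 3 replicates (240 samples),
  default 500 features (configurable up to 11,650 — the default is a
  working scale chosen so the full test suite runs in seconds while
  preserving every structural property; nothing in the pipeline
  depends on the feature count).  Four variance classes (genetic,
  dietary, interaction, null at twice the error variance) and four
  25-feature modules with loadings set for a within-module signal
  share of 0.7 on LS-means, i.e. mean within-module $|r| \approx 0.7$.
- `followup_panel`: 45 lines × 2 diets × 2 replicates
  (180 samples), 45 features, qPCR platform label.
- `conserved` / `cryptic` / `null`: 45 lines × 2 diets (familiar,
  novel) × 2 replicates, 500 features, 8 modules of 50 with signal
  share 0.8, each trait loading on four modules with signed unit
  weights.  In `conserved` the loading vectors are identical across
  diets; in `cryptic` the novel diet's vectors are orthogonal to the
  familiar diet's; in `null` all loadings vanish.  Two calibration
  choices matter here.  First, the trait is spread over several
  mid-sized modules: concentrating it in one or two large modules
  raises per-feature correlations but leaves the cross-diet
  co-correlation at the mercy of a handful of module-level sampling
  deviations, inflating its seed-to-seed variance.  Second, the module
  factors carry their variance entirely in the genotype-by-diet
  component: a line-shared factor component correlates the per-diet
  profile estimation errors between diets, which again widens the
  cryptic co-correlation distribution.  With these choices the
  conserved scenario's cross-diet co-correlation sits near 0.85 and
  the cryptic one near 0 with a spread small enough that a 0.4
  threshold separates them reliably.

What the generator does **not** emulate: raw microarray intensities or
probe effects, chromatogram peak shapes, platform dynamic-range
differences beyond a noise-share parameter, non-Gaussian abundance
distributions, correlated error across features outside the planted
modules, and missingness mechanisms.  Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under
the stated model, not robustness to the full messiness of real
profiling data.

# Power experiments

`power_experiment` simulates the chosen spec across a replicate-count
grid and reports the fraction of interaction-positive features
detected.  Detection defaults to the BH q-value at level `alpha`
(matching how discovery lists are made); `adjust = "none"` switches to
the raw p-value, which under a null spec estimates the per-test
false-positive rate — the appropriate reading when no interaction
variance is planted, and the one used for calibration checks.
Replicate counts below 2 are rejected: with one observation per cell
the interaction is saturated and inestimable.

# Problem sizes and runtime

The shipped tests use 40–2,000 features, 10–200 lines, and 5–100
simulation repeats per property — sizes chosen so each statistical
check retains its discriminating power (binomial standard errors are
asserted explicitly) while the whole suite completes in well under a
minute of compute per module.  The acceptance script scales the same
computations to a few seconds total.

# Known limitations

- The ANOVA is fixed-effects only; panels where lines should be
  treated as random draws from a population need external mixed-model
  tooling.
- Analytic co-correlation p-values ignore feature–feature dependence
  (flagged, see above); a unit-resampling bootstrap is the principled
  alternative and is deliberately left to the user, being orders of
  magnitude more expensive.
- Correlate screening at raw P thresholds does not control the FDR of
  correlate lists; it mirrors the screening character of the analysis
  the package implements.
- `ls_means` drops empty cells rather than imputing them; designs
  with systematic missingness should be examined with
  `validate_dataset` before interpretation.
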