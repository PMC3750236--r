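---
title: "Inferring transcription-factor regulatory activity from binding potentials and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription-factor regulatory activity from binding potentials and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfactivity)
library(dplyr)
```

## The problem

Differential expression tells you *which genes* moved between two conditions;
it does not directly tell you *which regulators* moved them. A transcription
factor (TF) can change activity — through phosphorylation, ligand binding,
cofactor availability — without changing its own transcript level, so ranking
TFs by their own expression misses much of the biology. This package scores a
TF's *regulatory* activity change by asking whether the genes the TF binds
(from ChIP-seq evidence) are concentrated among the genes that moved in the
expression comparison.

## From coverage to regulatory potentials

Binding evidence enters as a genes × profiles matrix of *regulatory
potentials* in $[0, 1]$ ("profile" = one TF assayed in one cell line or
condition). It can be supplied directly or built from a coverage track in
three steps:

1. **TSS-profile scoring.** `tss_binding_profile()` averages strand-oriented
   coverage windows (default half-width $W = 10{,}000$ bp, configurable)
   around every annotated TSS into one characteristic profile of where the
   factor binds relative to transcription start. Each gene's window is
   scaled to sum to one before averaging so a few deeply covered promoters
   cannot dominate the shape; all-zero windows contribute zero rows and the
   final profile is normalized to sum to one. `binding_affinity()` then
   scores each gene as the profile-weighted coverage in its own window,
   $a_i = \sum_o w(o)\,c(\mathrm{tss}_i \pm o)$, treating positions beyond
   the track or chromosome as zero coverage.
2. **Column standardization.** `affinity_zscores()` converts each profile's
   affinities to z-scores $(a - \bar a)/\mathrm{sd}(a)$ with the sample
   standard deviation. A constant column is mapped to all-zero z-scores with
   a warning rather than an error: such a profile carries no information,
   and degenerate synthetic tracks should not kill a pipeline.
3. **Potential transform.** `potentials_from_zscores()` maps each z to an
   upper-tail standard-normal p-value, takes $-\log_{10} p$ truncated at
   `cap = 10`, and min–max scales over the *whole* matrix to $[0, 1]$. The
   upper tail is a deliberate choice: only unusually strong binding should
   earn a high potential. The cap stops a handful of extreme promoters from
   dominating the running sums downstream; 10 corresponds to
   $p = 10^{-10}$, far beyond where the normal approximation is meaningful
   anyway.

Peak-based target sets (`promoter_targets()`) use a strand-oriented promoter
window, 1000 bp towards the gene's 5′ end to 500 bp towards its 3′ end of
the TSS. Orientation is a design choice — "upstream" is a strand-relative
notion — and all genomic intervals follow the 0-based half-open BED
convention with the TSS as a 0-based point.

## The activity score

Given a case–control expression matrix, `t_score_profile()` computes a
per-gene unequal-variance t statistic
$t = (\mu_1 - \mu_2)/\sqrt{\delta_1^2/n_1 + \delta_2^2/n_2}$ (sample sd,
$n-1$ denominator). Genes are then sorted by decreasing $t$ — ties broken by
gene id so runs are reproducible — and two cumulative shares are walked down
the ranked list:

$$
f(i) = \frac{\sum_{k \le i} t_{(k)}^2\, s'_k}{\sum_{k \le g} t_{(k)}^2\, s'_k},
\qquad
b(i) = \frac{\sum_{k \le i} t_{(k)}^2\, (1 - s'_k)}{\sum_{k \le g} t_{(k)}^2\, (1 - s'_k)},
$$

the *foreground* (potential-weighted) and *background* (complement-weighted)
running sums. Both are non-decreasing and end at exactly 1. Their maximal
gap is the pre-score: $ps^+ = \max(f - b, 0)$ at the earliest arg-max,
$ps^- = \min(f - b, 0)$ at the earliest arg-min, and
$ps = ps^+$ if $ps^+ > |ps^-|$, otherwise $ps = ps^-$. A positive $ps$ means
high-potential genes crowd the top of the ranking (activity up in cases).
The rank fraction of the winning extremum is reported as `location`.

```{r micro}
ranked <- rank_genes(
  tibble::tibble(gene = c("gA", "gB", "gC"), t = c(2, 1, -1)),
  tibble::tibble(gene = c("gA", "gB", "gC"), s = c(1, 0, 0.5)))
running_sums(ranked)
pre_score(running_sums(ranked))
```

### Permutation normalization

Raw pre-scores are not comparable across profiles (they depend on how many
genes carry appreciable potential), so `ras()` normalizes against a
*balanced* label-permutation null: each of `m` shuffles (default 1000)
builds a pseudo-case group from half of the original cases plus half of the
original controls, recomputes every t-score, re-ranks, and recomputes
$ps^\pm$. Balancing keeps the shuffled groups a mix of both conditions,
preserving the dataset's correlation structure under the null better than a
free shuffle. The regulatory activity score is
$RAS = ps / \overline{ps^{perm+}}$ for $ps \ge 0$ and
$ps / |\overline{ps^{perm-}}|$ otherwise.

All profiles share one seeded permutation plan — the same label shuffles at
the same permutation index. That is what makes per-profile-normalized null
scores poolable for the FDR, and it makes the whole run reproducible from a
single seed. Odd group sizes use the floor for both draws.

### Significance

The empirical p-value follows the sign of the pre-score: for $ps \ge 0$ it
is the fraction of permuted $ps^{perm+}$ at least as large (mirrored for
negative scores). Zero is attainable and reported as such; a conservative
add-one variant $(k+1)/(m+1)$ is reported alongside. The pooled FDR
normalizes each profile's permuted pre-scores by that profile's own null
means — the same denominators used for the observed score — pools them
across profiles, and compares tail fractions of pooled null scores versus
observed scores at each threshold, capped at 1.

**A calibration caveat.** The sign-conditional p-value inherits a selection
effect: the observed score is the *larger* of two extrema, but each null
value is not selected the same way. Under a global null this roughly doubles
the nominal type-I error. The `p_value_twosided` column compares $|ps|$
against each permutation's larger extremum and is calibrated; the
`scripts/acceptance.R` report computes the realized type-I error of both
variants on null data so the difference can be inspected on any run. For
ranking TFs and for the pooled FDR the distinction matters little; for
hypothesis testing on a single profile, prefer the two-sided column.

## Per-sample activity

`iras()` replaces the t-profile with one sample's *relative* expression
profile (signed log10 ratios). Absolute intensities are first
quantile-normalized (ties get the mean of the quantile values they span)
and divided by each gene's median across samples, then log10-transformed —
with an odd sample count every gene's relative profile has median exactly
zero. The null here permutes genes: the potential vector is shuffled against
the fixed expression ranking (equivalent to shuffling gene assignments, and
cheaper). One seeded permutation set is shared by every sample and profile,
so duplicated samples score identically and scores stay comparable across
the matrix. Cells whose null mean is zero are reported as missing, never as
zero. A positive score means the profile's high-potential genes sit among
the sample's most highly expressed genes.

`compare_activity_groups()` contrasts activity between two sample groups
with a one-sided Wilcoxon rank-sum test (exact for small untied samples;
with identical groups the continuity-corrected one-sided p sits just above
0.5).

## Survival screening

`screen_survival()` fits one Cox proportional-hazards model per profile,
$\log h(t) = \log h_0(t) + \beta' x' + \sum_i \beta_i x_i$, with the
profile's per-sample activity $x'$ plus selected clinical confounders, and
reports both the single-variable and covariate-adjusted coefficients,
hazard ratios, Wald 95% CIs and p-values, with Benjamini–Hochberg
adjustment across profiles. Confounder selection
(`select_confounders()`) fits one full model with all clinical covariates
and keeps those with Wald $p < 0.01$; it is a separate, composable step so
confounders can equally be pinned by hand. Ties use the Efron
approximation; censoring is right-censoring only; the screening threshold
defaults to $p < 0.001$ on the covariate-adjusted model.

## What the simulators emulate — and what they do not

`sim_config()` fixes the study conditions for all generators:

* **Potentials** — Beta-distributed (default shape $0.5, 4$): heavy mass
  near zero with a thin upper tail, mimicking the sparsity of genome-wide
  binding; min–max rescaled so the global extrema are exactly 0 and 1.
* **Expression** — Gaussian per-gene baselines on the log10 scale with
  within-group noise sd 0.3 (a typical log-intensity spread for microarray
  data), 2000 genes and 20 + 20 samples by default. An active profile
  shifts its top-decile-potential genes by `effect` × noise-sd in case
  samples; the default effect of one within-group sd is a moderate,
  realistic regulatory signal. `value_type = "absolute"` exponentiates to
  intensities; `"relative"` emits centred log values directly.
* **Coverage** — Gaussian-shaped pileups (lognormal amplitudes) at target
  TSSs on a flat background, with matching peak intervals.
* **Survival** — exponential event times with hazard
  $h_0 e^{\beta \cdot \text{activity}}$ and independent exponential
  censoring.

Every generator is deterministic under the config seed (stage streams are
derived from it), so emitted fixture files are byte-identical across runs.
The simulations deliberately omit several features of real data:
gene–gene correlation blocks, batch effects, heavy-tailed intensity noise,
probe-level artifacts, and potentials correlated across TFs. Passing the
injection-recovery and calibration checks therefore demonstrates that the
statistics behave as designed under their own assumptions — not that the
method is robust to everything microarray or ChIP-seq data can do.

## Numerical choices

* Ranking ties break by gene id; arg-max/arg-min ties take the earliest
  index; an exact $ps^+ = |ps^-|$ tie resolves to $ps^-$.
* A potential column that is constant in $(0,1)$ makes $f \equiv b$
  analytically; the engine short-circuits it to $ps = 0$ exactly instead of
  leaving $10^{-17}$-scale rounding residue. Columns constant at 0 or 1
  (vanishing foreground or background weight) are reported as failed
  profiles, not errors for the whole run; `ras()` continues and records the
  reason in the `note` column.
* Genes whose two group variances are both zero get $t = 0$ on equal means
  and the largest finite $|t|$ plus one (signed) otherwise, keeping the
  ranking well defined without infinities.
* The paired t statistic uses $\bar d / (\mathrm{sd}(d)/\sqrt{n})$ — the
  scale-consistent standard form.
* Pipeline-identity checks (vectorized engine versus a naive loop
  reference) hold to $10^{-12}$; sign-flip antisymmetry under profile
  negation is also verified at $10^{-12}$, since reversing a ranking changes
  floating-point summation order.

## Problem sizes used by the checks

The test suite exercises oracle equivalence at $g \le 50$, $m \le 20$ over
25 random instances; calibration at 2000 genes, 20 + 20 samples, $m = 200$,
200 replicate datasets; injection-recovery over 50 replicate studies at the
default config; survival recovery over 100 replicates at $n = 300$; and
promoter-target equivalence on $10^3 \times 10^3$ peak–gene instances.
`scripts/acceptance.R` reruns the main computations at the same defaults
and writes the resulting quantities as JSON.

## Known limitations

* The sign-conditional empirical p-value is anticonservative under a global
  null (see the calibration caveat above); the two-sided column is the
  calibrated alternative.
* Balanced permutation needs at least two samples per group; smaller groups
  require the opt-in free shuffle.
* Missing expression values are not modelled; rows containing any are
  dropped on load with a message.
* The group-level screen assumes an unpaired design for its permutation
  null; paired t-profiles can be scored and ranked
  (`paired_t_score_profile()` feeds `rank_genes()`), but a paired-aware
  permutation scheme is not provided.
* Potentials derived from a single coverage track inherit whatever biases
  the ChIP experiment has (antibody efficiency, mappability); the
  column-wise standardization removes level differences between profiles
  but not within-profile artifacts.
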