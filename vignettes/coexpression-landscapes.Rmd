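---
title: "Methods: cross-dataset co-expression landscapes and module statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset co-expression landscapes and module statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexland)
```

This vignette is the package's account of the methods it implements: the
correlation model, each tunable parameter and its default, what the
synthetic-data generator emulates (and what it deliberately does not), the
numerical conventions, and the limitations we know about.

## 1. The leave-one-out correlation model

The input is a cohort of $D$ expression datasets (studies) over a shared
gene list, normalized upstream and typically mean-centered per gene. For a
gene pair $(g, h)$ the pipeline computes $D$ Pearson correlations
$r_{gh}^{(-d)}$, $d = 1, \dots, D$, each over the pooled samples of the
$D - 1$ datasets remaining after excluding dataset $d$, and stores

$$ w_{gh} \;=\; \min_{d} \; r_{gh}^{(-d)}, $$

discarding the pair (stored as `NA`, never as 0) when $w_{gh} \le 0$.

The minimum is the whole point. A correlation that exists only inside one
study — a batch effect, a platform quirk, a confounded subcohort —
collapses in the leave-one-out round that excludes that study, and the
minimum collapses with it. Conversely a biological correlation present in
every study survives every round. The statistic is deliberately
conservative: it trades efficiency (the minimum of $D$ estimates is biased
downward by roughly one standard error for moderate $D$) for robustness,
which is the right trade when edges feed a hard threshold.

Two caveats follow directly from the construction and are worth stating:

- Correlations are computed on **pooled** samples of the retained datasets,
  not averaged per-dataset correlations. Additive per-dataset mean shifts
  therefore survive pooling when the *same shift pattern* recurs across
  several datasets; leave-one-out only defends against structure confined
  to a single dataset. The defense for shared mean structure is per-dataset
  centering (`mean_center(..., center_mode = "per_gene_within_dataset")`),
  which removes additive batch shifts exactly; the test suite demonstrates
  both the failure mode and the fix.
- A gene constant within any leave-one-out pool has undefined correlations
  there; its pairs are dropped with a warning rather than imputed.

**Significance floor.** `permutation_threshold()` permutes every gene's
values independently across the pooled samples — the only reading of a
"permuted-labels" null that destroys *all* gene–gene correlation while
preserving each gene's marginal distribution — and records the maximum
pairwise correlation per repetition. The reported threshold is the maximum
over repetitions, matching the convention of quoting the largest random
correlation ever observed; the per-repetition maxima are kept so users can
take a quantile instead (for many repetitions, the across-repetition
maximum keeps growing slowly at the Gumbel rate, and a 95th percentile of
per-repetition maxima is the more stable choice).

## 2. Preprocessing conventions

- **Probe collapsing**: probes flagged cross-hybridizing or mapping to more
  than one gene id are removed; surviving probes of a gene are averaged
  (arithmetic mean per sample). Order-independent by construction.
- **Centering** (`center_mode`): `per_gene_global` (default) subtracts each
  gene's mean over the pooled cohort; `per_gene_within_dataset` centers per
  study. Pearson correlations within any fixed sample set are
  location-invariant, so the mode affects only pooled-SD filtering,
  exported values, and — as noted above — the vulnerability of pooled
  correlations to shared additive batch structure. Both modes are
  supported; neither is claimed to be canonical.
- **Variance filter**: keeps genes whose pooled-sample standard deviation
  (with the $n-1$ denominator) is *strictly* greater than `sd_cutoff`
  (default 1, the conventional "most varying genes" cut on log-scale
  microarray data). The boundary is exclusive by the wording "above".

## 3. Networks, modules, landscape

`build_network()` connects pairs with $w_{gh} > r$ (strict inequality; a
tie at the cutoff is excluded) and prunes to minimum degree $k$
(`min_neighbors`, default 5). Pruning is **iterative** by default: nodes of
degree $< k$ are removed repeatedly until the $k$-core remains. The
alternative `single_pass` mode removes under-connected nodes once, using
degrees of the unpruned graph; it can leave nodes whose degree falls below
$k$ only because of the removal, so it violates the stated min-degree
property and exists for comparison only. Isolated nodes are dropped in both
modes.

**Modules** are the connected components of the pruned network with at
least `min_size` genes (default 6, the smallest possible 5-core), ordered
by decreasing size with ties broken by smallest gene id — fully
deterministic. Components are used because at stringent cutoffs the pruned
graph fragments into its tightly co-expressed neighborhoods; a
community-detection algorithm can be applied to the exported graph if finer
splitting of a connected region is wanted, but nothing in the package
depends on one.

**Landscape coordinates.** Over an ascending cutoff grid (default 0.3–0.7
in steps of 0.1) each gene receives $z$ = the highest cutoff whose pruned
network still contains it, with sentinel 0 for genes in none. Removing
edges can only shrink the $k$-core, so membership is monotone in the cutoff
and the maximum is well defined (property-tested). $x, y$ come from a
weighted Fruchterman–Reingold layout of the base-cutoff network, seeded for
reproducibility, centered at the origin and scaled to a unit bounding box.
Surface rendering (kriging/thin-plate splines) is left to plotting tools;
the package exports the coordinates.

## 4. Module statistics

- **Co-expression** (`module_coexpression()`): mean pairwise Pearson
  correlation over the module's genes in a target dataset, compared with
  `n_random` (default 1,000) uniformly drawn same-size gene sets.
- **NACC** (`nacc()`): the fraction of a gene set's pairs whose stored
  weight exceeds a cutoff, over $m(m-1)/2$ possible pairs. For a *pair* of
  modules, `combine_mode = "union"` treats them as one set (the classic
  clustering-coefficient reading), while `"cross_only"` counts only
  between-set pairs over $|A|\,|B|$ — a sharper interconnection measure
  unaffected by within-module density. Both are available because the
  between-module usage is not uniquely defined by the clustering-coefficient
  formula; analyses in the test suite use `cross_only` when the question is
  specifically about coupling.
- **Subgroup interconnectivity** (`subgroup_nacc_test()`): observed NACC on
  the correlation matrix of the tested subgroup's samples; null from
  `n_resample` same-size subsamples of the reference group, recomputing
  correlations each time; one-sided add-one p-values plus the null mean ±
  SD per cutoff. See §7 for the calibration regime.
- **Quartile profiles** (`quartile_nacc()`): samples split into four
  equal-size groups (±1 sample) by a stratifier gene's expression, rank
  order with ties broken by input order; NACC profile per quartile plus an
  all-sample reference.
- **Activity scores** (`activity_scores()`): within each sample all $G$
  genes are ranked ascending (average ranks on ties) and the module score
  is the mean rank of its genes divided by $G$, a value in $(0, 1]$. The
  definition is fixed by two invariances that are tested exactly:
  per-sample monotone transforms of expression leave scores unchanged, and
  module gene order is irrelevant. `expression_sum` mode (plain per-sample
  sums) is provided for conserved-core scoring, where the core is small and
  rank compression would discard most of the signal.
- **Conserved cores** (`module_conservation()`): module-internal pairs
  above the cutoff in **both** of two correlation matrices form the
  conserved-edge graph; the core is its largest connected component.
- **Dichotomization** (`dichotomize_scores()`): strictly-above-the-mean
  labels per module, exported for survival tooling; group comparisons
  (t-tests, ANOVA, log-rank) are left to standard packages.

All resampling p-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + R)$, so $p$ is never 0 and
the test is valid at finite $R$.

## 5. Screen tests

`module_knockdown_test()` compares a module's mean log Ki-67 intensity to
`n_samples` (default 10,000) random gene groups of the same size drawn
**without replacement** from the screened library (with-replacement
sampling would model a different statistic — independent gene draws — and
slightly overdisperse the null for modules that are a non-trivial fraction
of the library; groups of distinct genes match how the observed module is
formed). Controls are excluded from the null universe by default: they are
not library genes. Replicate intensities per gene are collapsed by median
before testing. The one-sided direction is reduced intensity (inhibited
proliferation); a two-sided flag doubles the smaller tail.
`control_group_test()` runs the same machinery on the flagged non-specific
controls.

## 6. The synthetic cohort generator

`generate_cohort()` samples from a Gaussian factor model chosen because
every moment the pipeline estimates has a closed form:

$$ x_{gs} \;=\; \sqrt{\rho_m}\, f_{ms} \;+\; \sqrt{1 - \rho_m}\,
\varepsilon_{gs} \;+\; b_{g,d(s)}, \qquad g \in \text{module } m, $$

with standard-normal factors $f$, noise $\varepsilon$, and optional batch
shifts $b \sim N(0, \sigma_b^2)$ per (dataset, gene). Within-module
pairwise correlation is exactly $\rho_m$; coupled modules with factor
correlation $\tau$ give cross-module gene correlation
$\tau\sqrt{\rho_i \rho_j}$ (both verified empirically within 4 standard
errors in the test suite). Background genes are independent noise. The
factor value $f_{ms}$ doubles as the per-sample activity amplitude of
module $m$, recorded in the truth object for score-recovery tests — no
separate amplitude mechanism is needed. Covariate-dependent coupling uses
$\tau_{\text{alt}}$ for samples carrying the alternative covariate label
(e.g. TP53-mutant), drawn with probability `alt_fraction`; the factor
correlation matrix of each stratum is checked for positive definiteness
before any sampling. An optional *artifact module* shares a factor only
inside one designated dataset — the planted input for leave-one-out
batch-defense tests.

**Default scenario** (chosen once, used by the end-to-end suites): 4
datasets × 150 samples, 500 genes, 8 modules of sizes 30, 28, 24, 20, 16,
14, 12, 10 with $\rho$ from 0.65 to 0.85 paired *inversely* with size.
The pairing is deliberate: a member of a 10-gene module has only 9
potential neighbors and must keep 5 of them above the landscape cutoffs, so
small modules are detectable at $r > 0.6$ only when very tightly
correlated, while a 30-gene module tolerates $\rho = 0.65$ comfortably.
The inverse pairing gives every planted module a comparable recovery
margin. Batch shifts default to 0 (they are scenario options, switched on
by the tests that study them). These sizes keep the full pipeline run in
seconds while preserving the multi-study, multi-module structure of a
compiled microarray cohort.

What the generator does **not** emulate: platform-specific probe effects
and intensity distributions (MAS5-like skew, floor effects), heavy-tailed
or discrete expression marginals, correlated noise beyond the factor
structure, missing values, and survival times. Passing tests therefore
demonstrate the pipeline's statistical behavior under a clean factor
model — recovery, calibration and invariances — not robustness to every
pathology of real array data. The rank-based score's invariance to
per-sample monotone transforms is the one property that transfers to
arbitrary marginals by construction.

`generate_screen()` plants additive intensity shifts for disjoint gene
sets on a normal noise background, with flagged controls offset by a
configurable amount.

## 7. Calibration regimes and known limitations

- **Subsampling nulls are conditionally correlated.** The null draws of
  `subgroup_nacc_test()` are subsamples of one finite reference group and
  therefore overlap; correlated null draws make the empirical p-value
  anticonservative when the tested subgroup is a sizeable fraction of the
  reference. Measured on exchangeable synthetic data: type-I error ≈ 0.12
  at a 40-vs-120 split, ≈ 0.05 at 30-vs-300. The test is calibrated in the
  dominated-reference regime (subgroup ≲ 10% of reference) and should be
  read as conservative evidence, not an exact p, when the groups are
  comparable in size. The acceptance suite measures calibration at
  30-vs-300 for this reason. A label-permutation variant would be exactly
  calibrated under exchangeability but answers a subtly different question
  (no fixed subgroup size in the null); it is noted, not implemented.
- **Minimum-statistic bias.** $w_{gh}$ underestimates the common
  correlation by roughly the expected minimum of $D$ correlated estimates
  (≈ 1 standard error below $\rho$ for $D = 4$ at these sample sizes).
  Thresholds therefore act slightly conservatively; planted-recovery tests
  account for this by requiring a margin between $\rho$ and the cutoff.
- **Permutation-threshold statistic.** The across-repetition maximum grows
  with the number of repetitions (extreme-value behavior); a single
  repetition's maximum at the default full-cohort dimensions sits a little
  below the many-repetition maximum. Users comparing thresholds across
  settings should fix `n_perm` or use a quantile of `per_perm_max`.
- **Components as modules.** Two genuinely distinct programs connected by
  even one above-cutoff, pruning-surviving bridge merge into one component;
  the cutoff grid (inspecting modules at the cutoff where the graph
  fragments) is the practical control.
- **Problem sizes in the test suite** were chosen so the statistical
  claims are sharp at desk scale: 500-gene cohorts for recovery, 500
  simulations for type-I rates (binomial SE ≈ 0.01 at $\alpha = 0.05$),
  resampling depths of 200–1,000 for power checks, and the full
  3,824 × 1,608 dimensions only for the permutation-threshold magnitude,
  where scale is the quantity of interest.

## 8. A compact end-to-end run

```{r pipeline, eval = FALSE}
sim  <- generate_cohort(synthetic_cohort_config(seed = 7))
corr <- loo_min_correlation(sim$cohort)
net  <- build_network(corr, network_config(cutoff = 0.6))
mods <- extract_modules(net)
coords <- landscape_coordinates(corr, seed = 1)
sc   <- activity_scores(mods, sim$cohort)
lab  <- dichotomize_scores(sc, "M1")
```

Every quantity above is exercised, with assertions, in
`tests/testthat/`; the vignette intentionally states no result that the
test suite does not itself compute.
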