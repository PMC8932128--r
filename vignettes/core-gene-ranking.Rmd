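---
title: "Ranking core transcriptional regulators from periodic transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking core transcriptional regulators from periodic transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(corerank)
library(dplyr)
```

## The problem

Periodic biological programs — the cell cycle, circadian clocks — are driven
by a small, strongly connected set of *core* transcription factors whose
autoregulatory interactions generate the rhythm. Downstream *output* genes
receive the periodic transcriptional signal and propagate it, but do not feed
it back; their observed rhythms are degraded copies of the core signal.
Identifying the core set experimentally is expensive: knock-out candidates
number in the thousands per genome.

`corerank` implements a pragmatic shortcut: score every gene's time-series
abundance profile for two dynamic features — **periodicity** at the single
specified period of the process, and **regulation strength** (variability of
abundance about its mean, a proxy for oscillation amplitude) — and rank genes
so that experimentalists encounter core candidates early. The package scores
profiles, attaches resampling-based and rank-based p-values, combines them
into ranking metrics, and evaluates rankings against curated label sets with
tie-aware precision–recall machinery. A synthetic-data generator provides
labelled benchmarks so every stage is testable without access to the original
experimental datasets.

## Scores and p-values

Let $G = (x_1, \dots, x_n)$ be a profile sampled at times $t_1 < \dots < t_n$
with specified period $T$, and $\tilde x$ the mean-centered profile.

**Regulation strength.** `reg_score()` is the population standard deviation
$\mathrm{Reg}(G) = \sqrt{\tfrac1n \sum_i \tilde x_i^2}$ (a `sd_type = "sample"`
switch selects the $1/(n-1)$ form). It is zero exactly for constant profiles,
invariant to additive shifts, and scales linearly with amplitude.

**Periodicity.** `per_score()` is the single-frequency Fourier magnitude at
$T$, evaluated at the *actual* sample times:
$$\mathrm{Per}(G) = \sqrt{\Big(\sum_i \tilde x_i \cos \tfrac{2\pi t_i}{T}\Big)^2
 + \Big(\sum_i \tilde x_i \sin \tfrac{2\pi t_i}{T}\Big)^2}.$$
Using true sample times matters: benchmark designs include non-integer
timepoints-per-cycle ratios (a 94-minute period sampled every 16 minutes gives
5.875 samples per cycle), and nothing in the package forces profiles onto an
integer phase grid. For a pure cosine of amplitude $A$ sampled evenly over
whole cycles, $\mathrm{Per} = \tfrac n2 A$, independent of phase.

**Empirical p-values.** Both scores are referred to a null ensemble of
synthetic profiles resampled from the observed matrix
(`sample_null_profiles()`). The default `pooled` mode draws each entry
uniformly with replacement from the pooled multiset of all observed values;
`per_timepoint` (column-respecting) and `within_gene_permutation` modes are
available because the choice materially affects the regulation null — pooled
nulls mix between-gene and within-gene variability, while within-gene
permutation preserves each profile's value set. One shared ensemble is scored
by both statistics, so the periodicity and regulation nulls come from the same
synthetic universe. The p-value is the add-one tail estimator
$p = \big(1 + \#\{\text{null} \ge \text{observed}\}\big) / (1 + n_{\mathrm{null}})$,
which is never zero, so products of p-values remain positive. With
$n_{\mathrm{null}}$ resamples only $n_{\mathrm{null}} + 1$ distinct p-values
exist; repeated values create tie blocks in rankings, and enlarging the
ensemble disambiguates them at linear cost. The default
$n_{\mathrm{null}} = 10{,}000$ keeps the discretization step at $10^{-4}$;
the seed is mandatory.

**JTK rhythmicity p-value.** `jtk_pvalue()` is a from-scratch, tie-aware
implementation of the JTK-CYCLE idea: correlate the profile's up–down rank
pattern with phase-shifted cosine templates via Kendall's S, and ask how
extreme the observed concordance is under random permutation of the profile.

* Templates (`build_templates()`) are cosines at the specified period
  evaluated at the true sample times for offsets $0, \delta, 2\delta, \dots < T$
  (default $\delta$ = the sampling interval, so the number of phase groups
  tracks timepoints-per-cycle), rounded to 9 decimals to stabilize numerical
  ties, converted to mid-ranks, and deduplicated.
* For an untied profile against a tied template, pairs within a template tie
  group contribute nothing and each cross-group pair contributes $\pm 1$, so
  $S = 2\,\mathrm{JT} - M$ where $\mathrm{JT}$ is a Jonckheere–Terpstra-type
  concordance count and $M$ the number of cross-group pairs. The permutation
  null of $\mathrm{JT}$ factors into a product of Gaussian binomial generating
  functions — a sum of independent Mann–Whitney components — which the package
  convolves exactly (in double precision; relative error $\sim 10^{-16}$) for
  profiles up to `n_exact = 25` timepoints. Null distributions are cached per
  tie structure, so scoring a whole matrix costs one convolution per template.
* Profiles that themselves contain ties have no polynomial-time exact
  convolution (the two-sided tie problem); up to 8 timepoints the package
  enumerates all $n!$ permutations exactly, beyond that it uses the normal
  approximation with the standard two-sided tie correction and a continuity
  correction. Fully tied profiles carry no evidence and get $p = 1$.
* Beyond `n_exact`, untied profiles use an Edgeworth-corrected normal
  approximation: the null of $S$ is symmetric (zero skew), so the leading
  error term is kurtosis, and because $\mathrm{JT}$ is a sum of independent
  Mann–Whitney components its fourth cumulant is the sum of exactly computed
  per-component cumulants. At $n = 20$ the approximation agrees with the
  exact tail to within about $5 \times 10^{-4}$ (the suite asserts 0.005
  over 1000 random profiles).
* The reported p-value is the minimum over deduplicated templates times the
  number of templates (Bonferroni), capped at 1. Because the phase grid spans
  the full period, anti-phase templates cover negative correlation, making the
  per-template one-sided test directionally complete. Asymmetric (sawtooth)
  template scanning and period grids are deliberately out of scope: the
  pipeline scores exactly one user-specified period with sinusoidal templates.

## Combined metrics and rankings

Eight metrics rank genes (`ranking_metrics()`): the four individual scores and
p-values, plus

* `dl = p_per * p_reg` (ascending — smaller is stronger),
* `dl_jtk = p_jtk * p_reg` (ascending),
* `per_reg = per_score * reg_score` (descending), which needs no resampling
  at all and scales as amplitude squared.

Ranking is invariant to any strictly monotone transform of a metric, so the
choice of product over, say, log-sum changes nothing downstream.
`rank_genes()` performs a stable sort and exports maximal equal-score runs as
*tie blocks*; the within-block order is reproducible but arbitrary, and all
evaluation treats blocks as exchangeable.

## Tie-aware evaluation

`average_precision()` uses non-interpolated AP — the mean of precision at each
positive's rank — with three tie policies. For a block of $b$ items containing
$c$ positives that starts after $s$ items and $R$ positives, the `expected`
policy uses the closed form
$$\sum_{i=1}^{b} \frac{c}{b} \cdot
  \frac{R + 1 + (c-1)\frac{i-1}{b-1}}{s + i},$$
the exact expectation of the block's AP contribution over uniformly random
within-block orderings (the test suite checks it against explicit
5000-shuffle Monte-Carlo averages to 0.005). `pessimistic` materializes every
negative before every positive within each block, `optimistic` the reverse;
the three always satisfy pessimistic $\le$ expected $\le$ optimistic, so the
reported bounds bracket whatever tie-breaking produced any published list.
`recall_at_k()` shares a straddling block hypergeometrically under the
expected policy.

**On the $C/N$ random baseline.** For a ranking of $N$ candidates containing
$C$ positives, the expected *precision at any fixed depth* of a random ranking
is exactly $C/N$, and the expected PR curve is the horizontal line at $C/N$ —
the package reports this as `baseline`. The expected value of the *AP
statistic itself* under random ranking is slightly larger than $C/N$
(by Jensen's inequality the early harmonic terms dominate: about $0.071$
versus $0.055$ at $C = 17$, $N = 307$), with a null SD of about $0.025$. When
the package compares an observed AP to the baseline, the comparison scale is
therefore the Monte-Carlo null SD of AP, not the standard error of a mean.

## The synthetic benchmark generator

No generative model accompanies the published conceptual picture, so
`sim_config()` pins the minimal model consistent with it — precisely the two
features the metrics quantify, period match and amplitude:

* **core** genes: $x(t) = A \cos\!\big(2\pi (t - \phi)/T\big) + \varepsilon$,
  amplitude $A \sim \mathrm{logN}(\log 4,\, 0.25)$ (median 4 against unit
  background noise — strongly but not trivially detectable), phase uniform on
  $[0, T)$, period exactly $T$;
* **output** genes at regulatory distance $d \sim U\{1, \dots, 3\}$: amplitude
  $A\gamma^d$ (default $\gamma = 0.6$), period $T(1 + \delta)$ with
  $\delta \sim N(0, 0.05)$, and an $e^{-\lambda t}$ envelope
  ($\lambda = 0.001$ per minute). No regulatory graph is simulated — distance
  is a label, network inference is out of scope;
* **background** genes: white noise with SD 1; measurement noise
  (SD 0.25) is added to every profile;
* **TF labels**: the core set plus `n_tf_extra` genes drawn at random, so
  TF-vs-all classification by dynamics alone is a negative control expected
  to sit at the random baseline;
* the default design is 16 samples every 16 minutes with a 94-minute period
  (5.875 timepoints/cycle), so the non-integer phase path is exercised by
  default; defaults `n_genes = 2000`, `n_core = 17`, `n_tf_extra = 290`
  mirror the yeast benchmark's proportions (17 core among 307 TFs);
* RNA-seq mode exponentiates to an FPKM-like scale
  ($2^{\mathrm{signal} + 5}$, keeping ordinary genes above the 1-FPKM floor)
  and can plant sub-threshold profiles and duplicate probe rows to exercise
  the preprocessing filters; the two plants are drawn from disjoint rows so
  filter and collapse counts stay independently checkable;
* an optional diurnal-forcing variant adds a common-phase periodic component
  to a fraction of background genes, emulating light/temperature-driven
  output rhythms.

What the generator does *not* emulate: realistic count noise
(negative-binomial dispersion), autocorrelated baselines and trends,
tissue-mixture convolution of phase-shifted signals, batch structure, or any
actual regulatory topology. Passing tests on this benchmark demonstrate that
the statistical machinery is correct and calibrated — not that the metrics
will achieve any particular AP on real datasets, where those nuisances all
operate.

```{r example}
cfg <- sim_config(n_genes = 1000, n_core = 17, n_output = 150,
                  n_tf_extra = 140, gamma = 0.4, seed = 1)
sim <- simulate_dataset(cfg)
scores <- score_profiles(sim$expression, n_null = 5000, seed = 2)
evaluate_rankings(scores, core = sim$core$positives, tfs = sim$tfs$positives,
                  tasks = "core_in_tfs") |>
  select(metric, average_precision, ap_pessimistic, ap_optimistic,
         baseline, recall_at_k)
```

```{r plots, fig.width = 6, fig.height = 4}
ranked <- rank_genes(scores, "dl_jtk")
labels <- label_set(scores$gene_id, sim$core$positives)
autoplot(average_precision(ranked, labels))
```

## Preprocessing rules

`preprocess_expression()` applies, in order:

1. **Leading-timepoint removal** (`drop_leading_timepoints()`), for series
   whose first samples reflect recovery from synchronization rather than the
   periodic program; the design and duration are recomputed.
2. **Low-expression filter** (`filter_low_expression()`, RNA-seq only): a
   profile is removed when its abundance is below 1 FPKM in *strictly more
   than half* of the timepoints — a 12-timepoint profile below the floor at
   exactly 6 timepoints is kept. The filter applies to raw FPKM, before any
   log transform, and is idempotent.
3. **Multi-probe collapse** (`collapse_duplicate_profiles()`): for genes with
   several probes, the profile with the highest average abundance is kept;
   exact mean ties keep the first in file order (deterministic).
4. **Log transform** (RNA-seq): `log2(FPKM + 1)` by default, because
   variance-based scores on the raw scale are dominated by the most abundant
   genes; `transform = "none"` disables it. Microarray log-ratios are used as
   provided.

Missing values are rejected at ingestion with an error naming the offending
row and column — the pipeline never imputes. Gene IDs are matched
case-insensitively against label lists, and unmatched labels are warned about
and reported, never silently dropped.

## Numerical and design choices

* **Tie rounding in templates**: cosine values are rounded to 9 decimals
  before ranking so that analytically tied values (e.g. the cosine at quarter
  period) rank as ties despite floating-point noise.
* **Exact-mode boundaries**: `n_exact = 25` bounds the convolution null;
  the $n \le 8$ enumeration bound keeps the tied-profile exact path under
  $40{,}320$ permutations. Both are arguments, not constants.
* **Continuity correction**: the $S$ lattice has spacing 2 for untied
  profiles, so tail probabilities shift the boundary by 1.
* **Degenerate inputs**: constant profiles score 0 on both statistics and get
  $p_{\mathrm{jtk}} = 1$; empty positive sets raise an undefined-AP error
  rather than returning `NaN`; `n_core = 0` simulations propagate that error.
* **Determinism**: every stochastic step (simulation, null resampling) takes
  a mandatory seed; `run_pipeline()` writes its full configuration next to
  its outputs, and reruns are byte-identical.
* **Problem sizes in the test suite**: calibration checks use 2000 null genes
  with 10,000 resamples; recovery checks use 5000 genes, 15 core, 20 seeds,
  and a three-point amplitude-ratio grid; the JTK oracle comparisons
  enumerate up to $7! = 5040$ permutations. These sizes give Monte-Carlo
  error comfortably below the asserted tolerances while keeping the suite
  fast.

## Limitations

* The DL-style scores assume a single known period; period estimation is a
  separate upstream problem and period grids are out of scope.
* Empirical p-values inherit the null ensemble's assumptions; the pooled
  default destroys within-gene structure, which is conservative for
  periodicity but can flatter regulation strength on matrices with strong
  between-gene scale differences. The within-gene permutation mode is the
  robustness check.
* The JTK exact null for profiles with ties is only available up to 8
  timepoints; beyond that the tie-corrected normal approximation is used.
  Heavily tied profiles (e.g. zero-inflated counts) at high time resolution
  are the worst case for it.
* AP comparisons against the $C/N$ baseline use Monte-Carlo null spread, as
  discussed above; the AP of a random ranking is not exactly $C/N$.
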