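---
title: "Reference-gene stability for stratified circadian qPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability for stratified circadian qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification reports a target gene's abundance divided by
a normalization factor built from reference ("housekeeping") genes that are
assumed stable. That assumption fails silently: a reference gene that is
stable within one mouse strain can shift systematically between strains or
across circadian time, and every such shift is transferred, inverted, onto
the target. `refstab` implements the two standard stability analyses —
geNorm and NormFinder — on top of efficiency-corrected quantification, for
experiments stratified by strain, tissue and circadian sacrifice time, and
ships a synthetic-data generator that emulates a three-strain, two-tissue,
seven-time-point study so the entire pipeline is testable with known ground
truth.

## From Cq to relative quantities

The measured signal is the quantification cycle Cq; technical replicates of
one (sample, gene) well are averaged arithmetically (the aggregation rule is
a package choice; replicate dispersion above `max_sd = 0.5` cycles is
flagged, never filtered, so downstream sample counts always match the
design). With amplification efficiency $E_g$ (fold product per cycle,
estimated from the standard-curve slope as $E = 10^{-1/\text{slope}}$), the
relative quantity of gene $g$ in sample $s$ is

$$Q_{gs} = E_g^{\;\min_{s'} Cq_{gs'} - Cq_{gs}},$$

so the most abundant sample of each gene sits at $Q = 1$ and all quantities
lie in $(0, 1]$. The per-gene minimum is taken within the analysis dataset
at hand (each of the eight strain/tissue groups is analysed on its own
cohort); both stability statistics are scale-invariant, so this convention
does not affect rankings — it only fixes the interpretation of $Q$.

## geNorm

For genes $j, k$ the pairwise variation is
$V_{jk} = \mathrm{sd}_s\!\left[\log_2 (Q_{js}/Q_{ks})\right]$, and the
stability value of gene $j$ is $M_j = \mathrm{mean}_{k \neq j} V_{jk}$.
Iteratively removing the highest-$M$ gene yields the exclusion ranking; the
final two genes cannot be ordered (their $M$ values are equal by
construction) and are reported as an unordered pair. Normalization factors
are geometric means of the selected genes' quantities, and
$V(n/n+1) = \mathrm{sd}_s \log_2\!\left[NF_n / NF_{n+1}\right]$ decides how
many genes to combine: the recommended $n$ is the smallest with $V$ below a
threshold, 0.15 by convention and configurable here (it is a guideline, not
a sharp rule).

Numerical conventions: sample standard deviation ($n-1$) throughout; all
logs base 2 — changing the base rescales $M$ and $V$ jointly, so the 0.15
threshold is base-dependent. An exact $M$ tie during exclusion is broken by
removing the lexicographically later gene, and the round is recorded;
ties are measure-zero on continuous data. Circadian time is not an input to
geNorm: the algorithm sees the pooled cohort.

## NormFinder

NormFinder models the log2 quantities per subgroup $g$ (by default the
seven sacrifice times) as

$$y_{igj} = \alpha_i + \beta_{gj} + d_{ig} + \varepsilon_{igj}, \qquad
\varepsilon_{igj} \sim N(0, \sigma^2_{ig}),$$

with gene levels $\alpha$, sample loadings $\beta$, gene-by-group
deviations $d$ (the systematic component that makes a reference gene
dangerous) and intragroup noise. Within each subgroup, two-way residuals
give raw variances $v_{ig}$, which are bias-corrected as
$\hat\sigma^2_{ig} = \frac{I}{I-2}\left(v_{ig} - \bar v_g/(I-1)\right)$
(floored at 0; the correction removes the contamination each gene's
residuals inherit from the gene and sample means, and a Monte-Carlo test in
the suite verifies unbiasedness to within 3% at $I = 8$, $G = 4$,
$n_g = 50$ over 2000 replicates). Group deviations $\hat d_{ig}$ are
centred gene-group means, weighted by group size, summing to zero within
each group. Their dispersion in excess of sampling noise,
$\hat\gamma^2 = \max\!\big(0,\ \sum \hat d^2 / ((I-1)(G-1)) -
\overline{\hat\sigma^2_{ig}/n_g}\big)$, acts as an empirical-Bayes prior
variance: deviations are shrunk,
$\tilde d = \hat d\,\hat\gamma^2/(\hat\gamma^2 + \hat\sigma^2/n)$, and the
stability value is the posterior magnitude-plus-uncertainty

$$\rho_i = \frac{1}{G} \sum_g \left[\,|\tilde d_{ig}| +
\sqrt{\frac{\hat\gamma^2}{\hat\gamma^2 + \hat\sigma^2_{ig}/n_g}
\cdot \frac{\hat\sigma^2_{ig}}{n_g}}\,\right].$$

Lower is more stable. With a single subgroup the value reduces to the
intragroup standard deviation, and ranking coincides with ranking by the
two-way residual sd.

**Degenerate case.** When the data show no resolvable intergroup variation,
$\hat\gamma^2$ floors to exactly 0 and every multigroup $\rho$ collapses to
0 — the estimator's continuous limit, not an error. One practically
relevant route to this collapse is a single catastrophically unstable gene
whose enormous $\hat\sigma^2$ inflates the subtracted sampling-noise term.
The fit flags this (`degenerate_gamma`), warns, resolves the 0/0 shrinkage
limit to 0, and the stability table breaks exact ties by a documented
secondary key, the mean intragroup standard error
$\mathrm{mean}_g \sqrt{\hat\sigma^2_{ig}/n_g}$ — so even in the collapsed
regime the ranking degrades to a pure intragroup ordering rather than to
alphabetical noise. The same tie-break applies in the best-pair search.

**Best pair.** Every unordered pair is scored by replacing the two genes
with the pseudo-gene $(y_a + y_b)/2$ (the log of their geometric mean,
matching how normalization factors combine genes), refitting, and taking
the pseudo-gene's $\rho$; the search is exhaustive. Because the refit
leaves $I - 1$ genes and the intragroup correction divides by $I' - 2$, at
least 4 genes are required. Averaging halves independent intragroup
variance, so the combined value usually — not always — beats the best
single gene; the result records which occurred.

## Normalization comparison and rhythm summaries

`compare_strategies()` normalizes a target gene under several
reference-gene choices and reports, per strategy, the cosinor peak time,
the peak/trough amplitude fold, and the between-strain fold (geometric mean
over time points of the ratio of per-time mean expression). The 24 h
cosinor is fitted by least squares on log2 values, so amplitude is
symmetric in the fold sense; it is a profile summary, not a rhythm
detection test, and profiles with fitted amplitude below $10^{-8}$ log2 are
reported as non-rhythmic with an undefined peak. The quantitative bias law
these tools expose: a reference gene carrying a strain-specific log2 offset
$\delta$ multiplies the apparent between-strain fold of any target
normalized to it by $2^{\delta}$ (verified by simulation in the test
suite at $\delta = 1.5$, recovering $2^{1.5} \approx 2.83$ within 10%
over 200 seeds).

## What the generator emulates — and what it does not

`default_sim_config()` reproduces the reference design: 3 strains
$\times$ 2 tissues $\times$ 7 circadian times (CT0–CT24 every 4 h, CT0 and
CT24 distinct samplings of the same phase) with the study's exact ragged
replicate counts (131 liver + 97 adrenal = 228 samples), 10 candidate
reference genes plus a strongly rhythmic Dbp-like target (2 log2 amplitude,
acrophase CT12), triplicate technical replicates, and the validated primer
efficiencies (1.64–1.98).

Noise is placed where physics puts it: biological variation and sample
loading act on log2 abundance; technical noise (default sd 0.15 cycles)
acts on Cq. Abundance couples to Cq through each gene's own efficiency, so
quantification with the true efficiencies inverts the simulation exactly.
Calibration targets the printed summary levels: the rRNA analogue at mean
Cq 8.8, the lowest-abundance candidate at 28.5, the rest between 18 and 29;
`Actb` and `Hmbs` combine large biological sd (1.0 log2) with
background-level strain offsets (+4 and −2.5 log2 on the mixed background,
shared by the wild-type and knock-out strains), spanning roughly 12 Cq
cycles and becoming unstable exactly when strains are pooled; the
`Eif2a`/`Tbcc`/`Utp6c` trio is tight (bio sd 0.20 log2, < 4-cycle range)
with no offsets. All candidates carry weak circadian modulation (0.08–0.5
log2, inversely related to their intended stability): perfectly flat
references would make the true $\gamma^2$ exactly zero and push NormFinder
into its degenerate regime, which real reference panels do not exhibit; the
trio's sd of 0.20 likewise represents the study condition that two
reference genes suffice ($V(2/3)$ comfortably below 0.15) rather than
sitting on the threshold.

Not emulated: plate and batch effects, inter-run calibration, RNA
degradation, per-tissue candidate panels (the full 11-gene panel is
simulated in both tissues; tissue-specific panels are applied at the
analysis layer by gene filtering), and shared animals across tissues
(samples are independent per tissue). Passing tests therefore demonstrate
algorithmic correctness and qualitative reproduction of the design's
behaviour, not quantitative agreement with any laboratory's stability
values — which also depend on unpublished raw measurements.

## Decisions on genuinely open points

* **Scope of the per-gene minimum Cq** for $Q$: per analysis dataset, since
  each dataset is analysed as its own cohort; both statistics are
  scale-invariant so this is a reporting convention only.
* **NormFinder grouping for the pooled datasets**: the default subgroup
  factor is sacrifice time everywhere, for consistency; `group_by =
  "strain"` is a supported alternative for the pooled liver/adrenal groups
  and is the configuration under which between-strain instability of offset
  genes is expressed most directly (the within-time-subgroup route turns
  strain offsets into enormous intragroup variances instead, which can
  trigger the degenerate $\gamma^2$ regime described above).
* **Stability values are in log2 units** and not comparable numerically to
  outputs of tools using other bases.
* **Dilution series**: the generator accepts any dilution factor and point
  count (default five-fold, five points, three replicates); efficiency
  estimation refuses non-negative or implausibly shallow slopes
  (|slope| < 0.5 cycles/decade) instead of returning a nonsense efficiency.
* **Technical-replicate outliers** are flagged (sd > 0.5 cycles), never
  auto-excluded.
* **Missing (sample, gene) cells** within a dataset are resolved by an
  explicit policy (`drop_gene` default, with a warning naming the genes;
  `drop_sample`; or `error`) because both stability algorithms require
  complete matrices.

## Problem sizes used by the test suite

The suite runs at desk scale by design: oracle-equivalence checks use 100
random instances of up to 6 genes × 12 samples (agreement to $10^{-10}$);
invariance properties use 200 random cases; estimator calibration uses
2000 Monte-Carlo replicates at $I = 8$, $G = 4$, $n_g = 50$; the
normalization-bias experiment uses 200 seeds of a compact two-strain
design; pipeline-level checks run the full 228-sample default design.

## Known limitations

* NormFinder's multigroup stability intentionally measures the intergroup
  deviation and its uncertainty; a gene with huge intragroup variance but
  no group structure is penalised only through the posterior-uncertainty
  term, and in the degenerate $\gamma^2 = 0$ regime only through the
  documented tie-break.
* The best-pair refit inherits the same fragility: under extreme
  heteroscedasticity a refit can itself go degenerate, and such pairs win
  only via the intragroup tie-break.
* The cosinor assumes a 24 h period; it will missummarise profiles with
  strong ultradian structure.
* geNorm's $M$ rewards co-regulation: two proportionally co-varying genes
  protect each other's ranking regardless of their joint instability. This
  is a property of the algorithm, reproduced faithfully.
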