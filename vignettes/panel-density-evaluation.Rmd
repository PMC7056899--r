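---
title: "Evaluating low-density SNP panels for genomic selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating low-density SNP panels for genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panelGBLUP` measures what happens to heritability estimation and genomic
prediction when the SNP panel used to build the genomic relationship matrix
is thinned. This vignette documents the statistical model, the simulator
that provides ground truth, the numerical choices, and the limits of what a
simulation-based evaluation can show.

## The animal model and its REML fit

All inference is based on the single-random-effect animal model

$$y = \mu + Xb + Za + e, \qquad
a \sim N(0, G\sigma_a^2), \qquad e \sim N(0, I\sigma_e^2),$$

with $G$ the frequency-weighted identity-by-state relationship matrix:
marker dosages are centered at twice the allele frequency and standardized
by $\sqrt{2p(1-p)}$, and $G$ is the average cross-product over markers.
This equals twice the Astle–Balding frequency-weighted kinship, so
$\mathrm{E}[G_{ii}] \approx 1$ for non-inbred individuals and full sibs sit
near 0.5 — relationship units a breeder can read directly. Allele
frequencies are always estimated in-sample, and re-estimated on the panel's
markers whenever $G$ is built on a panel, so a 100-SNP $G$ is exactly the
matrix a program genotyping only those 100 SNPs could compute. The uniform
cross-product diagonal was preferred over a $0.5(1+\hat f)$-style kinship
diagonal because it yields a self-consistent positive semidefinite matrix
with the same off-diagonal expectation; both conventions exist in the
literature and differ only in the diagonal's sampling noise.

Missing dosages are mean-imputed (centered value zero), which is fast and
keeps $G$ positive semidefinite; a pairwise-complete policy is available
behind `missing_policy = "pairwise"` for data with structured missingness.

Variance components are estimated by restricted maximum likelihood in the
eigenbasis of $G$: with $G = UDU'$, rotating $y$ and $X$ by $U'$
diagonalizes the covariance $\sigma_t^2\{h^2 D + (1-h^2)I\}$, the total
variance $\sigma_t^2$ profiles out in closed form, and the restricted
likelihood becomes a smooth one-dimensional function of
$h^2 = \sigma_a^2/(\sigma_a^2+\sigma_e^2)$. One $O(n^3)$ decomposition is
followed by $O(np)$ likelihood evaluations, and a bounded scalar optimizer
(`stats::optimize` on $[10^{-6}, 1-10^{-6}]$, tolerance $10^{-8}$) finds
the maximum. For this model class the approach gives the same optimum an
average-information algorithm would, without step-size or starting-value
tuning — which matters here because the cross-validation experiment runs
hundreds of independent REML fits unattended. The test suite pins the
eigenbasis likelihood to a naive dense implementation at $10^{-10}$ and the
optimizer to a $10^{-4}$ grid search.

Numerical edge cases are handled explicitly:

* eigenvalues below zero (finite precision, or the rank deficiency of a
  panel $G$ with fewer markers than individuals) are clipped at zero; the
  likelihood remains well defined for $h^2 < 1$;
* a $G$ proportional to the identity makes $\sigma_a^2$ and $\sigma_e^2$
  jointly unidentifiable and is rejected up front;
* estimates within $10^{-5}$ of an optimizer bound are flagged `boundary`;
  a profile that is flat to $10^{-10}$ across the interval clears the
  `converged` flag instead of raising an error, and downstream aggregation
  drops non-converged fits with a logged count;
* the standard error of $\hat h^2$ comes from the finite-difference
  curvature of the profile likelihood; it is reported, not tested, since
  delta-method SEs from other software can differ slightly.

Fixed effects use reference-level coding with an explicit intercept, so the
intercept estimates the overall mean and the remaining coefficients are
level contrasts. Individuals with a missing trait or factor level are
excluded from $y$ and $X$ but kept in $G$, where they still receive
breeding values. `solve_gblup()` computes those through the conditional
expectation $\hat a = \sigma_a^2 G_{\cdot o}V_{oo}^{-1}(y - X\hat b)$; the
equivalence with Henderson's mixed-model equations (using the explicitly
inverted $G$, ridge-escalated from $10^{-6}$ only when numerically
singular, with the ridge recorded) is asserted to $10^{-8}$ in the tests.

## The synthetic populations

Every stage of the pipeline is testable against ground truth because the
data come from a gene-dropping simulator:

* **Founders** are unrelated, with per-SNP allele frequencies drawn
  uniformly from a configurable interval (default $[0.05, 0.5]$) and
  haplotypes sampled binomially — i.e. linkage equilibrium. The linkage
  disequilibrium that low-density panels exploit arises *within families*
  from co-segregation during meiosis, which is the mechanism that dominates
  sib-testing designs.
* **Meiosis** follows the Haldane model: per chromosome, the crossover
  count is Poisson with mean equal to the genetic length of the marker span
  in Morgans, positions are uniform, and there is no interference. The map
  scaling defaults to 1 cM/Mb, a standard vertebrate ballpark, and is
  configurable. The oracle tests recover a mean of one crossover on a
  100 cM chromosome and the Haldane recombination fraction
  $(1-e^{-1})/2 \approx 0.316$ at 50 cM.
* **Families** are monogamous founder pairs, one full-sib family each, with
  equal family sizes by default (total split evenly, remainder spread) —
  the simplest structure consistent with published family counts. Offspring
  dosage is polarized to the minor allele at generation time; $G$ is
  invariant to this relabeling and PLINK round trips become exact.
* **Traits** are polygenic: a default of 500 causal markers (a "most
  polygenic traits" architecture; configurable for sensitivity checks) with
  standard-normal effects, scaled so the ratio of true-breeding-value
  variance to total variance equals the requested $h^2$ exactly in
  expectation. Fixed-effect factors are assigned at random with stated
  level shifts in phenotypic-SD units. A `log` transform stores the trait
  on the observed (exponentiated) scale — the analysis log-transforms it
  back, losslessly, mirroring how skewed growth traits are handled in
  practice. Right-censored days-to-death are produced by quantile-binning
  the continuous liability into integer days $1..d$, survivors landing in
  the final day; only means and dispersions of such traits are published
  for the real datasets, so a liability-binning mechanism is the neutral
  choice.

Four presets encode the emulation targets: 85 families / 1,481 individuals
/ 9,866 SNPs / $h^2 = 0.24$ with a 2-level tank effect (salmon analogue);
195 / 1,211 / 6,966 / 0.27 with a 4-level cross-group effect and log-scale
trait (carp); 73 / 741 / 7,598 / 0.20 with no fixed effect (sea bream); and
23 / 718 / 14,028 / 0.49 with a 2-level tank effect and day-8 censoring
(oyster). The real factorial mating design behind the carp data is not
described in enough detail to reproduce, so it is approximated by the
4-level fixed factor only. Chromosome counts and physical lengths are set
to species-plausible values (29 × 83 Mb, 50 × 34 Mb, 24 × 29 Mb,
10 × 56 Mb); fixed-effect sizes (0.5 SD for 2-level tanks, 0.2 SD steps for
the 4-level group) are moderate values typical of rearing-environment
effects. The whole simulation — genotypes, trait, ground truth — is a pure
function of the configuration including its seed.

## Quality control and panel design

QC mirrors PLINK 1.9's fixed internal order: individuals with more than 20%
missing genotypes are dropped first; then, on the remaining individuals,
SNPs failing missingness (>10%), the exact Hardy–Weinberg test
($p < 10^{-6}$), and minor allele frequency (<0.05) filters. Outcomes for
the three SNP filters are computed on the same post-step-1 individual set,
so only the *attribution* of a SNP failing several filters depends on the
order (first failure wins). The HWE test is the standard exact conditional
test on the heterozygote count — full enumeration, no mid-$p$ — applied to
all QC-surviving individuals: with strong family structure this test
rejects more often than in panmictic samples, which is visible in the
presets' QC reports and is left as-is since no founder annotation exists at
QC time.

Panels are drawn at a density grid (the published 100–9,000 ladder is
`default_density_grid()`; densities above the post-QC marker count are
dropped with a notice) under two strategies: genome-wide uniform sampling,
and within-chromosome sampling with largest-remainder allocation
proportional to chromosome length. "Length" for allocation is the span of
QC-passing marker positions, which needs no external assembly and is
well defined for linkage-group maps; largest-remainder ties break by
descending length then label order, deterministically. Since the two
strategies give statistically indistinguishable relationship estimates
(asserted as a property test), genome-wide sampling is the default and the
headline strategy. Each panel's seed derives from the master seed and the
(strategy, density, replicate) coordinates, so extending the grid never
perturbs existing panels.

## Cross-validation protocol

Accuracy is evaluated by replicated k-fold cross-validation over the
phenotyped individuals (unstratified random partitions, fold sizes within
one of each other). Per fold: $G$ is built on the panel's markers over
*all* individuals; variance components are re-estimated by REML on the
training subset (a flag allows reusing the full-data components for
speed, at the cost of protocol fidelity); GBLUP predicts the validation
individuals with their phenotypes masked — masking removes records, never
individuals, because sib information must keep flowing through $G$; and
accuracy is $r(\hat a, y)/\sqrt{h^2_{ref}}$ against the raw unmasked
phenotypes, with fixed effects handled inside the model rather than
pre-corrected. The denominator $h^2_{ref}$ is always the full-panel,
full-data estimate, for every density — low-density heritabilities are
themselves shrunken, and dividing by them would flatter sparse panels.
(`h2_ref` is an explicit argument to `run_cv()`, so per-density
denominators remain available for exploration, without any claim of
protocol fidelity.) Note the estimator can exceed 1 when
$r^2 > h^2_{ref}$.

Aggregation reports, per density: the mean accuracy over panels ×
replicates × folds; the SD and max–min range across *per-panel mean*
accuracies (the panel-to-panel spread that makes SNP choice matter at low
density); and the proportion of the full-panel mean accuracy. Loess
smoothing (local quadratic, tricube weights, span 0.75) is provided for
trend lines in figures only — no numeric summary depends on it.

`run_density_experiment()` chains all of the above for the four presets at
densities {100, 500, 1,000, 2,000} against the full panel, with three
random panels per density and two replicates of five-fold CV, plus a
five-panel heritability-shrinkage comparison at 200 SNPs. These problem
sizes keep a full four-dataset run to a few minutes on a single core while
leaving enough replication to average panel-sampling noise; the published
protocol's five panels and ten CV replicates are available by changing the
arguments. `scripts/acceptance.R` is a thin wrapper that runs exactly this
and writes the summary quantities as JSON.

## What the simulation does and does not show

The simulator reproduces the features that drive panel-density behaviour in
sib-testing programs: large full-sib families, within-family
co-segregation LD, polygenic architecture, moderate heritabilities,
environmental fixed effects, and skewed or censored trait codings. On these
populations the package reproduces the published qualitative pattern — a
plateau of prediction accuracy down to ~2,000 SNPs, a steep decline below
~1,000, heritability estimates that shrink roughly by half at 200 SNPs, and
panel-to-panel variability that grows as density falls.

Two things it deliberately does not model, and what that implies:

* **Population-level LD.** Founders are in linkage equilibrium, so markers
  carry no ancestral LD with causal variants and families are mutually
  unrelated. Real aquaculture base populations have small effective size;
  their markers tag QTL and between-family relatedness even after heavy
  thinning. Consequently the simulated accuracy loss at very low densities
  (≤500 SNPs) is *more pessimistic* than what the published datasets show:
  the simulated proportion-of-full-panel accuracy lands visibly below the
  published 0.89 / 0.70 at 500 / 100 SNPs while matching the 2,000- and
  1,000-SNP values. Estimates from this package at the lowest densities
  should be read as a lower bound for populations with substantial
  background LD.
* **Multi-generation structure.** No selection, mutation, overlapping
  generations, or cross-generation prediction; no dominance or epistasis.
  The evaluation speaks to within-generation sib-testing, which is where
  low-density panels are expected to work in the first place — predicting
  across generations or populations shortens shared haplotypes and is known
  to demand higher densities.

Passing tests on these simulations therefore demonstrate correctness of the
machinery (QC counts, exact HWE enumeration, REML optima, GBLUP algebra,
masking discipline, determinism) and qualitative fidelity of the density
trends, not that a particular real population will retain a specific
fraction of accuracy at a given density. For that, the pipeline accepts
real PLINK-format data directly.
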