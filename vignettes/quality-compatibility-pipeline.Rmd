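---
title: "Partitioning reproductive biases between male quality and male-female compatibility"
author: "matecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning reproductive biases between male quality and male-female compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matecomp)
```

## The scientific problem

In *Drosophila melanogaster*, females receive no material benefits from
males, so mate choice — before and after copulation — is expected to act on
genetic contributions. Two kinds of contribution compete for explanatory
power: *additive* male effects (intrinsic male quality or reproductive
value, shared across all females) and *nonadditive* male-female interaction
effects (genotypic compatibility, specific to a pair). This package
implements, as a tested pipeline on synthetic data with known ground truth,
the full analysis chain used to separate those contributions across
episodes of sexual selection:

1. a **diallel cross** (every male genotype by every female genotype) that
   measures mating latency *L*, egg-to-adult viability *V*, and total
   progeny *P* per replicate pair, plus **competitive assays** (pairwise
   mating trials and group-paternity vials);
2. **composite fitness indices**: the combination-level compatibility index
   $w_{ij} = (zL_{ij} + zV_{ij} + zP_{ij})/3$ and the male quality index
   $w_i = (zL_i + zV_i + zP_i + zMS_i + zPG_i)/5$, where $z$ denotes range
   standardization to $[0,1]$, $MS$ is the David's-score ranking from
   dyadic mating trials, and $PG$ the group-vial paternity share; female
   quality $w_j = (zV_j + zP_j)/2$;
3. **stratified bootstrap** confidence intervals for all indices;
4. a **contrast design** that pairs males differing primarily in quality
   (with matched compatibility) or primarily in compatibility (crossed
   between two females, same quality category);
5. the **mixed-model inference chain** for five outcomes — competitive
   mating success (MS), sperm-ejection latency, second-male sperm storage
   (S2), second-male paternity (P2), and the post-remating offspring-rate
   shift (Pr) — with random intercepts for male 1, male 2, female genotype,
   and male-pair, observation-level random effects (OLRE) for
   overdispersion, and backward likelihood-ratio simplification.

Because no raw data from the original experiments are deposited, every
stage is validated against the synthetic-data generator's known truth, not
against published coefficient values. The printed design counts (200
crosses, 3000 pairs, 90 dyads/900 trials, 24 trios/240 trials, 36
combinations/360 trials) and the full-sib inbreeding recurrence
($F_t = (1 + 2F_{t-1} + F_{t-2})/4$, reaching 96% by generation 15) are
reproduced exactly.

## The generative model

`effect_spec()` fixes the generator. Male genotypes carry additive effects
$a_i \sim N(0, \sigma_m^2)$, females $b_j \sim N(0, \sigma_f^2)$, and each
combination an interaction $c_{ij} \sim N(0, \sigma_{mf}^2)$ (defaults all
$0.3$ on the latent scale, giving male, female, and compatibility signals
of equal prior weight). These are drawn once per run from a dedicated
sub-stream of the single global seed, so the diallel, the competitive
assays, and the stage-two experiments all see the same genotypes. Traits
are linked to the shared signal by loadings:

* log mating latency $= \mu_L - \lambda_L (a_i + c_{ij}) + d^L_{ij} -
  \beta_{block} + \varepsilon$, lognormal because latencies are strictly
  positive and right-skewed (the assay literature reports no distribution);
* viability: adults $\sim$ Binomial(eggs, $p$), $\mathrm{logit}\,p = \mu_V
  + \lambda (a_i + b_j + c_{ij}) + d^V_{ij} + \beta_{block} + \kappa z_k +
  \varepsilon$, eggs $\sim$ Poisson(40);
* progeny $\sim$ NegBin with log mean of the same form (size 12), the
  overdispersion that the analysis models later absorb with OLREs.

The trait-specific combination effects $d_{ij}$ and the shared replicate
latent $z_k$ decouple the traits just enough to reproduce the observed
correlation structure: viability and progeny positively correlated (target
0.37 both at the combination-mean and the replicate level), latency nearly
uncorrelated with both at the replicate level while still tracking quality
at the genotype level (via $\lambda_L = 0.8$; the genotype-level Spearman
correlation between inverse latency and progeny comes out near 0.7).

The loadings $\lambda$ and $\kappa$ are not free parameters: they are
solved at construction from the two target correlations through
delta-method closed forms (exact lognormal moments, quadrature for the
logit-normal component; see `implied_vp_cor()` and
`implied_replicate_vp_cor()`). The combination-level loading additionally
receives a one-step secant calibration against a deterministic internal
simulation (48 datasets from a fixed internal sub-stream, independent of
the user's seed), because the empirical Pearson correlation over a finite
20 x 10 crossed design is shrunk a few points below the superpopulation
value by the shared additive effects and the sampling of realized effect
variances. Without that step the mean realized correlation sits near 0.33
instead of 0.37.

Blocks (3, as in the assay design) enter as a shared random shift (SD 0.1)
applied with fitness-consistent sign to every trait. The
`observation_noise = FALSE` switch suppresses all sampling noise and
returns rounded expected values — a diagnostic mode that makes degenerate
configurations exactly reproducible.

### Competitive assays

Pairwise mating trials follow a Bradley-Terry-style logistic link:
$P(A\ \text{mates first}) = \mathrm{logit}^{-1}(\beta_c (q_A - q_B))$ with
$q_i = a_i + u_i$, $u_i \sim N(0, 0.2^2)$ a competitiveness residual not
expressed in the noncompetitive traits, and $\beta_c = 2$ so that a 1-SD
quality gap shifts the win probability to about 0.74. Group-vial paternity
shares are beta-binomial (precision 8) around
$\mathrm{logit}^{-1}(q_i)$ — the standard competitors sit at the population
baseline $q = 0$.

### Stage-two outcomes

Given a roster of planned trials with their quality difference
$\Delta q$, compatibility difference $\Delta w$ (male 2 minus male 1), and
female quality, the generator draws remating interval, sperm counts
(negative binomial: ~1400 transferred, ~400 resident, ~450 stored),
ejection latency (lognormal, residual SD 0.45), and the three share
outcomes S2, P2, Pr. All generating coefficients act on covariates
standardized across the roster, so they are directly comparable to fitted
standardized slopes. Genotype-level random intercepts (SD 0.25 each for
female, both males, and the male pair) induce the clustering the analysis
models estimate.

Share overdispersion defaults to a **logit-normal observation-level
perturbation** — exactly the OLRE structure the binomial mixed models use —
rather than beta-binomial mixing. The two mechanisms produce similar
marginal overdispersion, but they differ on the conditional scale: under
Beta($\mu\theta$, $(1-\mu)\theta$) mixing the logit-scale slope an OLRE
model estimates is inflated by
$\theta\mu(1-\mu)\,(\psi'(\mu\theta) + \psi'((1-\mu)\theta))$, about
1.3-1.5 at realistic precisions, so generating and fitted coefficients
would live on different scales and parameter-recovery validation would be
meaningless. `overdispersion = "betabinomial"` restores the beta-binomial
mechanism when the marginal shape (e.g., the bimodal P2 distributions seen
in sperm-competition data) matters more than scale-consistent recovery.

Missingness rates (70% remating, 92% observed ejections, 96% recoverable
sperm counts, 88% offspring production) were set so the realized analysis
sets approximate the assay's sample sizes (roughly 167 MS trials, 227
ejection, 241 S2, 214/170 P2 inclusive/conservative).

### Generating coefficient defaults

The nonzero stage-two coefficients are the conditions under which the
recovery suite runs, chosen once by a design-phase power analysis: each
must give an expected Wald $z \gtrsim 3$ at the assay sample sizes so that
an 80%-power sign-recovery criterion is meaningful. Magnitudes follow
field-typical sperm-competition effects where those are strong (sperm
transferred +1.35 and resident sperm -1.7 on S2; remating interval -0.74
and quality +0.59 on Pr; quality x female-quality -0.85 on P2; quality
+1.2 on MS). Two pathways are deliberately zero by default: the
compatibility x female-quality interaction on MS (the 24-trio design
yields only ~24 distinct covariate cells, so its estimate has a true SD
near 0.5 — no plausible magnitude is estimable with adequate power) and
the weak main effects whose detection the original assay itself could not
secure. All are configurable through `stage2_defaults()`.

## Index construction and bootstrap

`range_standardize()` is the exact linear map $(x - \min)/(\max - \min)$;
a constant vector is a hard error rather than a silent NaN. Latency is
negated *before* standardization so fast maters score high. David's scores
are computed from dyadic win proportions $P_{ij} = s_{ij}/n_{ij}$
(equivalent to mean matings per combination when every trial has one
winner), separately per fluorescence color — the GFP and RFP tournaments
are separate experiments — and then range-standardized across all 20 males
jointly when entering $w_i$, matching the index's across-genotype
standardization; a within-color switch is provided.

`bootstrap_scores()` resamples with replacement within the natural strata:
replicate pairs within each male-female combination (for *L*, *V*, *P*),
trial outcomes within each male-male dyad (for David's scores), and
replicate vials within each focal genotype (for PG). Each of B = 1000
iterations recomputes every component and every index; scores are reported
as the iteration mean with percentile 95% intervals (the percentile method
is used throughout; nothing in the procedure motivates BCa and the
original workflow reports plain intervals).

A caveat established by this package's own coverage simulations (see the
acceptance suite): because the indices depend on the sample minimum and
maximum across genotypes, the nonparametric bootstrap — formally
inconsistent for extreme functionals — understates the sampling
variability of $w_i$. At a reduced 8 x 5 x 6 design the nominal 95%
intervals cover the generator's plug-in truth about 81-83% of the time,
and fixing the standardization bounds at their true values only raises
this to ~88%. The intervals are reproducible and honestly constructed, but
they should be read as optimistic for genotypes near the extremes; this is
a property of bootstrapping range-standardized composites at these assay
sizes, not of the implementation.

## Correlations

`rmcorr()` estimates the common within-subject association by the
subject-intercepts-plus-common-slope ANCOVA, computed through
within-subject centering (algebraically identical, and fast enough to sit
inside a bootstrap): $r_{rm} = \mathrm{sign}(b)\sqrt{SS_x/(SS_x +
SS_{err})}$ with $df = n_{obs} - n_{subjects} - 1$. The subject unit is
the male-female combination — the same stratum the bootstrap resamples;
the assay description does not pin this choice, and the combination is the
finest unit at which repeated measures exist. `bootstrap_rmcorr()` and
`spearman_boot()` wrap the stratified percentile bootstrap around the
replicate data (each trait resampled from its own assay's strata, since
different flies underlie different assays).

## Contrast design

`select_extreme_genotypes()` takes the top and bottom three genotypes per
color by $w_i$, breaking ties by narrower bootstrap CI and then by
identifier, so the selection is deterministic. `assign_contrasts()`
searches all (GFP extreme, RFP extreme, female pair) candidates:

* *quality contrasts* require opposite quality categories and
  $|\Delta w_{ij}|$ at or below the 25th percentile of all pairwise
  compatibility differences for **both** females (the source describes
  "comparable compatibility" without a numeric rule; a quantile keeps the
  threshold scale-free), and maximize $|\Delta w_i|$;
* *compatibility contrasts* require the same category and an exactly
  crossed sign pattern of $\Delta w_{ij}$ across the two females,
  maximizing the weaker arm of the cross.

Assignments are made greedily by contrast strength with no female pair
reused — the original assignment algorithm is undescribed, and the greedy
no-reuse rule is this package's choice (male genotypes may recur, as they
necessarily did with only six extremes per color). `enumerate_trials()`
expands assignments multiplicatively: 12 assignments -> 24 trios -> 240
simultaneous trials; 18 assignments -> 36 combinations x 2 mating orders x
5 replicates -> 360 sequential trials, with the planned covariates emitted
per row and the deltas following the male2 - male1 convention of each
order.

## Mixed models, simplification, variance components

`fit_outcome_model()` fits binomial-logit GLMMs (Laplace, `lme4`) for MS,
S2, P2, Pr and a Gaussian LMM for log ejection latency, always with the
four design random intercepts. For proportion responses the OLRE is added
automatically when the Pearson dispersion ratio of the OLRE-free fit
exceeds 1.5 — a threshold this package fixes, since "where needed to
account for overdispersion" names no rule; binary responses never receive
one. Continuous predictors are standardized on each model's analysis
sample, and the transformation is recorded. Convergence messages are
captured on the fit object rather than silently dropped; the ML
convergence tolerance is lme4's default (relative change below 1e-6).

`lrt_simplify()` removes fixed effects backward: each round, every
droppable term (marginality respected — a main effect is droppable only
when no retained interaction contains it; the focal quality and
compatibility differences are never dropped; random effects are never
simplified) is tested by likelihood ratio against the current model, and
the weakest term is removed while its p-value exceeds 0.10. Reduced fits
are warm-started from the parent fit's variance parameters.
`check_collinearity()` reports definitional VIFs on the fixed-effects
design and flags values above 5.

`variance_components()` partitions a replicate-level diallel trait under
$y = \mu + m_i + f_j + (mf)_{ij} + e$: REML via `lme4` by default, with
the balanced method-of-moments closed form (expected mean squares,
negative estimates truncated at zero) available for exactly balanced
layouts. P2 analyses support both the inclusive set (all rematers with
post-remating offspring) and the conservative confirmed-mixed-paternity
subset via `p2_set`; the subsets genuinely differ — the conservative
filter selects against extreme paternity outcomes and attenuates
coefficients by ~10-15% in this generator — which is why the recovery
simulations use the inclusive set while the analysis drivers also report
the conservative one.

## Validation strategy and problem sizes

The acceptance suite (in `tests/testthat/test-acceptance.R`) runs at sizes
chosen to keep the full suite in the tens of minutes on one core: exact
design enumeration and the inbreeding recurrence at the study scale;
David's scores checked against an independent brute-force implementation
on every win configuration of 3- and 4-genotype tournaments at 5 trials
per dyad (about 47k matrices) plus randomized unequal-trial sweeps; rmcorr
against an lm/anova ANCOVA oracle on 100 random datasets; bootstrap
coverage on 300 reduced diallels (8 x 5 x 6, B = 400); end-to-end
parameter recovery over 200 replicates of the full five-model chain at the
assay sample sizes (one fixed scored roster, per-replicate redraw of
genotype effects and outcomes); and variance partitioning against EMS
algebra exactly, with REML compared on the same data and against the
generating truth in mean over 25 replicates.

What passing these suites shows — and what it does not: the pipeline's
estimators agree with their definitional oracles, the design enumeration
is exact, and the inference chain recovers known generating effects at
realistic sizes and noise levels. The generator emulates the dominant
structure of real assay data (shared genetic signal with trait-specific
loadings, overdispersed counts and shares, genotype-level clustering,
realistic missingness) but not everything: no within-vial larval
competition dynamics, no block-by-genotype interactions, no
male-strategic ejaculate allocation, and lognormal/negative-binomial shapes
are assumptions, not measurements. Agreement here therefore validates the
*analysis machinery*, not any biological claim about real flies.

## Known limitations

* Bootstrap intervals for range-standardized composites undercover at
  small assay sizes (quantified above) — an intrinsic property of
  percentile bootstraps of extreme-dependent functionals.
* The compatibility x female-quality pathway on mating success is not
  estimable with useful power under the 24-trio contrast design; the
  package exposes it but defaults it to zero.
* Wald intervals from binomial GLMMs with ~12-24 genotype clusters are
  slightly anticonservative; pooled recovery coverage sits near 0.91
  rather than 0.95.
* The method-of-moments variance partition requires exact balance; REML
  handles mild imbalance but inherits lme4's boundary behavior when
  genotype-level variances are near zero.
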