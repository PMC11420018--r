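---
title: "Emotion-regulation symptom networks: models, simulation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion-regulation symptom networks: models, simulation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: the statistical
models, the synthetic-data generator that stands in for participant data,
the simulation engine, and the choices made where the methodology left the
design open.

## 1. The analysis in one paragraph

Item-level data from three instruments — the 38-item RESS measuring six
emotion-regulation (ER) strategies on a 1–5 scale, and the PHQ-9 and GAD-7
measuring sixteen depression and anxiety symptoms on a 0–3 scale — are
analyzed in two complementary ways. First, an exploratory graph analysis
(EGA) of the RESS items: a regularized partial-correlation network whose
walktrap communities play the role of factors, checking that the item pool
organizes into the six strategies. Second, a 22-node mixed graphical model
(MGM) over the six strategy sum-scores and sixteen symptoms, from which we
read centralities (strength, bridge strength), global graph descriptives,
bootstrap stability, and — the analysis's distinctive step — *expected
symptom activity* (ESA): the model-implied total symptom level when the
strategies are clamped at chosen sum-scores, swept one strategy at a time
under three background scenarios (all others at minimum, median, or
maximum use).

## 2. Network estimation

### 2.1 EBIC-glasso

The item network is a Gaussian graphical model fit by the graphical lasso
on the Pearson correlation matrix of raw item scores. The solver (compiled
code, block coordinate descent) follows the classic column-by-column
formulation: each column's subproblem is an \(\ell_1\)-penalized
regression solved by coordinate descent, warm-started both within a fit
and along the penalty path. The diagonal is not penalized, the convention
of the EGA literature. The path holds 100 log-spaced penalties from
\(\lambda_{\max}\) (the largest absolute off-diagonal correlation) down to
\(0.01\,\lambda_{\max}\); each fit is scored by
\(\mathrm{EBIC}_{\gamma} = -2\ell + E\log n + 4\gamma E \log p\) with
\(\gamma = 0.5\), the default of the EGA literature (\(\gamma\) is exposed;
the selected edge set shrinks monotonically in \(\gamma\), a property the
test suite asserts). Edge weights are partial correlations. Correlation
matrices that fail positive definiteness are repaired with a nearest-PD
projection before fitting (with a message).

Raw-score Pearson correlations are the default because the analysis
convention for these instruments works on raw scores; Spearman is exposed
as an option. Polychoric correlations are deliberately out of scope.

### 2.2 Walktrap communities

Community detection runs on absolute edge weights (a random walk needs
non-negative transition weights; the sign of a partial correlation does
not change that two items travel together) with the canonical 4 steps,
taking the maximum-modularity cut of the merge dendrogram. Isolated nodes
form their own communities. Communities are numbered contiguously from 1,
the R convention.

### 2.3 Mixed graphical model

Each of the 22 nodes is regressed on the remaining 21 with a lasso
penalty, all variables standardized. Ordinal symptoms enter as their 0–3
integer codes in linear regressions rather than as multinomial outcomes:
a deliberate simplification that keeps every pairwise conditional linear —
which is what makes the model *generative* for the Gibbs engine of
Section 4 — and preserves a single interpretable sign per edge (a
multinomial edge has none). Continuous strategy sum-scores enter as is.

The per-node penalty is selected by 10-fold cross-validation with a fold
assignment fixed by a seed. Two selection rules are offered:

* `lambda.min` (default) — the penalty minimizing cross-validated error,
  the convention of mixed-graphical-model software. It maximizes power for
  the weak strategy–symptom edges this analysis cares about, at the price
  of occasional tiny spurious edges: on independent noise it returns a
  completely empty network in roughly three quarters of fits, not almost
  always.
* `lambda.1se` — the largest penalty within one standard error of the
  minimum. Near-certain to return an empty network on independent data,
  but with substantially lower power; on the default synthetic conditions
  it misses most planted cross-edges. These two behaviours cannot be had
  simultaneously by any single standard CV rule; the default favours
  fidelity to the published pipeline and to edge recovery.

Directed coefficient pairs are merged by the AND rule by default (edge =
mean of the two coefficients when both are nonzero with agreeing sign;
zero if either is zero); sign-conflicting nonzero pairs are set to zero
and counted in a warning. Effectively duplicate columns (|r| > 0.999) are
rejected up front — nodewise lasso would otherwise silently split their
shared structure. Every returned network is exactly symmetric with a zero
diagonal, asserted on all construction paths.

## 3. The synthetic-data generator

The participant data behind this style of study are typically not
publicly deposited, so the generator is a first-class module: it defines
the study conditions under which the pipeline is exercised and tested.

**Latent structure.** A 22-dimensional Gaussian: six strategy factors and
sixteen symptom latents. The strategy block is equicorrelated at 0.3
(marginal correlation — a pairwise *partial* correlation of 0.3 among six
nodes is not a valid precision matrix), entered through its inverse so
that the remaining structure can be planted in precision space: a
positive within-instrument partial of 0.1 among the nine PHQ latents and
among the seven GAD latents, and fourteen signed strategy–symptom partial
edges of magnitude 0.2 — the positive links (e.g., rumination with
uncontrollable worry, suppression with low self-esteem, arousal control
with fatigue/restlessness/worry) and negative links (e.g., reappraisal
with hopelessness, fatigue, low self-esteem, uncontrollable worry,
irritability) that the analysis is meant to recover. If a user-supplied
configuration makes the precision matrix non-PD, its off-diagonal is
scaled down proportionally (with a warning) rather than ridge-inflated,
which would silently crush the planted structure.

**Magnitude calibration.** The 0.2 magnitude is close to the feasible
ceiling of this construction: at 0.25 the precision matrix is
near-singular and the structure, encoded in tiny differences, is wiped
out by discretization noise — measured large-sample partial correlations
on the observed variables collapse from ~0.14 to ~0.04. At 0.2 the
observed-scale partials land at 0.13–0.16 after Likert discretization and
sum-score proxying, the regime where cross-validated lasso at \(N = 376\)
recovers each planted edge with its sign in the large majority of fits.

**Observables.** Each RESS item loads 0.7 on its strategy factor plus
unique Gaussian noise and is cut at \(-1.5, -0.5, 0.5, 1.5\) into 1–5
codes. Symptom latents are cut at \(\Phi^{-1}(0.45), \Phi^{-1}(0.75),
\Phi^{-1}(0.90)\) into 0–3 codes, giving right-skewed marginals with cell
probabilities (.45, .30, .15, .10) and mean 0.9 per symptom — community
(non-clinical) severity, placing the 16-symptom baseline sum near 14.4.
Default \(N = 376\). All randomness flows from one integer seed; RNG
state is restored afterwards.

**What it does not emulate.** Marginal-vs-conditional subtleties of real
data are only partly reproduced: with the full default edge list, some
planted positive links have near-zero or even negative *marginal*
correlations because indirect paths cancel them (suppression–low
self-esteem is the clearest case: suppression correlates positively with
reappraisal and distraction, which both carry negative edges to the same
symptom). The conditional structure — what the MGM estimates — is intact;
tests of marginal sign recovery are therefore restricted to pairs whose
marginals are unambiguous (the arousal-control links). Also not emulated:
item wording effects, acquiescence and method variance, missing data
(complete data are an input contract), demographic heterogeneity, and any
longitudinal dynamics. Passing tests show the pipeline recovers *this*
structure at *this* sample size; they cannot certify behaviour on real
data with weaker or differently shaped dependence.

## 4. Expected symptom activity

### 4.1 Sampler

The MGM's stored nodewise conditionals (standardized-scale coefficients,
intercepts, residual scales, training means/sds) define a single-site
Gibbs sampler. Clamped strategies are fixed at their standardized
sum-score values (raw clamp values are standardized with the *training*
statistics — the sweep is on the raw 8–40 / 6–30 / 4–20 scales); each
free node is redrawn from a Gaussian around its regression mean, and
ordinal nodes are clipped to [0, 3] and rounded, the discretized code
re-entering the other nodes' conditionals. The chain state is therefore
discrete over the free symptoms, which is what makes exact verification
possible: on networks of up to three nodes the test suite builds the
one-sweep transition matrix over the full code space, extracts its
stationary distribution, and requires the sampler's ESA to match the
exact expectation within 0.02 at 50,000 retained sweeps. Defaults:
20,000 samples after 2,000 burn-in, thinning 1, all behind one seed.
Within a sweep, every grid point reuses the same seed, so profiles are
deterministic and their point-to-point differences are not confounded by
RNG state.

### 4.2 Baseline, profiles, crossing points

Baseline symptom activity is the sum of the sixteen *observed* symptom
means. An unclamped Gibbs run provides the model-implied analogue, and
both are reported with their discrepancy. The observed value is the
reference because the discretized sampler has a known upward bias: the
clip at zero is asymmetric under right-skewed marginals (mass below 0 is
reflected up), rounding injects variance, and the strong positive
symptom–symptom coupling (spectral radius of the fitted coefficient
block ≈ 0.7 on default synthetic data) amplifies both. On default
synthetic data the model-implied baseline exceeds the observed one by
roughly 2.5 points; the discrepancy is printed rather than hidden.

An ESA profile clamps one strategy at every integer of its range with the
other five at the scenario background (minimum 8/6/4, median 24/18/12,
maximum 40/30/20 for the 8-item / 6-item / 4-item subscales). The
crossing point is the smallest clamp value whose ESA *strictly* exceeds
baseline — strict, because the question is where the strategy starts
generating more activation than already exists.

Because the planted cross-edges are strong enough to be recoverable (the
generator's reason for existing), clamping six strategies at extreme
values moves symptom means much further here than in typical empirical
data, where strategy–symptom edges are weaker; profile *shapes* (signs,
monotonicity, scenario ordering) are the meaningful output on synthetic
data, not absolute ESA levels.

## 5. Stability

The case-dropping bootstrap subsamples without replacement — the
definition underlying the CS-coefficient — re-estimating the network on
retained fractions from 90% down to 25% of cases and correlating the
statistic vector (node strength, vectorized edge weights; both harvested
from the same refits) with the full-sample one. CS is the largest drop
proportion at which ≥ 95% of replicates correlate ≥ 0.7; proportions
whose subsample would not support a fit (< p + 1 rows) are skipped and
flagged. Replicate counts are configurable; the pipeline default is 100
per proportion, and the acceptance script uses 40 on a coarser grid to
keep a full run in minutes.

## 6. Numerical choices and degenerate inputs

* Glasso convergence: outer loop stops when the largest change in the
  working covariance is below \(10^{-4}\) times the mean absolute
  off-diagonal of the input; inner lasso at \(10^{-6}\) relative. Exact
  zeros are preserved only where both directed coefficient sets vanish.
* Nodewise CV folds are a seeded random permutation of a balanced fold
  vector; the same folds are reused for all 22 regressions of a fit.
* Rounding at code boundaries (ties at .5) has probability zero under
  continuous draws; the enumeration oracle integrates the same half-open
  intervals.
* Constant columns are an explicit error naming the item, in both
  correlation and MGM paths. Out-of-range or missing cells fail CSV
  validation with the row and item named.
* Disconnected graphs: average path length is computed over reachable
  pairs and a `connected` flag is set. Mean local clustering averages
  over nodes with at least two neighbours.
* All report CSVs print doubles with exactly six decimals, making
  byte-identical reruns achievable (and asserted in the tests).

## 7. Problem sizes used by the tests

The suite runs the full EGA chain on 50 generated datasets at
\(N = 376\), the MGM sign-recovery sweep on another 50, Gibbs-vs-exact
comparisons at 50,000 retained sweeps on five small networks, reduced ESA
sweeps (10,000 sweeps per grid point) for monotonicity and scenario
ordering on constructed 22-node networks, and stability pins at 50
replicates on a coarsened grid with the (fast, compiled) EBIC-glasso
estimator over the 22 scored nodes — sizes chosen so the whole suite
completes in a few minutes while each check retains a comfortable margin
over its Monte-Carlo noise.

## 8. Known limitations

* Linear-Gaussian conditionals for ordinal nodes are an approximation;
  a categorical MGM would model the codes more faithfully but has no
  single edge sign and no linear Gibbs conditional.
* The discretized sampler's upward mean bias (Section 4.2) means
  model-implied and observed baselines differ; comparisons across clamp
  values within a profile are unaffected, absolute ESA levels should be
  read with that bias in mind.
* EGA here does not bootstrap its community structure; stability is
  assessed only for the 22-node network statistics.
* The cross-sectional model has no directionality: clamping is
  conditioning, not intervention, and no causal reading is warranted.
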