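---
title: "Methods: building and validating T-score maps"
author: "tscoremap"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: building and validating T-score maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscoremap)
```

## The problem

Patient-reported outcome instruments scored on a standardized T metric
(mean 50, SD 10 in a reference population) are precise but hard to
interpret at the bedside: a T of 61 carries no immediate clinical meaning.
When the instrument was calibrated with item response theory, however,
every score implies a most probable answer to every item in the bank. A
*T-score map* makes this explicit: for each item, the score continuum is
partitioned into contiguous bands, each labelled with the response option
that is most likely in that score range. A clinician reading "T = 61"
against the map sees, item by item, the answers a typical patient at that
level would give.

This package builds such maps from graded-response-model calibrations,
scores short-form responses onto the same metric, and quantifies how well
map-predicted responses agree with observed ones.

## Model

Items follow Samejima's graded response model. For an item with
discrimination $a > 0$ and thresholds $b_1 < \dots < b_{K-1}$ on the
latent trait $\theta$, the boundary (cumulative) curves are

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_k)}}, \qquad k = 1, \dots, K-1,$$

and the category probabilities are adjacent differences
$P_k = P^*_{k-1} - P^*_k$ with $P^*_0 = 1$, $P^*_K = 0$. Slopes are in
pure logistic units per $\theta$; an optional per-item scaling constant
(default 1) accommodates banks calibrated on the normal-ogive
approximation metric (1.7). The reporting metric is affine,
$T = 50 + 10\,\theta$ by default and configurable per bank.

The modal response at a score is the category with the largest $P_k$.
Exact ties are broken toward the lower index — deterministic and
conservative toward less severity; under the continuous model ties occupy
a measure-zero set of scores, so the rule only matters at band
boundaries.

## Map construction

`buildMap()` scans each item's modal category on a 0.01-T grid over
[20, 80] (±3 reference SD, covering operational reporting ranges; both
ends configurable) and refines every change point by bisection to a
bracket narrower than $10^{-6}$ T. Bands are half-open $[t_{low},
t_{high})$: a score exactly at a crossing belongs to the lower-category
band, consistent with the tie rule. Because the boundary curves share one
slope, the modal category is non-decreasing in $\theta$, so band
categories increase strictly along each row.

Categories that are never modal anywhere in the range — which happens
when two thresholds sit close together, squeezing a category's curve
below its neighbours everywhere — are omitted from the bands rather than
given zero-width placeholders, and are listed per item in
`omittedCategories()`. A low-discrimination item can have several such
categories at once.

## Fitting an item from printed probability snapshots

Published articles sometimes print an item's full category-probability
vector at one or two scores without the underlying parameters.
`fitItemFromSnapshots()` inverts such snapshots deterministically:
probabilities are converted to cumulative form and clamped to
$[10^{-6}, 1-10^{-6}]$ (printed values like 0.002 are rounded, and
clamping keeps logits finite); a cumulative-logit linear regression —
$\mathrm{logit}\,P^*_k = a\theta - ab_k$ is linear in $\theta$ and a
per-boundary intercept — supplies starting values; Levenberg–Marquardt
least squares on the category probabilities then refines them. The
optimizer works on $(\log a,\; b_1,\; \log \Delta b_k)$, so positivity
and strict threshold ordering hold by construction and no constraint
handling is needed. Two snapshots at distinct scores give $2(K-1)$
constraints for $K$ parameters; the fit is refused when snapshots are
fewer, coincident, or imply non-decreasing cumulative probabilities.
Noiseless round trips recover parameters to about $10^{-4}$ or better,
and the shipped published snapshot pair is reproduced within 0.001 per
category.

## Scoring

Two routes place a respondent on the T metric, both using a discretized
normal prior (81 equally spaced nodes on $[-4, 4]$, weights proportional
to the N(0,1) density — accurate to well under 0.005 $\theta$ against a
10,001-node grid):

* **Summed-score lookup** (default): the Lord–Wingersky recursion gives
  $P(s \mid \theta)$ for every summed score $s$; the table maps each $s$
  to its posterior mean $\theta$ and T. This mirrors operational
  short-form scoring practice.
* **Pattern EAP**: the posterior mean given the exact response pattern,
  using only answered items (missing responses contribute likelihood 1).

The two agree closely when items are similarly discriminating — over all
625 patterns of a four-item form with slopes in a typical operational
range, the probability-weighted correlation of the two T's exceeds 0.99 —
but genuinely diverge when slopes are strongly heterogeneous, because the
summed score weights all items equally. The validation pipeline defaults
to the summed route; incomplete forms fall back to pattern EAP with a
warning, since a summed score is undefined under missingness. T values
are reported to one decimal; band placement always uses the unrounded
value (an `integerT` flag reproduces integer-resolution placement for
comparison with published tables).

## The validation pipeline

`validationReport()` scores every respondent, reads the map-predicted
category for each item at the scored T, and tabulates *difference scores*
(observed minus predicted category, range $-(K-1)\dots K-1$; positive
means the observed answer was more severe than predicted). It reports,
per item, the difference distribution, exact and ±1 match percentages and
the Spearman correlation between predicted and observed categories
(Pearson on midranks), and per scale the perfect-match rate (respondents
matching on every item; anyone missing an item leaves that denominator,
while per-item tables keep them wherever observed). Reports are invariant
to respondent order.

With a single respondent, or constant predicted/observed vectors, the
rank correlation is undefined; the report records NA with a warning
rather than a silent zero.

## Synthetic data and the enumeration oracle

`simulateRespondents()` draws $\theta_i$ from a normal distribution
specified on the T metric and each response by inverse-CDF sampling from
the item's category probabilities, with optional missingness injected
completely at random. The clinical-like defaults — n = 1594 respondents
with T centred at 52, SD 9.5 — emulate the score distribution of a large
chronic-conditions sample in which four-item short forms were
administered. All randomness flows through an explicit seed and a fixed,
version-stable generator (Mersenne-Twister with inversion normals), and
the caller's RNG state is left untouched.

`makeFixtureBank()` generates structural test banks: slopes uniform in
[1.2, 3], thresholds sorted-uniform over [−2, 2] with a minimum gap of
0.05, and (by default) one engineered item — slope 0.8, thresholds
(−0.1, 0.1, 1.5, 1.7) — whose squeezed second category is never modal,
exercising the map's omission path. `makeClinicalBank()` is a
deterministic four-item emulation of an anxiety short form: the item
fitted from the shipped published snapshots plus three synthetic
companions with discriminations (2.5–3.1) and severity-skewed,
well-spread thresholds of the magnitude typical of operational
calibrations. It is an emulation for end-to-end testing, not a
replication of any published calibration.

`expectedMatchRates()` is the analytic twin of the simulated analysis:
for banks of up to 5 items it enumerates every response pattern, scores
it, reads the predicted band, and accumulates
probability-weighted match indicators over a quadrature grid describing
the population — exact up to quadrature. Larger banks fall back to
seeded, quadrature-weighted Monte Carlo (enumeration above 8 items is
refused outright). The population grid is separate from the scoring grid:
operational scoring always uses the standard-normal prior, while the
population may be shifted (the clinical-like checks use mean 0.2, SD 0.95
on $\theta$, i.e. T mean 52, SD 9.5, with 161 nodes spanning ±4 SD).

## What the synthetic checks do and do not show

Simulated data satisfy the model exactly: unidimensionality, local
independence, no response styles, no item drift, and a single common
$\theta$ per respondent. Under these conditions the pipeline's observed
match rates agree with the enumeration oracle within binomial error
(checked at n = 1594 across three seeds), exact match is the modal
difference category, departures concentrate at ±1, and
predicted-observed Spearman correlations on the clinical-like bank run
about 0.79–0.82 — the same qualitative regime as published clinical
analyses. Real questionnaire data are more self-consistent than local
independence implies, so observed concordance on real data can exceed
the model-consistent expectation; conversely, none of these checks
establish concordance for any particular real instrument or sample. Item
geometry matters too: narrow categories and slope heterogeneity
genuinely attenuate both match rates and rank correlations, which is why
the structural fixture banks (random thresholds) score lower on these
summaries than the clinical-like emulation.

Replicating a published clinical analysis requires the original
de-identified response data and the official calibration parameters,
distributed separately from articles. The package supports that path
directly: `readBank()` accepts a user-supplied calibration file (JSON or
flat CSV with threshold columns b1..b4), `readResponses()` validates the
response CSV against it, and `buildMap()` + `validationReport()` produce
the full difference-score and correlation report.

## Numerical choices

* Modal-scan resolution 0.01 T; crossings refined to $10^{-6}$ T. A
  crossing can land exactly on a grid point, making the probability
  difference exactly zero at the lower bracket edge; the bisection
  accepts this and returns the edge, which the half-open convention
  assigns to the lower band.
* Quadrature: 81 nodes on [−4, 4] for scoring; posterior moments by
  direct weighted sums.
* Clamping: $10^{-6}$ on cumulative probabilities in the snapshot fit,
  guarding logits of rounded printed values.
* Category probabilities are computed as telescoping differences of the
  boundary curves, so they sum to 1 to machine precision by
  construction.
* Problem sizes in the test suite: exhaustive enumerations up to $5^4$
  patterns, dense-grid scoring oracles at 10,001 nodes, recovery on
  2000 simulated respondents from an 8-item bank, pipeline consistency
  at n = 1594 across seeds 7, 11 and 13, and one 100,000-respondent
  frequency check. The full suite runs in well under a minute.

## Known limitations

* Only the graded response model is supported; partial-credit and
  nominal models are out of scope, as is calibration from raw responses.
* The simulator models a single domain; joint distributions across
  domains (a respondent's fatigue *and* anxiety) are not emulated.
* Maps omit never-modal categories silently (apart from the recorded
  note); figures render band labels only where bands are wide enough.
* The summed-score route requires complete forms; its lookup table is
  bank-specific and must be rebuilt if items change.

## A worked map

```{r example}
bank <- makeClinicalBank()
map <- buildMap(bank)
mapBands(map)[mapBands(map)$item_id == "anx_worry", ]
predictResponses(60, map)
```
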