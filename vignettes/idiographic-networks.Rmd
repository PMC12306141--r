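---
title: "Idiographic symptom networks from EMA data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Idiographic symptom networks from EMA data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idionet)
```

## The problem

When eating-disorder pathology and suicidality co-occur, the symptoms that
maintain the joint system differ from person to person, and group-average
("nomothetic") treatment guidelines offer little help in deciding what to
target first. The idiographic alternative models one patient at a time:
collect intensive repeated measurements of that patient's symptoms, estimate
the network of within-person symptom dynamics, and nominate the most central
symptoms — and the symptoms bridging the two clinical domains — as
personalized treatment targets.

`idionet` implements this workflow end to end for ecological momentary
assessment (EMA) data: bounded 0–100 symptom ratings collected several times
per day over a few weeks, with each item pre-assigned to one of two clinical
communities (eating disorder, `ED`, vs. suicidality, `SUI`).

## The measurement protocol

The default schedule is 21 days × 5 beeps/day = 105 scheduled assessment
points, with beeps every 2.5 h inside a participant-chosen 12-h waking
window and a 2-h response window per beep. The canonical time axis is the
integer pair (day, beep); wall-clock timestamps are deliberately out of
scope, as is irregular-interval modeling. A skipped survey is a fully
missing beep; a missing value is always `NA`, never 0, because 0 is a valid
slider score.

Availability percentages always use the scheduled total as the denominator
(e.g. 96 of 105 observed beeps → 91.43%, half-up rounding to two decimals).
If completion counts come from a different scheduled total than the
protocol's nominal one, percentages computed elsewhere with an inconsistent
denominator will not match this package's output; the convention here is
fixed and explicit.

## The model

Let $y_t \in \mathbb{R}^p$ be the standardized scores of the $p$ selected
symptoms at beep $t$. The package estimates a lag-1 graphical vector
autoregression:

$$ y_t = B\, y_{t-1} + \varepsilon_t, \qquad
   \varepsilon_t \sim \mathcal{N}(0, K^{-1}), $$

* $B$ is the **temporal network**: a directed, signed matrix in which entry
  $B_{ij}$ is the standardized effect of symptom $j$ at $t-1$ on symptom
  $i$ at $t$, controlling for all other symptoms at $t-1$. Diagonal entries
  are autoregressive self-loops; they are retained but marked, and excluded
  from centrality by default.
* $K$ is the precision matrix of the innovations. The **contemporaneous
  network** is the derived partial-correlation matrix
  $\omega_{ij} = -\,K_{ij}/\sqrt{K_{ii}K_{jj}}$: the association between two
  symptoms at the same beep after conditioning on all other symptoms at that
  beep and (through the VAR residualization) on the previous beep.

Both matrices are estimated jointly by penalized maximum likelihood with
separate L1 penalties: coordinate descent on the rows of $B$ (weighted by
the current $K$) alternating with a graphical-lasso update of $K$ on the
residual covariance, until the largest parameter change falls below `tol`
(default `1e-6`, at most 200 outer alternations). At zero penalties the
steps reduce to exact least squares and direct inversion, which is how the
estimator is oracle-tested.

### Penalty selection

Both penalties are chosen by minimizing the extended Bayesian information
criterion over a 10 × 10 log-spaced grid running from $\lambda_{\max}$ (the
smallest penalty that empties the corresponding matrix, computed from the
data) down to $0.01\,\lambda_{\max}$:

$$ \mathrm{EBIC}_\gamma = -2\,\ell + \log(n)\,\mathrm{df}
   + 4\gamma \log(p)\,\mathrm{df}, $$

with $\gamma = 0.5$ by default, $n$ the number of lagged pairs, and
$\mathrm{df}$ the count of nonzero off-diagonal $B$ entries plus nonzero
upper-triangle $K$ entries plus both (always-free) diagonals — the diagonal
term is constant across the grid and therefore never affects the argmin.
Exact EBIC ties resolve toward the larger penalties, i.e. the sparser
model. All of this is configurable (`penalty_grid()`, `gamma`), since
published applications of this model family rarely state their tuning
settings; the defaults above are this package's own documented choices.

### Missing data and the day boundary

Estimation uses listwise deletion at the lagged-pair level and nothing
else: a (t−1, t) pair enters only when both beeps are consecutive scheduled
points and every selected node is observed at both. No imputation pathway
exists. By default pairs never span the overnight gap
(`day_boundary_policy = "within_day"`): within a day, beeps are roughly
equally spaced 2.5 h apart, while the overnight gap is several times
longer and would violate the equal-interval assumption of a lag-1 model.
`"across_all"` is available for sensitivity analysis.

An optional per-item linear-in-day detrend (`detrend = TRUE`, default off)
is provided because slow within-study trends can masquerade as lag-1
dynamics; it is off by default since detrending is an analysis decision
that should be deliberate, not silent.

## Node selection

Networks use a small, a priori node set: the `k = 4` highest-mean items per
community (an 8-node network), means computed over observed values only.
Guidance in this literature suggests roughly six nodes for 75–100
observations, and eight-node models have been used productively for
treatment planning; `k` is therefore configurable. Two guards apply:

* **Zero-variance items** are skipped by default (with a logged message) —
  a constant item cannot carry any edge after standardization.
* **Ties** at the k-th rank are broken by higher SD (more dynamic range is
  more informative), then lexicographic `item_id`, and always flagged:
  clinically, a tie deserves human review rather than silent resolution.

## Centrality and target nomination

Six statistics are computed per node (`centrality_table()`): strength and
bridge strength on the contemporaneous network; InStrength, OutStrength,
bridge InStrength and bridge OutStrength on the temporal network. Bridge
variants restrict the sums to edges crossing the ED/SUI partition, which is
clinically pre-defined and never inferred from the data.

Two conventions are explicit because the applied literature often leaves
them implicit, and both are toggles:

* **Absolute values.** Statistics sum $|w|$ by default (the dominant
  convention in this toolchain); `signed = TRUE` yields the
  expected-influence variant in which negative edges cancel positive ones.
  This matters whenever a network contains negative edges, e.g. a
  "desire to live" item that correlates negatively with eating-disorder
  symptoms.
* **Self-loops** are excluded from In/OutStrength by default.

Targets are nominated as the top 2 nodes on each of four statistics:
contemporaneous strength, contemporaneous bridge strength, temporal
OutStrength, and temporal bridge OutStrength. ("Temporal strength" in this
context is read as OutStrength: a treatment target matters through its
outgoing influence.) The deduplicated union, with every nominating
statistic listed per symptom, is matched against an editable
symptom-to-intervention registry (`default_intervention_registry()`);
unmatched targets are kept and flagged, never dropped. Nomination ties are
broken by aggregate centrality across all six statistics, then `item_id`,
and flagged in the report.

## The synthetic generator

Because real EMA series of this kind are not publicly distributable, the
package ships a generator (`make_truth()`, `simulate_ema()`) whose defaults
emulate the study conditions: 8 nodes (4 + 4), a stable sparse $B$
(autoregressive diagonal in \[0.2, 0.5\], off-diagonal density 0.15, effect
magnitudes in \[0.25, 0.40\], spectral radius capped at 0.9), a sparse
unit-diagonal precision with at least one forced inter-community edge in
each matrix, and a latent-to-score mapping with means in \[35, 65\] and
marginal SD ≈ 15 on the 0–100 scale. Those effect sizes are what this
literature would call moderate within-person coupling; the mapping keeps
boundary clipping near 1%, well under the 5% design bound beyond which
clipping visibly distorts the Gaussian likelihood.

Simulation details that mirror the estimator's assumptions:

* under `"within_day"` semantics each day restarts from the stationary
  distribution (consistent with excluding overnight lags); `"across_all"`
  simulates one continuous chain;
* missingness deletes whole beeps completely at random (a skipped survey),
  not single items; item-level MCAR is available as an option;
* the stationary covariance solves the discrete Lyapunov equation
  $\Sigma = B \Sigma B^\top + K^{-1}$ in closed form
  (`stationary_covariance()`), which is also the simulator's fidelity
  oracle.

What the generator deliberately does **not** emulate: floor/ceiling-heavy
response styles, time-of-day and weekend periodicity, missingness related
to symptom state (MNAR), measurement reactivity, and item-level skew.
Passing recovery tests on these synthetic data therefore demonstrates that
the estimation machinery is correct and well calibrated under its own
assumptions — not that real EMA series satisfy those assumptions.

## Problem sizes used in validation

The test suite and acceptance script validate at sizes chosen to separate
sampling noise from implementation error while staying desk-scale: exact
oracles at $n = 2000$ pairs ($p = 6$); support-recovery at ten times the
default schedule (210 days × 5 beeps ≈ 840 pairs, 20 replicates), where
median support F1 reaches ≈ 0.86 (contemporaneous) and ≈ 0.81 (temporal);
null calibration on 20 white-noise replicates of the default 105-point
schedule, where ≥ 90% of fits select at most one edge per network; and
simulator fidelity on a 50,000-step latent chain, within 2% of the
closed-form stationary covariance. At the single-patient scale (~84 pairs)
contemporaneous edges of realistic size are recoverable but temporal recall
is limited — the honest operating regime of this design, and the reason the
EBIC default leans conservative: in a treatment-planning context a spurious
edge is costlier than a missed weak one.

## Known limitations

* Single-subject estimation only; no pooled or multilevel variant.
* Gaussian likelihood on bounded, often skewed slider data; heavy clipping
  or floor effects will bias edges toward zero.
* Lag-1 only, with equal-interval assumptions inside a day.
* The selected node set conditions the entire downstream analysis; items
  excluded by the mean rule may still be dynamically important.
* Network centrality is a hypothesis-generating device: a high-strength
  symptom is a candidate target, not a demonstrated causal lever.
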