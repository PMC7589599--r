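---
title: "Floating catchment accessibility scores and equity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating catchment accessibility scores and equity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcaequity)
```

## The problem

Whether an elderly person can actually use a rehabilitation service depends
on where the service is, how large it is, and — in systems with free choice
of provider — on how attractive it looks compared with its competitors.
`fcaequity` scores the geographic accessibility of capacity-bearing
facilities for a set of demand points and then asks the distributional
question: is the resulting access spread fairly across regions, and where
should a policy-maker intervene first?

## The five scores

All methods consume the same inputs: demand points with elderly population
counts $P_i$, facilities with capacities $S_j$ (provider head counts) and
consumer ratings $V_j \in [1,5]$, and a sparse table of route distances
$d_{ij}$ in km, where a missing pair is unreachable. Scores are scaled per
10,000 persons by default.

**A0 (regional average).** Capacity per capita inside each administrative
region, $A_i = 10^4 \sum_{j \in i} S_j / P_i$. It ignores distance and
cross-region use, so towns without a facility score exactly 0 regardless of
a clinic across the border; we include it because it is the baseline many
administrations still plan with, and the contrast against the catchment
methods is itself informative.

**A1 (two-step floating catchment area).** Step one computes each
facility's service ratio over the demand inside its catchment,
$$R_j = \frac{S_j}{\sum_{k:\ d_{kj} \le 30} P_k\, f(d_{kj})},$$
step two accumulates the reachable ratios at each demand point,
$A_i = 10^4 \sum_{j:\ d_{ij} \le 30} R_j f(d_{ij})$.

**A2–A4 (three-step FCA).** Before the two steps, each demand point's
demand is split across the facilities in its catchment by a choice
probability
$$w_{ij} = \frac{m_j f(d_{ij})}{\sum_{k \in \mathrm{catchment}(i)} m_k f(d_{ik})},$$
with multiplier $m_j = S_j$ (A2: bigger facilities attract more demand),
$m_j = V_j$ (A3: better-rated facilities attract more demand) or
$m_j = V_j S_j$ (A4: both). The weights enter symmetrically: step one
becomes $R_j = S_j / \sum_k w_{kj} P_k f(d_{kj})$ and step two
$A_i = 10^4 \sum_j w_{ij} R_j f(d_{ij})$.

Two consequences are worth stating. First, *conservation*: because each
unit of demand is split with weights summing to one and every facility's
ratio is its capacity divided by exactly the weighted demand it receives,
$\sum_i P_i A_i / 10^4$ equals the total capacity of facilities with any
reachable demand, for A1 through A4. The test suite asserts this to a
relative $10^{-6}$ on 100 random landscapes. Second, *degenerate
equivalences*: with all ratings equal A4 reduces elementwise to A2, and
with all capacities equal A4 reduces to A3 — useful both as sanity checks
and to see what the rating factor actually adds.

The published family of formulas this implements is often printed as a
single ratio of two grand sums with band-indexed summations. Read
literally, that binds the indices inconsistently; the accompanying prose
(step one: facility service loads; step two: accumulate reachable ratios)
and the two-/three-step catchment literature it builds on describe the
sum-of-ratios form above, which is what we implement. Likewise the choice
probabilities are sometimes printed with a per-band sum outside the ratio;
a probability interpretation requires a single normalization over the whole
catchment (the bands still enter through $f$), and that is what
`selection_weights()` computes — its rows sum to one, enforced at
$10^{-9}$ in the tests.

## The distance-decay kernel

$$f(d) = \begin{cases} 1 & d \le 3 \text{ km}\\ 3/d & 3 < d \le 15\\
15/d^2 & 15 < d \le 30\\ 0 & d > 30 \end{cases}$$

The bands correspond to roughly an hour on foot, half an hour by car and an
hour by car for an elderly traveller. Band membership is closed on the
right exactly as the inequalities are written, so $f(15) = 0.2$ and
$f(30) = 1/60$; the kernel is continuous at 3 km and drops at 15 and 30 km.
`decay_params()` accepts other edges $(e_1, e_2, e_3)$, with coefficients
derived from the edges ($e_1/d$, then $e_2/d^2$) so the first break stays
continuous; the functional family (constant / $a d^{-1}$ / $b d^{-2}$ /
zero) is fixed. A missing distance entry is treated as beyond the last
edge, not as an error, so sparse matrices are valid input. The 30-km cutoff
is inclusive — the printed band "15 < d ≤ 30" settles a convention the
prose leaves open.

## Inequality assessment

`summary_stats()` reports, per county and nationally: mean, median, sample
standard deviation ($n-1$ denominator, the common spreadsheet convention; a
single-unit group reports 0), min, max, and median − mean. A negative
median − mean flags a group where more than half the units score below the
group average — concentrated, right-skewed access.

The Gini coefficient is twice the area between the equality diagonal and
the Lorenz curve, integrated by the trapezoidal rule over the curve's
vertices (no smoothing) and clipped to $[0,1]$. The Lorenz construction
sorts units ascending by score (ties broken by id so curves and output
files are reproducible), cumulates population shares on the x axis and
*resource volume* $A_i P_i$ shares on the y axis. Cumulating $A_i P_i$
rather than $A_i$ follows the income-Gini analogy in which the score plays
per-capita income and the x axis carries population; an unweighted variant
(`weighted = FALSE`: equal x steps, y cumulates raw scores) is provided as
a sensitivity check because the convention is not universal. When the total
resource volume is zero the curve is degenerate and the Gini is defined as
0. The trapezoidal Gini is cross-checked in the tests against the
independent population-weighted mean-absolute-difference formula
$G = \sum_i \sum_j p_i p_j |a_i - a_j| / (2\bar a)$ at $10^{-9}$, and
satisfies scale invariance and the transfer principle.

Categories follow the conventional five-level scale: ≤ 0.2 highly
equitable, ≤ 0.3 equitable, ≤ 0.4 bearable, ≤ 0.6 median inequality,
> 0.6 high inequality. Boundary values at 0.2/0.3/0.4 take the lower
category; high inequality starts strictly above 0.6.

`quintile_classes()` produces the map legend classes: class $k$ holds units
whose percentile rank (maximum rank over ties, divided by $n$) falls in
$((k-1)\cdot 20\%,\ k\cdot 20\%]$, colored red, orange, green, lightblue,
darkblue from lowest to highest. Tied scores share one class. Fewer than
five units degenerate to rank order; an all-equal vector has nothing to
classify, so every unit is placed in class 1 with a warning rather than
silently in the top class.

`prioritize()` encodes the three-stage policy rule, applied to per-county
summaries under one method (typically A4): stage 1 — negative
median − mean *and* Gini in the median/high-inequality categories; stage 2
— negative median − mean and county mean below the national mean (stage-1
counties excluded); stage 3 — any remaining negative median − mean; other
counties need no action.

## The synthetic landscape generator

No town-level population, provider roster, rating or road-network dataset
is shipped; `generate_landscape()` exists so that every method and property
is testable on data with the right *structure*. Its defaults are calibrated
to the national aggregates of the motivating setting — 19 counties, ~349
towns, 658 facilities, capacities summing to ~1,140 providers, ratings with
mean 3.72 and SD 0.66 clipped to $[1,5]$ — as targets, not reproductions.

Mechanics and the reasoning behind the defaults:

* County seed points are uniform on a 150 × 400 km rectangle (the rough
  extent of a long, narrow island); the first 6 counties act as urban
  centers, mirroring six highly urbanized municipalities.
* Towns scatter around their county seat (Gaussian, SD 6 km urban / 18 km
  rural). Base populations are log-normal (meanlog 8.08, sdlog 1); urban
  towns get a 4× multiplier, which puts roughly two thirds of demand in the
  metros (the study setting reports 68%) and a national total near 3.6
  million elderly.
* Facilities anchor to towns with probability proportional to the local
  population density (Gaussian kernel, 10-km bandwidth) raised to
  $\gamma = 1.5$, then jitter 2 km. $\gamma > 1$ makes supply concentrate
  in metros more than proportionally, the documented behavior of clinics
  clustering where they train and where clients are; $\gamma = 0$ recovers
  placement uniform over towns. Capacities are $1 + \mathrm{Pois}(0.73)$,
  integers ≥ 1 averaging 1,140/658 providers per facility; ratings are
  clipped normal.
* Route distances are Euclidean × a detour factor (default 1.3, a typical
  road-network to straight-line ratio), stored sparsely up to 45 km.

What the generator does **not** emulate: real administrative boundaries,
actual road topology (a scalar detour factor has no mountains or rivers),
spatial correlation between ratings and capacity, or within-county rating
structure. Passing tests therefore demonstrate the correctness and the
mathematical properties of the methods on realistically shaped data — not
agreement with any published score table, which would require the
unreleased town-level source data.

Determinism: generation runs under a fixed Mersenne-Twister seed via
`withr::with_seed` (algorithm pinned, not platform default), so a
configuration and seed reproduce byte-identical outputs across platforms;
the CLI's `simulate --seed` inherits this.

## Numerical choices and degenerate inputs

* Accumulation in double precision throughout; no compiled code is needed
  at these problem sizes (a 349 × 658 dense decay matrix is ~1.8 MB).
* A facility with zero reachable (weighted) demand has an undefined service
  ratio: it is flagged, excluded from step two with a warning, and the
  conservation identity then holds over the remaining facilities.
* A demand point whose catchment is empty scores 0 under every catchment
  method — "no resources reachable within 30 km" is a real outcome, not an
  error.
* In A0, a region with facilities but zero population is an undefined
  ratio: reported as a warning with the score set to 0. Facilities whose
  region matches no demand region are ignored with a warning.
* Median of an even count is the midpoint of the central pair; Lorenz ties
  break by unit id; quintile ties share the maximum rank.

## Problem sizes in the test suite

The randomized property suites run on 100 compact landscapes (5 counties,
~50 towns, 20 facilities, 100 × 100 km) for conservation and weight
normalization, 50 instances of ≤ 50 units for the Gini oracle, and ≤ 20 × 10
instances for the double-loop score oracle; the end-to-end CLI check runs
one national-scale landscape (~349 towns, 658 facilities). These sizes give
the properties room to fail (unreachable pairs, empty catchments and
flagged facilities all occur) while keeping the default test run fast.

## Known limitations

Distances are consumed, never derived: there is no geocoding, network
routing or travel-time support. Capacity is a provider count; other supply
units work arithmetically but the per-10,000 interpretation is up to the
user. The Gini has no confidence interval or bootstrap. GeoJSON is
write-only and carries whatever planar coordinates the inputs use. The
package renders no maps — `classify` emits the class labels and color names
a mapping tool needs.
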