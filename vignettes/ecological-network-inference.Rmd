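---
title: "Inferring plankton dependency networks from discretized abundance data"
author: "planknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring plankton dependency networks from discretized abundance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planknet)
```

## The problem

Long plankton time series — above all the Continuous Plankton Recorder
(CPR) surveys — record which zooplankton were where, decades before anyone
counted jellyfish systematically. If the dependence of jellyfish on their
zooplankton prey field can be measured *today* (from a cruise snapshot),
and the historic dependency structure *among* zooplankton groups can be
learned from the CPR archive, the two can be combined to reconstruct the
probability that jellyfish abundance was low or high in past decades.

`planknet` implements that chain as a reusable pipeline:

1. taxa are pooled into biogeographic groups (Warm Temperate, Warm
   Temperate Oceanic, Temperate Oceanic, Shelf Sea, Sub Arctic) and
   weekly-averaged;
2. abundances are discretized into three ordinal states,
   ZERO < LOW < HIGH;
3. a discrete Bayesian network is learned per period by greedy
   hill-climbing under a Bayesian–Dirichlet (BDeu) score, repeated over
   bootstrap subsamples and averaged into a consensus network;
4. each consensus edge carries a signed influence score (IS) separating
   aggregation, segregation and non-monotonic dependence;
5. jellyfish dependencies from a spatial (cruise) network are grafted onto
   each decadal network, and the jellyfish posterior is queried under low
   and high sea-surface-temperature (SST) evidence;
6. an annual catch series too short for structure learning is screened
   against each group by forced-edge scoring (a naïve-Bayes-style ranking).

A synthetic generator reproduces the statistical shape of the real data
(zero inflation, seasonality, a regime shift, a station snapshot) from a
known ground-truth network, so every stage is testable end to end without
any data download.

## Discretization

Counts become three states: an exact zero is ecologically different from a
small positive count, so zeros form their own state; the LOW/HIGH break is
the **median of the non-zero values** of each variable, with values equal
to the median coded LOW. Median rather than mean because plankton counts
are heavy-tailed — a mean break would starve the HIGH bin. Environmental
variables without zeros simply occupy two states. Variables occupying
fewer than two states are flagged degenerate and excluded from learning.

Before the search, every variable pair is screened with a Pearson
chi-squared test on its joint state table (no continuity correction,
empty rows/columns dropped). Pairs with `p > 0.25` — i.e. pairs whose
joint distribution is indistinguishable from the product of their margins,
typically because of shared zero inflation — are blacklisted and can never
form an edge. The permissive 0.25 cut deliberately errs toward keeping
pairs: the score, not the filter, makes the final call.

## Scoring and search

Network quality is the log BDeu marginal likelihood with equivalent sample
size `ess = 1` (configurable). Cardinalities are *effective*: a variable's
arity is its number of occupied states, so a zero-free SST is binary and a
constant parent changes nothing. The score decomposes over node families,
which the hill-climber exploits: single-edge additions, deletions and
reversals are scored by the affected families only, the best move is taken
(ties broken randomly under a caller-supplied seed), and the climb stops
when no move improves. In-degree is capped at three parents per node to
limit CPT size on these sample sizes. Restart 1 climbs from the empty
graph; further restarts (default 10) start from sparse random DAGs. The
budget counts scored candidate moves (default cap 10^7, never binding on
networks this small). On three-node problems the greedy optimum is checked
against exhaustive enumeration of all 25 DAGs.

## Model averaging and the consensus

Structure learning on these data is unstable to small perturbations, so
each network is re-learned on 100 random subsamples holding 90% of the
rows (drawn without replacement — a delete-10% jackknife; rows are the
weekly samples). Each directed edge's occurrence frequency and mean IS are
tallied.

Thresholding works on the **unordered pair**: the two orientations of a
dependence are mutually exclusive within one DAG, so their summed
frequency is the fraction of bootstraps containing the dependence at all.
Score-based search identifies dependencies far more reliably than arrow
directions — in synthetic runs a pair present in 100/100 bootstraps can
split 52/48 between orientations — and thresholding directions separately
would silently discard exactly the strongest dependencies. The frequency
histogram is characteristically bimodal (noise edges near zero, real edges
near one); the `"valley"` rule splits the two modes by exhaustive
two-class variance maximization and falls back to 0.5 with a warning when
the histogram is not bimodal. A pair whose minority orientation carries at
least a quarter of its occurrences is flagged mutual and rendered without
an arrow. Periods are compared by a chi-squared test on the
periods-by-edges table of bootstrap occurrence counts.

## Influence scores

The IS of an edge summarizes how the child's conditional distribution
shifts across parent states, with co-parents marginalized at their
empirical configuration weights. For each adjacent pair of occupied parent
states the child's cumulative distributions are compared: all comparisons
stochastically increasing gives a positive IS, all decreasing negative,
mixed directions zero (non-monotonic dependence), identical conditionals
zero. The magnitude is the mean absolute CDF difference between the two
*extreme* occupied parent states, so a deterministic identity CPT scores
exactly +1 and a deterministic reversal −1, and |IS| ≤ 1 always. Voting
uses the empirical (count-based) conditionals rather than the
prior-smoothed CPT: unequal configuration totals would otherwise inject
sub-prior-sized non-monotonicity and collapse genuinely monotone edges to
zero.

## Exact inference and transposition

Posterior queries run sum-product variable elimination on the CPT
factorization and are verified against full-joint enumeration (an
independent brute-force code path kept in the package) to 10⁻⁹ on networks
up to 12 nodes. Evidence is hard (a single state); evidence assignments of
probability zero raise an identifying error.

Historic jellyfish inference assumes the jellyfish–zooplankton
dependencies measured in the spatial snapshot remained static across
decades: each jellyfish node is grafted onto a decadal network with its
parent edges and CPT verbatim (parent names normalized through the
group-name alias map, e.g. "Cold Temperate" → Temperate Oceanic). Grafted
nodes are sinks, so host-network marginals are untouched. Because edge
*direction* in the learned spatial consensus is weakly identified, the
pipeline re-orients consensus edges incident to the imported nodes toward
them before fitting — the construction requires jellyfish dependencies as
parent edges. CPTs for each decade are refit on that decade's full data
over the consensus structure (bootstrap-averaged CPTs would be an
alternative; refitting keeps the probability model in closed form). The
output table reports, per decade and SST state, the full zero/low/high
posterior and the low/high pair renormalized to 100% with zeros excluded.

## Forced-edge ranking

An annual catch series gives only ~10 samples per decade — too few to
enter the structure search — so each candidate group `g` is evaluated by
forcing the single edge `g → catch` into the network and recording the
score change. By decomposability only the catch node's family changes, and
the family-local shortcut is verified against full-network rescoring.
`deltaScore` is reported on the conventional cost scale
(−Δ log marginal likelihood): **more negative = better fit**, and an
uninformative forced edge costs prior parameters, so its deltaScore is
≥ 0. Zooplankton windows are September-anchored yearly means (September
being herring spawning time) paired by default with the catch of the
following calendar year; the pairing lag is a configuration option because
the right convention is genuinely ambiguous.

## The synthetic generator

The generator emulates the *statistical* structure of grouped CPR data; it
is not a plankton simulator. Weekly latent states are drawn ancestrally
from a known ground-truth network over the five groups, chlorophyll index,
SST and a monthly NAO-like index; group state probabilities are tilted by
a per-group seasonal cycle (staggered peak months, log-odds amplitude
0.3); counts are emitted by a zero-inflated negative binomial
(`mu` 5/50 for LOW/HIGH, dispersion 1, extra zero mass 0.25/0.02), with
1–4 samples per week. Those emission defaults were calibrated analytically
so the weekly-averaged tables carry ≈39% zeros, the zero mass typical of
grouped, weekly-averaged CPR data (measured 40.8% over 1565 weeks). SST
follows an annual sinusoid (mean 10.5 °C, amplitude 3.5 °C, late-August
peak, noise sd 0.4) — Irish Sea values. A regime shift (default 1985)
rewires the network afterwards: the Warm Temperate Oceanic group becomes
dependent on Shelf Sea zooplankton (joining the two decoupled
sub-networks) and the Warm Temperate–SST dependence flips sign.

The spatial snapshot (default 144 stations) uses sharper conditionals and
lighter zero inflation (`pi` 0.10/0.01, dispersion 3): cruise net hauls
filter far more water than a CPR silk transect, so station counts resolve
abundance states much better. *Aurelia* depends negatively on Warm
Temperate and positively on Temperate Oceanic zooplankton by default, and
an "other jellyfish" pool follows *Aurelia*.

What passing tests on these data do **not** show: robustness to taxonomic
misclassification, to the CPR's changing spatial coverage, to
autocorrelation beyond the month scale, or to emission families other than
the zero-inflated negative binomial. The month-blocked NAO index in
particular shares seasonal blocking with SST, and the learner can pick up
such pseudo-replicated dependence — visible in synthetic runs as
occasional SST–NAOI consensus edges, and a caveat that applies equally to
real data.

## Numerical choices and degenerate inputs

* Ordinal states are coded 1/2/3; CPT columns index parent configurations
  in mixed-radix order, first sorted parent fastest.
* Ties at the discretization median go to LOW; all-zero and constant
  variables are excluded from learning with a warning.
* CPT smoothing follows the scoring prior (`ess/(q·r)` per occupied cell);
  unoccupied child states keep probability 0; unreachable parent
  configurations are filled uniformly (they carry no probability mass).
* Greedy ties among equal-gain moves (within 10⁻¹²) are broken uniformly
  at random under the search seed; each bootstrap's search seed is a hash
  of its drawn rows, so identical subsamples search identically and a
  `frac = 1` "bootstrap" is exactly replicated.
* The valley threshold falls back to 0.5 with a warning on unimodal
  frequency histograms; an all-blacklisted problem returns the empty
  network with a warning.
* ISO-8601 weeks define the weekly grid (the week is otherwise
  ambiguous at year boundaries); monthly SST is interpolated linearly
  between month midpoints and held constant outside the range, while the
  NAO index attaches to weeks by month membership, not interpolation.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the statistical properties sharp yet quick to
compute: 200 random networks of 3–12 nodes for the inference oracle, 50
three-node datasets of n = 200 for search optimality, a 300-week series
with 100 bootstraps at 90% for structure recovery (F1 against the
generating edges, direction-agnostic), 1565 weeks for the zero-mass
calibration, n = 500 for IS sign recovery, and 50 ten-year response
problems for the ranking check.

## Known limitations

* Only hard, single-node evidence; no soft or multi-node evidence
  composition beyond what the joint factorization gives.
* No dynamic (time-lagged) networks: weeks are treated as exchangeable
  samples within a period, exactly as in the averaging design.
* The IS magnitude normalization is one defensible choice among several;
  comparisons of IS *magnitudes* across packages are not meaningful,
  only signs and orderings.
* Direction of consensus edges is reported but weakly identified;
  downstream inference relies on it only where the sink construction
  pins it down.
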