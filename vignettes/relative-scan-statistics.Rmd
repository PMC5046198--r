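---
title: "Scan statistics for binary genomic event data: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan statistics for binary genomic event data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relscan)
```

## The model

relscan treats a two-stranded genome as a large collection of independent
Bernoulli trials, one per (chromosome, position, strand). A trial is a
success when a point event — in the motivating application, a viral vector
integration site (IS) recovered by sequencing — maps to that coordinate.
Stretches that the assay cannot observe ("blind regions", from restriction
enzyme placement or unmappable sequence) are removed from the trial set
strand by strand, so the effective genome size is

    N = 2 * sum(chromosome lengths) - (masked bases, both strands),

and the effective size of an interval `[s, e]` is `n_Z = 2 * (e - s + 1)`
minus the masked bases it overlaps. Two conventions are fixed package-wide
and matter at the  base-pair scale only: interval *trial counts* include
both endpoints (`e - s + 1` per strand), while the *length filter* below
uses the simple coordinate difference `e - s`. Coordinates are 1-based
inclusive everywhere except the BED input boundary, where the standard
0-based half-open convention is converted on read.

### Univariate scan

For a candidate zone `Z` with `n_Z` trials and `x_Z` of the `X` total
events, the Bernoulli scan statistic is the likelihood ratio comparing an
elevated in-zone success probability `p_Z` against the constant-rate null
`p = X / N`:

    lambda_Z = 2 * [ l(p_hat, q_hat) - l0 ],   p_hat = x_Z / n_Z,
    q_hat = (X - x_Z) / (N - n_Z),

with `lambda_Z = 0` whenever `p_hat <= q_hat` (the alternative is
one-sided: only enrichment is of interest). The scan maximum `S` and its
zone are reported together. All likelihood work is in log space with the
`0 * log 0 = 0` convention, which keeps the closed forms exact at boundary
counts; at genomic `N` this is a numerical necessity, not a nicety.

### Relative scan

Given two event series on the same masked support (for example MLV- and
HIV-derived vector IS sets, whose integration preferences differ), the
relative scan asks where the two series' in/out rate ratios differ *beyond
a shared factor*. Conditional on a zone, the null allows any common
in-zone multiplier `k_Z`:

    H0: p_1 = k_Z q_1  and  p_2 = k_Z q_2
    H1: the ratios p_i / q_i differ between series.

The alternative has closed-form MLEs (four free parameters, two per
series, by independence). The null (three parameters) has no closed form;
the package maximizes it numerically (below). Twice the log-likelihood
difference is referred to a chi-squared distribution with one degree of
freedom (4 - 3 = 1). A significant zone is labelled for the series with
the larger estimated ratio, and the effect size reported is the natural
log of the ratio of ratios (positive: first series).

Shared rate variation is exactly what makes naive comparisons misleading:
both vector types concentrate in accessible chromatin, so a region can be
a hotspot for both without being differentially targeted. The shared-`k`
null absorbs such common structure.

### Why event-delimited zones suffice

For fixed event content, growing a zone only adds failure trials, and the
likelihood ratio strictly decreases until the window absorbs another
event. The maximizer is therefore attained on intervals whose endpoints
are event positions, reducing the candidate family from all `O(L^2)`
intervals to at most `(X1 + X2) (X1 + X2 - 1) / 2` pairs (pooled events in
two-series mode). The test suite verifies this reduction against an
exhaustive all-interval scan on small synthetic genomes; the comparison
restricts the exhaustive side to intervals holding at least two distinct
event positions, because the candidate family is defined by pairs of
distinct delimiters.

### Multiple testing and secondary clusters

Every zone is a test, and zone tests overlap heavily in both directions,
so the package controls the family-wise error rate with Holm–Bonferroni
(valid under arbitrary dependence) at level `alpha` (default 0.01).
Secondary clusters come from a sequential loop: accept the maximizer if
its Holm-adjusted p-value clears `alpha`, make its interval blind on both
strands, drop its events, rebuild the zone family excluding anything
overlapping an accepted zone, and rescan with the family size reset to the
current family. Accepted zones are pairwise disjoint by construction. A
`batch` mode accepts all Holm-significant, mutually disjoint zones of a
round in rank order; it reaches the same regions in fewer rounds but the
error-control argument is cleaner for the default one-per-round loop.

## Numerical design of the constrained null fit

The null log-likelihood separates, for fixed `k`, into two concave
one-dimensional problems whose stationarity conditions are quadratics in
`q_i` — so the conditional maximizers are closed-form, and the whole fit
reduces to maximizing a one-dimensional profile over `log k`. The profile
maximum is located through the envelope derivative

    dP/dk = sum_i [ x_i / k  -  (n_i - x_i) q_i* / (1 - k q_i*) ],

by a 33-point sign grid on `log k` in `[log 1e-9, log 1e9]` plus 50
bisection steps per sign change, evaluating the log-likelihood itself only
at the few candidate roots. Zones with no in-zone events drive `k` to the
lower bracket edge and are flagged as boundary fits. The rare
configurations whose conditional maximizer hits the feasibility clamp
`k q <= 1 - 1e-12` (possible only when a series has `x = n`) fall back to
a golden-section search on the profile. This design is deterministic —
identical inputs give identical fits with no starting values or seeds —
and is validated in the test suite against an independent refining grid
search over `(k, q1, q2)` to step 1e-6 (observed agreement ~1e-9 relative,
versus the 1e-4 requirement), with `lambda >= 0` asserted throughout.
Sub-tolerance negative `lambda` from the numerical fit (never observed
beyond 1e-8) is clamped to zero; anything worse is flagged and the zone is
excluded from ranking with a warning.

## Tunable parameters

* `L_max` (bp, default 2.5e7): longest admissible zone, measured as
  `end - start`. Zones beyond a few tens of Mb are rarely interpretable
  and inflate the family; values above half the support trigger a warning.
* `EC_min` (events, default 3): smallest admissible pooled event count.
  Three events is the smallest cluster that is not a mere pair. In
  two-series mode the filter counts *pooled* events, so zones empty in one
  series — precisely the most interesting relative clusters — survive.
* `alpha` (default 0.01): family-wise level of the sequential detection.
* P-value mode: chi-squared (default) or a Kulldorff-style Monte Carlo
  reference for the scan maximum (`mc_null_max_lambda`), which re-scans
  simulated uniform null datasets. The chi-squared route is conservative
  for the univariate scan because the one-sided truncation puts mass at
  zero; this is documented rather than corrected.

Whether the tables' statistic is the likelihood ratio or its log is a
presentation choice; the package reports `lambda` (the Wilks scale, on
which the chi-squared reference applies) and also exposes
`S = exp(lambda / 2)`.

## The synthetic-data generator

`simulation_scenario()` + `simulate_is()` generate event sets with the
structure the scans assume: exactly `X_i` distinct events per series
(matching the analyses' conditioning on observed totals), placed on the
mappable trials with a piecewise-constant rate. Planted intervals multiply
the base rate per series; equal multipliers in both series encode the
relative-scan null of *shared* rate variation, unequal multipliers plant a
relative cluster. Sampling draws a segment with probability proportional
to width times multiplier and a uniform position within it, redrawing the
rare duplicate coordinate; at genomic trial counts this is an accurate
stand-in for successive weighted sampling without replacement. The
expected fraction of events inside a plant has the closed form
`w r / (w r + rest)` used by the calibration tests.

What the generator deliberately does not emulate: sequencing-depth bias,
PCR duplicates collapsing to shifted coordinates, chromatin-state rate
gradients, or correlated integration within clones. Passing tests
therefore demonstrate correctness of the statistics under the stated
Bernoulli model, not robustness to every real-data artefact; blind-region
masks are the one systematic bias the model does absorb.

## Verification study design (and one honest limitation)

The acceptance checks in `tests/testthat/test-acceptance.R` and the
recomputation script `scripts/acceptance.R` use problem sizes chosen so
the full suite runs in minutes on one core: exhaustive-scan equivalence on
genomes of a few kb (where all intervals can be enumerated), null-fit
oracle checks on counts of tens-to-hundreds, Wilks calibration with 500
events per series and a 5% shared hotspot (k = 3) on a 1 Mb support,
family-wise error over hundreds of null pipelines at 1e5 trials and 200
events, and recovery of a 1%-of-support plant (rate x10 in series 1, 1000
events per series) on a 200 Mb support.

Two distributional checks are deliberately strict at desk scale and can
fail even though the statistics behave as intended; both are asserted
as stated and analysed here rather than weakened.

First, a one-sample Kolmogorov–Smirnov test of the fixed-zone `lambda`
against chi-squared(1) over 5000 replicates. With a shared support
(`n_1 = n_2`) and equal totals, any replicate with `x_1 = x_2` saturates
the constrained null *exactly*, so `lambda` carries a point mass at zero
of size `P(x_1 = x_2) >= 0.025` for every possible zone weight at 500
events per series — above the KS critical distance (0.023) at this
replicate count, while the continuous reference puts no mass there. The
calibration that matters is verified alongside and passes: moments (mean
~1, variance ~2) and the nominal-level rejection rate at the 3.841
cutoff (0.05 +/- 0.01). The discrepancy is a small-count discreteness
effect that vanishes as counts grow, not a miscalibration of the test.

Second, the family-wise error bound of 2.5% for the sequential pipeline
at `alpha = 0.01` on null data with 200 events over 1e5 trials. At this
density (mean spacing 250 bp) the zone family contains 3-event zones a
few bp wide, for which the asymptotic chi-squared tail *understates* the
true probability by orders of magnitude; Holm cannot repair invalid
per-zone p-values. Measured over 2000 independent null pipelines the
detection rate is ~2.5% — inflated above the nominal 1% and sitting at
the bound, so individual 500-run batches land on either side. At genomic
scale (N in the billions, kb-wide zones) the chi-squared tail tracks the
exact small-count tail closely and the inflation disappears; where exact
control matters at small scale, the Monte Carlo scan-maximum mode is the
conservative alternative.

## Known limitations

* Zones are one-dimensional, intra-chromosomal intervals; no circular or
  cross-chromosome windows, and no more than two series.
* Chi-squared p-values are asymptotic; for very sparse zones (counts of a
  handful) they can be anticonservative per-zone, which Holm over a large
  family mitigates but does not remove. The Monte Carlo mode is the
  conservative alternative for the scan maximum.
* Blind regions are consumed, never inferred; a wrong mask biases `n_Z`
  and `N` directly.
* The sequential loop's conservative exclusion of zones *partially*
  overlapping accepted ones can split a broad signal into adjacent
  detections across rounds.
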