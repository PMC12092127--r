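---
title: "Methods: population genetics and depth-envelope range projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and depth-envelope range projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadalrange)
```

## Scope and intended use

`hadalrange` supports studies of cosmopolitan deep-sea species for which
two kinds of evidence are available: single-locus sequence alignments
(mitochondrial and nuclear barcodes such as 16S, COI, 28S) from a handful
of widely separated sites, and a compiled table of occurrence records with
depths. The package turns the first into standard descriptive population
genetics (haplotype structure, diversity indices, neutrality tests,
distance-based delimitation screens) and the second into a
one-dimensional habitat model: the closed depth interval spanned by the
records, projected onto gridded bathymetry to ask what fraction of each
ocean basin lies at depths the species is known to occupy.

## Missing data and the site universe

All diversity statistics, haplotype collapsing and distance matrices
default to **complete deletion**: a column is retained only if every
sequence carries an unambiguous `A/C/G/T` there. IUPAC ambiguity codes
are treated as missing rather than expanded, because expansion rules
would silently change the haplotype count. The practical consequence is
that segregating sites, mean pairwise differences and per-site diversity
share one site universe, which is what makes two cross-checks exact:

* `pi` equals the mean of the raw p-distance matrix entry-for-entry, and
* Tajima's D combines `ss` and `k_hat` measured on the same columns.

Pairwise deletion is available for distance matrices
(`p_distance_matrix(..., deletion = "pairwise")`); a pair sharing no
comparable site yields a flagged `NA`, never a silent zero.

## Diversity statistics and Tajima's D

Haplotype diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\,(1 - \sum_i p_i^2)$. Nucleotide diversity is the mean
proportion of differing retained sites over all $\binom{n}{2}$ pairs.
Tajima's D follows the 1989 formulation exactly
($D = (\hat k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$); with $S = 0$ the
statistic is returned as `NaN` with an `undefined` flag rather than an
error, since monomorphic barcode alignments are routine in this setting.

Significance uses the beta approximation: under neutrality D is treated
as a generalized beta variate with mean 0 and variance 1 on
$[D_{\min}, D_{\max}]$, the bounds implied by the most skewed possible
site-frequency configurations. We report a **two-sided** p-value
$2\min(F(D), 1-F(D))$ and star flags at 0.05/0.01/0.001. Coalescent
simulation of the null is available through the bundled simulator for
users who prefer an empirical reference distribution. The beta
approximation's rejection rate at $\alpha = 0.05$ is checked by Monte
Carlo in the acceptance suite and stays within [0.01, 0.10] — adequate
for flagging, slightly conservative in the tails, which is a known
property of the approximation.

## Distance corrections and base frequencies

JC69 is $d = -\tfrac34\ln(1 - \tfrac43 p)$; F81 is $d = -B\ln(1 - p/B)$
with $B = 1 - \sum_i \pi_i^2$ from **supplied** base frequencies, because
studies in this area typically fix frequencies rather than re-estimate
them per matrix (empirical estimation is offered via
`empirical_base_freqs()`). Published frequency sets are rounded to three
decimals and can miss 1 by up to 0.005; `base_freqs()` renormalizes such
sets with a warning and rejects anything farther off. At uniform
frequencies $B = 3/4$ and F81 reduces to JC69 exactly, which the tests
assert to 1e-12. Saturated pairs ($p \ge B$) become flagged `NaN`, not
`Inf`, so range summaries skip them.

## The parsimony connection limit

Statistical-parsimony networks connect haplotypes only up to the step
count at which unseen multiple substitutions remain improbable. The
package estimates the parsimony probability with a seed-deterministic
Monte-Carlo scheme rather than reproducing any particular legacy
recursion: $w_k$ is the probability that $k$ Jukes–Cantor substitutions
placed uniformly over $L$ sites leave exactly $j$ visible differences
(estimated by simulation; a site hit $h$ times differs from its ancestor
with probability $\tfrac34(1 - (-\tfrac13)^h)$), and
$P(j) = w_j / \sum_{k \ge j} w_k$, truncating the sum at the first
contribution below $10^{-4}$. The truncation is part of the estimator's
definition: it is what makes $P(0) = 1$ exact. The default 95% threshold
and 10 000 replicates are exposed in the configuration; estimates are
reproducible given the seed, and monotonicity over $j$ is asserted at a
fixed seed rather than in expectation. This estimator is deliberately
simpler than the original statistical-parsimony derivation; it trades
fidelity to an opaque legacy computation for a reproducible, testable
contract, and at typical barcode lengths it yields somewhat more
conservative (smaller) limits.

## Network construction

`build_network()` builds a minimum spanning **network**: candidate pairs
are processed in increasing step-distance order, and a pair is linked
when its endpoints belonged to different components at the start of that
distance level. This keeps all equally short alternative connections
(reticulations), is independent of input row order by construction, and
degrades to disconnected components when no inter-component distance is
within the connection limit. Links of $d$ steps are expanded through
$d-1$ latent nodes (frequency 0, ids `<id1>-<id2>-step-<k>`), matching
the convention that unsampled intermediates are displayed explicitly.
Haplotypes are classified `private` (single locality) or `shared`
directly from the locality sets.

## Delimitation screen

The partition sweep is single-linkage agglomeration evaluated at every
distinct merge height; at threshold $t$ the groups are exactly the
connected components of the graph with edges $\{d_{ij} \le t\}$ (the
tests assert this equivalence against a brute-force component search).
Partitions are ranked by barcode gap (smallest between-group distance
minus largest within-group distance), ties broken toward fewer groups. A
partition with no within-group pair — notably the all-singleton
partition over distinct sequences — has no intraspecific distance
distribution and therefore no defined gap; it is excluded from ranking.
Without that rule the all-singleton partition would trivially top every
sweep. When no partition has a positive gap the one-group partition is
returned with a warning. This gap-rank screen deliberately does **not**
reproduce composite scores or panmixia p-values of published
automatic-partitioning software; reports carry that caveat.

## Habitat projection

Areas are computed analytically on the authalic sphere
($R = 6371.0088$ km): a cell of longitudinal width $\Delta\lambda$
between latitudes $\phi_1 < \phi_2$ contributes
$R^2\,\Delta\lambda_{\mathrm{rad}}(\sin\phi_2 - \sin\phi_1)$ km².
Any equal-area projection (e.g. world Mollweide) measures the same
quantity; the analytic route has closed forms ($4\pi R^2$ for the
sphere, $\pi R^2$ for the 0–30° zone) that the tests verify to 1e-9
relative. The depth interval is closed on both ends because its
endpoints are themselves observations. Percentages are rounded
half-to-even at two decimals; published tables in this area sometimes
truncate instead, so comparisons against printed cells allow one unit in
the last digit. Basin masks are consumed as label rasters co-registered
with the grid; converting polygon basin boundaries to such a raster is a
documented pre-step outside the package. Grid exchange uses the ESRI
ASCII text format (plus a JSON legend for basin labels) — the installed
stack has no GeoTIFF/netCDF reader, and the analytic contract does not
depend on the container format.

## What the synthetic generators emulate

* `simulate_coalescent_alignment()` is a standard neutral Kingman
  coalescent with infinite-sites mutation placed onto distinct columns of
  a fixed-length alignment (an explicit error on overflow rather than
  silent finite-sites recycling). This makes $E[S] = \theta a_1$ and
  $E[\hat k] = \theta$ exact, so the simulator doubles as the calibrated
  null for Tajima's D: over 500 replicates at $n = 20$, $\theta = 5$ the
  mean D must sit within ±0.15 of zero. It does **not** model
  recombination, migration/structure, selection or rate heterogeneity —
  a green calibration says the statistics are computed correctly under
  neutrality, not that real populations are neutral.
* `make_synthetic_records()` emulates a compiled occurrence table. Its
  reference parameterisation — 195 records over 75 sites spanning
  3890–8931 m, with a strongly Pacific-skewed basin mix — mirrors the
  compiled dataset dimensions this kind of study reports; depth endpoints
  are forced present so the derived envelope equals the requested range
  exactly. Coordinates and site-to-record multiplicities are parametric,
  not geographic truth.
* `make_synthetic_bathymetry()` builds latitude-band worlds whose every
  area has a closed form, with basins as longitude sectors; band edges
  must align with cell edges so the grid sum reproduces the closed form
  to rounding error.

## Numerical and degenerate-input conventions

* Single-record envelopes are returned degenerate with a classed warning,
  not an error.
* Tie-breaking in the network is by (distance, lexicographic id pair);
  latent ids are deterministic.
* D reporting uses 5 decimals in CSV outputs, matching conventional
  table formatting.
* All stochastic components (parsimony estimator, simulators) take
  explicit seeds and restore the caller's RNG state.

## Known limitations

Haplotype relabeling under row permutation is by design (ids follow first
occurrence); comparisons across orderings must key on representative
sequences. The parsimony estimator's limit is Monte-Carlo noisy near the
threshold; raise `mc_reps` for production runs. The habitat model is
depth-only — using depth as a habitat proxy inherits all the caveats of
ignoring temperature, oxygen and substrate. Reproducing published
per-locus tables additionally requires the exact deposited sequence sets,
which are not bundled.
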