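---
title: "Methods: voxel-based FA contrasts, tiered cluster inference, and gap-based subgrouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based FA contrasts, tiered cluster inference, and gap-based subgrouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model and its assumptions, every tunable parameter with
its default and rationale, the numerical conventions, the design
decisions taken where the design was genuinely open, and the known
limitations. The companion README shows a worked example.

## 1. Data model

An `fa_volume` is a 3-D scalar field of fractional anisotropy values on a
shared grid with a 4×4 voxel-to-mm affine. FA is dimensionless in
[0, 1]; `NaN` marks voxels without valid FA after registration. Voxel
indices are **0-based** at every interface (the NIfTI convention); peak
coordinates are reported as uninterpolated voxel centers mapped through
the affine. Analyses that report sub-millimetre peak coordinates do so by
interpolating the statistic map; we deliberately do not, so peak
coordinates land on the voxel lattice.

Values outside [0, 1] by less than 1e-6 are clamped with a warning
(double-precision round-off after resampling); larger violations are
errors, because they indicate a unit or preprocessing problem rather than
noise.

All volumes entering one contrast must share grid shape and affine
exactly; any mismatch is an error, never silently resampled —
registration is an input to this package, not a feature of it.

## 2. Voxel contrast

At each voxel we test patients versus controls with a two-tailed
two-sample t statistic; `t > 0` means patients elevated. The default is
the classic pooled-variance (Student) test with `df = n1 + n2 − 2`; it is
what the mass-univariate neuroimaging tools of the 2-mm DTI era computed,
and with one-to-one matched cohorts of equal size the pooled and Welch
tests coincide closely. Welch's test is available (`variance = "welch"`)
and recorded in the stat map and the run manifest.

Voxels are excluded from the search set (not assigned infinite t) when
any subject is missing there or when the pooled variance is zero: a
zero-variance voxel carries no evidence, and an infinite statistic would
otherwise dominate every cluster.

## 3. Cluster inference

**Contiguity.** Clusters are maximal connected components of same-sign
voxels with uncorrected `p <` `voxel_p_threshold` (default 0.05). The
contiguity rule is *sharing a face or an edge, never only a corner*,
which in 3-D is the 18-neighbourhood; this is the default
(`connectivity = 18`), with 6 and 26 selectable and recorded in
provenance, since the edge-sharing phrase is unambiguous in 2-D but
admits readings in 3-D. Positive and negative differences never join the
same cluster because each cluster is reported with a direction.

**Tiers.** Each cluster is assigned to an area of evaluation (AOE) iff
strictly more than 50% of its voxels fall inside the AOE's mask; exactly
50% does not qualify (ties go to the less favourable tier), and among
several qualifying AOEs the most lenient tier wins (primary over
secondary). Unassigned clusters are evaluated at the whole-brain tier.

**Correction.** The peak voxel of a cluster in a tier with search volume
`N_search` and extent requirement `k` must clear
`alpha · k / N_search` — a Bonferroni correction over the `N_search/k`
non-overlapping cluster-sized blocks that fit in the search volume. With
the default tiers (k = 9, 27, 81; N = 418, 9,308, 200,000) this gives
0.00108, 1.45e-4 and 2.03e-5 at `alpha = 0.05`. Peaks within one order
of magnitude (`trend_factor = 10`) of the threshold are flagged as
trends. `N_search` for the primary and secondary tiers is the total
voxel count over that tier's AOE masks; the whole-brain tier uses the
evaluated-voxel count of the search mask, with a fixed constant (such as
the 200,000-voxel compatibility value) available through
`tier_config(n_search_whole_brain = ...)`.

**Known limitation — calibration depends on spatial correlation.** The
`N/k` correction treats the search volume as `N/k` independent blocks.
With spatially *independent* voxel noise it is strongly conservative
(a high peak essentially never sits in a 9-voxel connected component of
`p < 0.05` voxels). With spatially *smooth* noise it is anticonservative:
once any voxel crosses the corrected peak threshold, its correlated
neighbourhood almost automatically supplies the required extent, while
the number of independent opportunities for a high peak is not `N/k` but
the (larger) effective number of resolution elements. The test suite
measures this directly: under the default synthetic conditions
(no effect, 22 vs 22, noise smoothed to FWHM 2 voxels, 100 seeds) the
primary-tier family-wise significant-cluster rate exceeds the nominal
`alpha = 0.05`, and the corresponding calibration test is expected to
fail and documents the measured rate. Users applying the scheme to
smooth data should treat the tiered thresholds as approximate and lean
on the permutation validation.

**Permutation validation.** For any detected cluster,
`permutation_validate()` tests the absolute group difference in
per-subject cluster means under unrestricted label permutation,
exhaustively when `choose(n, n1)` fits in `n_perms` and by Monte Carlo
(identity permutation included in numerator and denominator, so `p > 0`)
otherwise. The scheme permutes cluster-mean values, not voxelwise maps:
it validates the magnitude of the regional difference, not the cluster
search itself.

**Laterality.** `laterality_compare()` reports the per-subject index
`(R − L)/(R + L)` on homologous region means, a within-group two-tailed
test of index ≠ 0, and a between-group two-tailed test. Degenerate
inputs (exactly symmetric volumes) are handled explicitly: zero spread
around a zero mean yields `t = 0, p = 1` rather than an error.

## 4. Gapping analysis

Given per-subject cluster means `x(1) ≤ … ≤ x(n)`, the lowest and
highest `floor(0.25 · n)` values are discarded (at `n = 22`: 5 from each
end, retaining 12 values and 11 gaps). The retained middle is where a
break between two latent subpopulations would appear; the trim protects
the statistic from ordinary outliers. `floor` is used because the
"middle 50%" of a sample not divisible by four must round somewhere;
either rounding retains the decisive boundary in the packaged fixture,
and `floor` keeps more data.

The statistic is the largest retained gap scaled to a dimensionless
quantity, with two conventions:

* `gap_ratio` — the largest gap divided by the **mean retained gap**.
  This ratio is exactly location- and scale-invariant (a property the
  test suite verifies), so the Monte-Carlo null can draw from standard
  distributions, and the resulting p-values are calibrated: feeding null
  samples through the full procedure yields uniform p-values (verified
  by a Kolmogorov–Smirnov property test). The choice of null family is
  nearly immaterial for this pivot. Recommended for fresh data.

* `standardized_gap` — the largest gap divided by the **25%-winsorized
  root-mean-square deviation** of the sample (winsorization count equal
  to the trim count, n-denominator), referred to the largest middle gap
  of *unit-scale* null samples: standard Gaussian, or a raw Student t
  with `df` degrees of freedom. Because the null samples are not
  themselves re-standardized, this convention is not a pivot and its
  null p-values are not uniform; but unlike any ratio statistic it is
  sensitive to the tail weight of the null family (a heavy-tailed null
  produces large unit-scale middle gaps more often, hence a larger p).
  It is the convention under which the packaged 22-value fixture
  reproduces its historical Monte-Carlo calibration (p ≈ 0.001 Gaussian,
  p ≈ 0.005 for t with df = 4 at 10,000 simulations — values the
  acceptance script recomputes), and it is provided for comparability
  with that analysis. No scale-invariant ratio statistic can separate
  the two null families this way, which is how the convention was
  identified; the distinction matters only for reproducing the packaged
  calibration, not for the subgroup labels, which depend on the gap
  location alone.

Numerical conventions: equal adjacent values produce a zero gap; if all
retained gaps are zero the statistic is undefined and reported as an
error. The subgroup boundary is the midpoint of the two values flanking
the maximal gap, and every subject is labelled by its side of that
boundary. The Monte-Carlo p is the plain proportion of simulated
statistics `≥` the observed one (no +1 correction; 10,000 simulations
express p = 0.001 exactly as a proportion), and the simulation seed is
mandatory in the pipeline configuration and logged.

## 5. Subgroup re-contrasts and symptom comparison

Each subgroup from the gap split is re-contrasted against **its own
matched controls** (via `pair_id`), with the full-cohort tier
configuration reused verbatim — including the search-volume sizes — so
that subgroup findings are corrected exactly as the original contrast
was. A subgroup equal to the full cohort reproduces the full-cohort
output identically (a consistency property in the test suite).

Symptom measures (IDS-SR total, anhedonia, sadness, psychomotor;
STAI-T) are compared between subgroups with two-tailed pooled-variance t
tests, available-case per measure (each measure's df reflects its own
non-missing ns), and a Bonferroni threshold of `alpha / n_measures`
(0.05/5 = 0.01 by default). A measure entirely missing in one subgroup
is reported as not computable rather than failing the batch.

## 6. The synthetic-data generator

`generate_cohort()` draws, per subject, independent Gaussian voxel noise
smoothed with an isotropic kernel (default FWHM 2 voxels) and rescaled
to the target voxel s.d., added to a constant baseline. Defaults:
32×32×32 grid at 2 mm (fast enough that the full pipeline and its
calibration tests run in minutes on one CPU), 22 matched pairs, baseline
FA 0.45 and voxel s.d. 0.05 — mid-range white-matter FA with a noise
level chosen for test power, since voxelwise FA variance in registered
cohorts is design-specific. Smoothness is the minimal realistic
structure of registered FA maps; the generator does not simulate raw
diffusion-weighted signal, gradient tables, registration error fields or
susceptibility artifacts.

Planted effects shift the carrier patients inside a region by
`effect_size · fa_sd` (whole-cohort effects) or `separation · fa_sd`
(sub-cohort effects, planting a bimodal structure); direction sets the
sign. The latent subgroup is a single random carrier subset of
`round(fraction · n_pairs)` patients shared by all sub-cohort effects.
Trait anxiety is drawn per latent subgroup (abnormal 61.80 ± 7.32,
normal 51.27 ± 8.96, controls 35 ± 8) and the depression measures from
distributions shared across subgroups, so a correct analysis should
separate subgroups on STAI-T but not on the IDS measures. At these
planted effect sizes the theoretical power of the STAI-T comparison at
the 0.01 Bonferroni level is only ≈ 0.58 for 10–12 subjects per
subgroup, so the property tests assert rates (STAI-T flagged in a clear
majority of replicates, IDS measures near the nominal rate), not
certainty.

What passing tests do and do not show: the generator reproduces the
*statistical structure* the pipeline assumes — smooth noise, matched
pairs, focal effects, a bimodal region, subgroup-linked anxiety. It does
not reproduce anatomy, registration error, scanner drift, or the true
spatial covariance of FA maps, so passing tests demonstrate correctness
of the statistics, not expected sensitivity on real data.

## 7. Reproducibility

All pipeline randomness flows from one top-level seed, expanded
deterministically into per-stage sub-seeds; stage outputs are cached on
disk and a JSON manifest records the configuration, seeds, input hashes,
timings and output paths. Re-running with an identical configuration
reproduces every output bit-exactly; deleting one stage's cache
recomputes only that stage and everything downstream.

The problem sizes used by the test suite — 16³ fields for the
connectivity oracle, 100 null cohorts at 32³ for the family-wise-error
measurement, 10,000-simulation gap calibrations over 5 seeds — were
chosen so the whole suite completes in a few minutes on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances.
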