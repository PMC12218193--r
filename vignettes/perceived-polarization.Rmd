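---
title: "Perceived polarization through group-specific lenses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceived polarization through group-specific lenses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenspol)
```

## The model

Respondents to a survey wave are points in the unit opinion cube
$[0,1]^m$, one axis per ordinal item mapped onto $[0,1]$. Each respondent
carries a group identity (e.g. the party they feel closest to; the
reserved label `"None"` marks nonpartisans) and a positive analysis
weight. The model's central assumption is that people do not measure
opinion differences neutrally: a perceiver in group $g$ re-represents the
opinion space in the basis of the principal components of the in-group
opinion covariance $\Sigma_g$, each axis scaled by the square root of its
eigenvalue. Measuring ordinary distance in that subjective basis is
equivalent to the Mahalanobis form in the original coordinates,

$$d(x_i, x_j \mid L_g)^2 = (x_i - x_j)^\top \Sigma_g^{-1} (x_i - x_j),$$

which is what `subjective_distance()` computes. Three consequences anchor
the implementation and its tests:

* an identity covariance gives the Euclidean (objective) distance;
* in one dimension the distance is $|\Delta|/\sigma_g$, the opinion
  difference normalized by the in-group standard deviation;
* replacing $\Sigma_g$ by $c\,\Sigma_g$ ($0 < c < 1$) multiplies every
  distance through that lens by exactly $1/\sqrt{c}$ — homogenization
  amplifies perceived distances.

Because the induced metric is $\Sigma_g^{-1} = (L L^\top)^{-1}$, it
depends only on the covariance: eigenvector sign flips, reordering of
equal eigenvalues, and any affine change of the opinion coordinates
(with the lens refitted on the transformed in-group) leave all subjective
distances unchanged. These invariances are verified in the test suite.

Mean perceived disagreement in a wave averages, over ordered pairs
$(i, j)$, $i \neq j$, the distance perceiver $i$ measures to $j$ through
the lens of $i$'s group, with pair weight $w_i w_j$ normalized over the
included pairs (`mean_disagreement()`). Perceived polarization between
waves $t_1$ and $t_2$ is
$P = \bar d(X_{t_2}, L_{t_2}) - \bar d(X_{t_1}, L_{t_1})$, and it
telescopes exactly into a pure part
$P_1 = \bar d(X_{t_2}, L_{t_1}) - \bar d(X_{t_1}, L_{t_1})$ (opinion
change under frozen lenses) and a lens-specific part
$P_2 = \bar d(X_{t_2}, L_{t_2}) - \bar d(X_{t_2}, L_{t_1})$ (the effect
of lens updating). `decompose()` implements the identity $P = P_1 + P_2$
by construction; `decompose_instantaneous()` covers the zero-delay
extreme in which each wave's lenses are refitted on that wave, so the
returned `P2` is the instantaneous lens-specific polarization $P_2^*$.
Only the two extremes of the lens-updating delay are modelled — frozen
lenses and instantaneous refitting; intermediate delays can be explored
by passing caller-supplied lens sets (`mode = "custom"`), but no delay
parameter is estimated.

## Parameters that matter

* **`ridge_epsilon`** (default `1e-6`, dimensionless): the covariance
  passed to `build_lens()` is regularized as
  $\Sigma + \varepsilon \cdot \overline{\mathrm{diag}(\Sigma)} \cdot I$
  before inversion. A perfectly unanimous group has a singular
  covariance and would perceive infinite distances; the ridge keeps them
  very large but finite. For an all-zero covariance the ridge falls back
  to the unit scale, so a unanimous group's perceived distances are
  $O(1/\sqrt{\varepsilon})$. With `ridge_epsilon = 0` a singular
  covariance is an error. Exactness-sensitive analyses (the contraction
  law, the self-calibration identity) should use `ridge_epsilon = 0` on
  nondegenerate data.
* **`min_group_size`** (default 3): a covariance of fewer than three
  points is rank-deficient by construction, so smaller groups fall back
  to the full-sample (`"None"`) lens; every fallback is recorded in the
  lens set and reported.
* **Weights**: the in-group covariance uses the frequency-weight
  convention — weights normalized to sum to the in-group count, unbiased
  $n_g - 1$ denominator — which is invariant to rescaling all weights
  and reduces to the ordinary unbiased covariance under equal weights.
  Pair weighting in $\bar d$ is the product $w_i w_j$ over ordered
  pairs, the standard U-statistic form. Whether the original empirical
  analyses weighted the covariance itself is not documented; weighting
  it is this package's choice, flagged here, and all identities tested
  hold under it.
* **Likert mapping**: the default 5-point scheme maps codes $1..k$ to an
  equally spaced grid $0, \tfrac{1}{k-1}, \dots, 1$. Equal spacing is
  the minimal assumption, and the subjective metric is invariant to any
  affine rescaling of an axis, so this choice does not affect perceived
  distances through fitted lenses (it does affect the objective
  Euclidean benchmark).

## Design choices where the design was open

* **Metric form.** The lens basis is documented as principal axes scaled
  by $\sqrt{\lambda_k}$; squaring to the metric gives
  $\Sigma^{-1}$. An alternative reading that scales axes by
  $\lambda_k$ would square to $\Sigma^{-2}$ and would *not* reproduce
  the 1-D $|\Delta|/\sigma$ normalization, so the $\sqrt{\lambda}$
  reading is adopted and the metric is implemented directly as the
  inverse regularized covariance rather than by inverting a basis
  matrix (numerically better behaved, and independent of eigenvector
  sign/order conventions).
* **Cross-wave lens application.** Waves are independent cross-sections,
  so lenses attach to *groups*, not persons: a wave-2 perceiver of group
  $g$ evaluated under wave-1 lenses uses group $g$'s wave-1 lens. A
  group present only in the later wave falls back to the earlier wave's
  full-sample lens, and the fallback is logged on the report.
* **Per-group restriction.** Per-group disagreement restricts the
  *perceiving* side to the group while the other side ranges over the
  whole wave — it is the average distance members of that group measure
  to everyone else. The population mean is exactly the pair-mass-weighted
  aggregation of the per-group means (tested to $10^{-10}$ relative).
* **Relative reporting.** Population quantities are reported relative to
  the population baseline $\bar d(t_1)$; per-group quantities relative
  to that group's own baseline $\bar d_g(t_1)$, since a percentage
  change experienced by a group is only meaningful against what that
  group perceived before.
* **Exact pairwise computation.** $\bar d$ is computed exactly in
  $O(n^2 m)$ via blockwise whitened cross-distances (the `block_size`
  argument only bounds memory; results are independent of it).
  Self-pairs are excluded structurally, not numerically. A seeded
  uniform pair-subsampling estimator (`subsample_pairs`) exists for very
  large waves and is off by default.
* **Numerical tolerances.** Covariances are symmetrized before
  eigendecomposition; asymmetry beyond $10^{-8}$ (relative) and negative
  eigenvalues beyond the same tolerance are errors rather than silently
  clipped. Lens JSON serialization writes 17 significant digits and wave
  CSVs print `%.17g`, read back through a correctly rounded parser, so
  both round-trips are bit-exact.

## What the synthetic generator emulates — and what it does not

`generate_wave()` draws each group's opinions from a Gaussian with the
specified mean and covariance, truncated to $[0,1]^m$ by rejection
(resampling until inside, bounded retries). Rejection avoids the
boundary atoms that clipping would create, which would distort fitted
covariances; for spreads well inside the cube the acceptance rate is
near 1 and sample moments match the specification (tested at
$n = 2000$: means within 3 standard errors, covariance entries within
15%). The canonical fixtures are:

* `two_lenses_spec()` — a "red" group with small isotropic covariance
  (`0.004 I`) and a "blue" group with a larger anisotropic one, means
  $(0.75, 0.75)$ vs $(0.35, 0.40)$: the narrow-lens group perceives the
  same cross-group gap as far while the wide-lens group perceives it as
  modest. Group sizes, spreads and separation were chosen once to give
  clearly separated groups with realistic within-group spread on a
  bounded opinion scale.
* `contraction_scenario()` — a two-wave design in which exactly one
  group's covariance is multiplied by `factor^2` with all means fixed:
  homogenization without opinion movement.

Real survey data differ from these draws in ways the generator does not
emulate: ordinal (not continuous) responses — covered separately by
`discretize_to_likert()` and the survey pipeline, which snap coordinates
to the Likert grid (each coordinate moves at most half a level spacing)
— plus nonresponse structure, weighting design effects, and panel
conditioning. Passing tests on synthetic data therefore validate the
*estimators and identities*, not distributional claims about any real
population.

## Two exact identities worth knowing

* **Self-calibration.** For a single unweighted group whose lens is
  fitted on the same sample with a zero ridge, the pair-weighted mean
  *squared* perceived distance is exactly $2m$ — an algebraic identity
  ($\sum_i \|y_i - \bar y\|^2 = (n-1)m$ after whitening by the unbiased
  sample covariance), not an asymptotic fact. A one-group society that
  keeps recalibrating its lens therefore perceives essentially constant
  disagreement no matter how its opinion variance drifts: perceived
  polarization between two such waves is statistically zero.
* **Contraction.** In the two-group contraction experiment the
  contracted group's instantaneous lens-specific polarization is large
  and positive while objective polarization is near zero — perceived
  polarization without opinion divergence. Note that pure polarization
  is *not* exactly zero there: redrawing the contracted group's opinions
  from a narrower distribution makes opinions objectively converge a
  little, so $P_1$ carries a small negative component (a few percent of
  $P_2^*$) on top of sampling noise. The construction's claim is that
  the lens effect dominates, not that the opinion effect vanishes.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the decomposition at
$n = 2000$ per group (20 replicates for the contraction experiment), the
self-calibration check at $n = 5000$ with $m \in \{1, 2, 3\}$, and the
metric-level identities on hundreds of random covariances in 2-5
dimensions — sizes at which pairwise computation is exact and sampling
bands (3 standard errors) are tight relative to the effects measured.

## Known limitations

* Lenses are always the PCA-of-covariance construction; no shrinkage or
  sparse covariance estimation, and no lens models driven by anything
  other than in-group opinion variation (no affect, no segregation, no
  cognitive-bias mechanisms).
* Waves are treated as independent cross-sections; respondents are never
  linked across waves.
* No inferential uncertainty is attached to $P$, $P_1$, $P_2$ — they are
  point functionals of the observed waves.
* Groups below the minimum size borrow the population lens, which
  understates their homogeneity if they are genuinely tight-knit but
  tiny.
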