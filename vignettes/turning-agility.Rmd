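---
title: "Estimating turning agility in bipedal dinosaurs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating turning agility in bipedal dinosaurs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theroturn)
```

## The model

A turning animal imparts angular acceleration `alpha = tau / I_y`: torque
from its locomotor muscles divided by the yaw mass moment of inertia of
whatever it is rotating.  For extinct bipeds neither torque nor inertia is
observable directly, so `theroturn` estimates both from what fossils
preserve — body outlines, ilium outlines, and tail depths — and compares
*relative* agility between taxa rather than absolute performance.

### Bodies as superelliptical frustum chains

A digitized body is a `station_series`: dorsal and ventral outline heights
and half-widths at successive anteroposterior stations, with an anatomical
region (head/neck/trunk/tail) per inter-station interval.  Coordinates are
metres; `x` runs from the rostrum tip, `y` from the ventral-most trunk
point, and the body is assumed bilaterally symmetrical about `z = 0`.

Each interval becomes a frustum whose faces are superellipses
`|y/a|^k + |z/b|^k = 1`.  The exponent `k` controls the cross-sectional
shape: `k = 2` is an ellipse, larger `k` approaches a rounded rectangle.
Terrestrial vertebrate cross-sections fall between `k = 2` and `2.5`, and
the package default is 2.3.  The face area is `C(k) (2 r_DV)(2 r_LM)`,
where the constant is available in two flavours:

* `closed_form` (default): the exact identity
  `C(k) = Gamma(1 + 1/k)^2 / Gamma(1 + 2/k)`;
* `table`: the four historically tabulated constants
  (0.7854, 0.8227, 0.8324, 0.8408 at k = 2, 2.3, 2.4, 2.5), linearly
  interpolated.  These derive from polynomial regression fits and sit
  0.1–0.5% below the exact values for `k > 2`; both are offered because
  published mass tables were built with them.  At `k = 2` the two agree
  exactly (`pi/4`).

Frustum volume uses the truncated-cone formula on face areas, which is
exact for any cross-section scaled linearly between faces.  Masses apply
regional densities (defaults: head 990 kg/m³, an averaged value accounting
for cranial air spaces; neck 930; trunk 740, reflecting lungs and air
sacs; tail and legs at muscle density 1,060).  Density defaults are a
single place to change as anatomical data improve.

### Centres of mass

The anteroposterior centroid of a frustum uses the circular-frustum
formula with a single effective radius per face, the geometric mean
`sqrt(r_DV r_LM)`; this preserves face areas and is exact for circular
faces.  The dorsoventral centroid is the four-point average of the
digitized face extrema — the approximation that published whole-body
tables actually apply.  A taper-weighted alternative exists in the
literature, but its printed parenthesization is dimensionally suspect
(a numerator quadratic in heights over a denominator linear in heights
yields a height only under one specific reading); the most literal
reading is implemented behind `method = "taper_weighted"` for comparison
and excluded from all defaults.  Likewise the coarse shortcut of placing
each frustum's centroid at its larger face (`method = "larger_face"`) is
retained purely as a validation mode: on long bodies it changes the body
COM by a fraction of a millimetre, but there is no reason to prefer it.

The body COM is the mass-weighted mean of frustum centroids.  For the
en-pointe scenario the collective COM of body plus swing leg is the
mass-weighted mean in the horizontal plane, and lies between the two.

### Yaw inertia

For the planted-feet scenario,
`I_y = sum_i C rho_i l_i rbar_DV rbar_LM^3 + m_i r_i^2`:
a local slab term (the yaw inertia of a superelliptical slab about its own
vertical axis, with face-averaged radii) plus the parallel-axis transfer
to the body's COM.  The per-frustum length term `m_i l_i^2 / 12` is
omitted by default, following the published slicing procedure: with 60+
slices it is O(1/n²) relative and the distributed-mass behaviour of the
whole body emerges from the parallel-axis sum.  The convergence tests
quantify this (a 500-slice cylinder recovers `m(r^2/4 + l^2/12)` to
0.1%); `include_length_term = TRUE` adds it back for coarse chains.

The swing leg, straightened and rotating about its own long axis,
contributes the polar slab sum
`sum_i C rho_i l_i (rbar_AP rbar_LM^3 + rbar_LM rbar_AP^3)`, and the
en-pointe inertia composes the four parallel-axis terms about the
collective COM.  By construction the result can never be smaller than the
body's own `I_y`; published tables that violate this are flagged by the
validator rather than accepted or corrected.

Graphical double integration (each segment an extruded cylinder with its
anterior face's area) is included as a cross-check only: it converges to
the frustum result on tubular bodies and overestimates strongly tapered
parts (anterior-face bias) at coarse slicing — the behaviour the tests
assert.

### Tail modifiers

Two sensitivity handles address the most uncertain soft tissue: tail
half-widths can be multiplied by a factor (1.4 reproduces the
lateral bulge measured on adult *Alligator* tails, an upper bound for
tail mass), and tail depths scaled about the section midline (±10%
probes chevron articulation uncertainty).  The modifier applies to every
station bounding a tail interval, including the station shared with the
trunk: a constant-section tail then changes volume by exactly the width
factor, at the cost of also widening the posterior face of the last trunk
frustum.  The alternative (leaving the shared station untouched) would
keep the trunk bit-identical but break the exact-factor property; we
chose the exact tail semantics and document the boundary effect, which is
one frustum out of 60+.

### Muscle proxies and agility indices

Lateral ilium area — the whole lateral surface dorsal to the
supra-acetabular crest, since individual scars are often ambiguous — is a
shoelace polygon area; self-intersecting outlines are rejected.  The CFL
(m. caudofemoralis longus) cross-section is one semicircle of radius half
the hypaxial depth minus one centrum section per side; the depth
sensitivity scales the centrum with the same linear factor, so a ±10%
depth change yields exactly +21%/−19% area changes.  Whether published
comparisons subtract the centrum once per side or in total is not
recorded; the per-side convention is the package's documented choice and
the `centrum_area` argument makes the other trivially available.  CFL
areas are computed and reported but kept out of the regression responses
(the preserved sample is too small for comparative fits).

`Agility_force = A_ilium / I_y` and
`Agility_moment = tau_rel / I_y` with
`tau_rel = (m^{1/3} / 100) × A_ilium × 20 N/cm²`.  The `m^{1/3}` factor
carries isometric moment-arm scaling; 20 N/cm² is a sub-maximal concentric
specific tension; the divisor 100 is an arbitrary linear adjustment.  The
tests assert that neither constant affects between-taxon ratios, which is
the property that makes the indices comparative rather than physical.
Under pure geometric scaling (`A ∝ s²`, `m ∝ s³`, `I_y ∝ s⁵`) the
log-log slopes against mass are exactly −1 (force) and −2/3 (moment);
the scaling-series generator reproduces both to 1e-6, bracketing the
slopes fitted to real theropod samples (−1.01/−1.02 and −0.71).

## Phylogenetic statistics

Trait covariance follows Brownian motion on a time-calibrated tree:
`V[i, j]` is the shared root-to-MRCA path length.  Pagel's λ multiplies
off-diagonals, leaving the diagonal intact, and is estimated by profiling
the ML likelihood over [0, 1] (scalar optimization, tolerance 1e-8, with
boundary checks so exact 0/1 are returned).

**Calibration.**  Published analyses use a two-pass "equal-rate-sharing"
calibration whose internals are specified elsewhere; rather than
reconstruct an algorithm from memory, the package ships a deliberately
simple, fully documented scheme: tips sit at their first-appearance dates;
each node at `max(oldest descendant FAD + padding, oldest child age +
epsilon)` (defaults: padding 1 Myr, epsilon `max(0.001 × FAD span, 1e-3)`
Myr).  Same-species polytomies are resolved arbitrarily with
epsilon-length branches, preserving near-equal pairwise covariances — the
hard-polytomy semantics — while keeping `V` invertible.  A pre-calibrated
Newick tree bypasses all of this, which is the recommended route when a
published calibration exists.

**PGLS.**  `beta = (X' V^{-1} X)^{-1} X' V^{-1} y`, fitted by whitening
with the Cholesky factor of `V(λ)`.  Both response and covariate are on
log10 scale (log10 agility against log10 mass): published slopes near −1
and intercepts near 3 are only dimensionally sensible on log–log axes.
Two R² flavours are reported and labelled — `r_squared_gls` (on the
whitened scale, against a GLS intercept-only null) and `r_squared_raw`
(ordinary scale) — because published tables mix the two conventions
without saying which is which.  Per-tip confidence and prediction
intervals use the same covariance; the prediction variance at tip *i*
adds `sigma² V[i, i]`, and tips at or above the upper prediction limit
are flagged (the pattern of interest when one clade outperforms the
regression).

**Grade-wise ANCOVA.**  Each comparison fits a reduced and a full grade
assignment (grades differ in intercept by default; optionally in slope
too, since the published formulation does not say whether slopes were
freed — both are options) by GLS under one shared λ, estimated once on
the pooled single-grade model so nested models are compared like for
like.  `F = ((RSS_red − RSS_full)/Δdf) / (RSS_full/df_full)` on whitened
residuals.  The default comparison ladder is: among the three groups
(adult tyrannosaurids, juvenile tyrannosaurids, others); juveniles versus
adults (others kept as their own grade); all tyrannosaurids versus
others.  Conditional error probabilities
`alpha(p) = (1 + [−e p ln p]^{−1})^{−1}` accompany every p-value; no
other multiple-testing adjustment is applied, matching the analysis the
indices were designed for.

**Calibration of the F-test.**  With the true (generating) λ the nested
GLS F-test is exact: under a simulated null with randomized groups its
empirical type-I error at nominal 0.05 is 0.053 (n = 20 tips, 1,000
replicates).  Plugging in the shared ML λ̂ instead makes the test
finite-sample *conservative* at this sample size (empirical rate ≈ 0.02),
never anticonservative — rejections lose no credibility, but borderline
effects may be missed on small trees.  The acceptance suite therefore
calibrates the test under the known generating λ and separately asserts
that the ML plug-in does not inflate the error rate.

## What the synthetic generator emulates — and what it does not

`make_theropod_body()` produces smooth tapering head/neck/trunk/tail
outlines (60+ stations), a straightened leg with a constant mediolateral
radius, and a synthetic ilium area defined as a fixed fraction (default
0.08) of trunk lateral area so scaling laws hold exactly.  The default
plan is a large tyrannosaurid-like biped: total length ≈ 11.3 m, axial
mass ≈ 8.7 t (plus two ≈ 1.0 t legs), COM ≈ 4.6 m from the rostrum, tail
≈ 12% of axial mass.  Under these defaults a ±10% tail-depth change moves
total mass by ≈ 1.3% and `I_y` by ≈ 3.7%, and the 1.4× tail width adds
≈ 5.4% mass — inside the envelopes reported for real digitized theropods
(masses within 3%, `I_y` within 4%, widened-tail masses +5–7%).  The
en-pointe inertia exceeds the planted inertia by ≈ 1.5%, within the
published 0.55–5.3% range.

`simulate_traits()` defaults (`rate = 1e-5`, `x_rate = 0.005` per Myr on
100-Myr-deep trees) produce residual scatter of ≈ 0.03 log10 units around
the regression and a log10-mass spread of about two thirds of a decade —
the magnitudes seen in the real specimen tables.

What the generator does **not** emulate: real digitization error
structure (correlated view-reconciliation errors, not i.i.d. jitter),
asymmetric or flexed postures, forelimbs, dorsal fins, pneumatic cavities
beyond the regional densities, or anatomically faithful proportions of
any particular taxon.  Passing tests on synthetic bodies therefore
validate the *mathematics* — convergence to closed forms, scaling laws,
statistical calibration — not the anatomical fidelity of any
reconstruction.

## Numerical choices and degenerate inputs

* Station `x` must be strictly increasing; violations are reported with
  the offending station index.  Fewer than 60 intervals warns (files) but
  does not error — the 60+ guideline is about precision, not validity.
* Zero-area faces are legal (tail tips, leg ends); a frustum with *both*
  faces empty is a degeneracy and errors in centroid computation.
* λ optimization: bounded scalar search, tolerance 1e-8, with explicit
  endpoint evaluation so boundary maxima are exact.
* Rounding for table reproduction is R's default half-even rounding at
  the printed number of decimals.
* The specimen-table validator accepts a printed cell when it is within
  1.5 units of the last printed decimal of the recomputed value — half a
  unit for the cell's own rounding plus headroom for the rounding already
  present in its printed inputs.  Everything beyond that is flagged, and
  known-inconsistent published cells (including two rows whose
  body-plus-leg inertia is *less* than the body's, which the
  parallel-axis theorem forbids) are flagged, never corrected.

## Problem sizes used in the tests

Convergence oracles run at 200–500 slices (errors fall as O(1/n²); the
0.5% acceptance bands are met from ~150 slices).  λ recovery uses 200
replicates on a 50-tip tree; F-test calibration 1,000 replicates on a
20-tip tree; PGLS slope coverage 300 replicates on 40 tips.  These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands
while keeping the full suite under a minute of compute.

## Known limitations

* The agility indices are comparative, not absolute: no moment arms,
  muscle architecture (pennation, fascicle length), or activation are
  modelled, and CFL sections ignore the intermuscular septum.
* Frustum slicing assumes bilateral symmetry and superelliptic sections;
  strongly flared ribcages are only as well represented as their
  digitized extrema.
* The simplified calibrator is not the published two-pass algorithm;
  supply a pre-calibrated tree to reproduce a published covariance
  exactly.
* The grade F-test shares one λ per comparison; with very small samples
  the ML plug-in is conservative (see above).
* Roll and pitch inertia, forelimbs, and absolute turning dynamics are
  out of scope.
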