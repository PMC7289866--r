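---
title: "Methods: snap biomechanics, energy inversion, and defence statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snap biomechanics, energy inversion, and defence statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapmech)
```

## The system

Soldiers of some soil-dwelling termites defend their galleries with a
power-amplified mandible strike in which spring and striking tool are the
same appendage: the twisted left mandible. The right mandible presses
against the left for a few hundred milliseconds (the loading phase), elastic
energy accumulates in a functional joint of the left mandible, and when the
surfaces slip past each other the anterior part of the left mandible rotates
about that joint in tens of microseconds — one of the fastest movements
known in animals. snapmech implements the quantitative layer of such a
study: how to turn masses, lengths, angular measurements, digitized video
tracks and fight tallies into velocities, forces, energies and defence
probabilities.

## The inertia model

The anterior rotating part (mass $M_A$, length $L_A$) is too irregular for a
textbook inertia formula, so its moment of inertia about the pivot is
written as

$$I_A = K\,M_A\,L_A^2,$$

with a dimensionless constant $K$ estimated from two cut subsections: a
distal piece A1 and a proximal piece A2 with masses $M_{A1}$, $M_{A2}$
($M_A = M_{A1} + M_{A2}$). The centre of mass sits at

$$L_{COM} = \frac{\tfrac14 L_A M_{A2} + \tfrac34 L_A M_{A1}}{M_A},$$

and the constant is the two-point-mass sum

$$K = \frac{M_{A2}}{M_A}\left(\frac{L_{COM}}{2L_A}\right)^2
    + \frac{M_{A1}}{M_A}\left(\frac{L_{COM}+L_A}{2L_A}\right)^2 .$$

Two remarks that matter for maintenance:

* **The lever arms are $L_{COM}/2$ and $(L_{COM}+L_A)/2$, not the
  subsection centroids $L_A/4$ and $3L_A/4$.** A conventional two-point
  model would place each subsection's mass at its own centroid. We
  implement the formula exactly as published and do not "correct" it: the
  package's job is to reproduce the published estimator, and the choice
  only shifts $K$ within its admissible band. The discrepancy is confined
  to `compute_k()` and documented here.
* With `l_com` derived from `compute_lcom()`, $K$ is bounded in
  $[1/64, 49/64]$ (all mass proximal / all mass distal) and is strictly
  increasing in the distal mass fraction; both facts are asserted by
  property tests over a 1,000-point grid.

Subsection masses at the sub-microgram scale are noisy to weigh, so they are
routinely pooled across many cut mandibles; the `mandible_morphometry`
object carries a `provenance` flag (`"individual"` or `"cohort-mean"`) so a
report can say which was used. Degenerate splits ($M_{A1}=0$ or $M_{A2}=0$)
are legal limits; both zero is an error.

The termite body is a uniform cylinder about its centre of mass,
$I_T = M_T L_T^2/12$.

## Snap kinematics

From an ultrahigh-speed recording the observables are the peak angular
velocity $\omega_A$ and the time $t_A$ to reach it. The chain is

$$V_{MT} = L_A\omega_A,\qquad \alpha_A = \omega_A/t_A,\qquad
  F_A = \tfrac13 M_A L_A \alpha_A,\qquad E_A = \tfrac12 I_A\omega_A^2 .$$

Defaults and conventions:

* $t_A$ defaults to 8.68 µs — four inter-frame intervals at 460,830 fps —
  and is configurable per event (`peak_from_series()` extracts
  $\omega_A, t_A$ from a digitized series, ties broken by earliest time).
* Body-weight ratios use $g = 9.81\ \mathrm{m/s^2}$ (standard gravity; the
  choice is stated because the headline numbers are quoted in units of
  $10^3$ BW).
* Internal units are strict SI. The reporting layer converts to the mixed
  units conventional in this literature (µg, mg, mm, µs, µJ, mN) through
  named converters, and a unit registry ties every reported field to the
  converter applied — audited by a test.
* Reports round to one decimal, half away from zero, via
  `round_half_up()`; internal values are never rounded.

**Mean-of-events vs event-at-means.** $F_A$ and $E_A$ are nonlinear in
$\omega_A$, so the mean of per-event values differs from the value computed
at mean inputs whenever inputs vary (Jensen's inequality). Cohort tables in
this literature mix the two, which makes naive cross-checks fail by design.
The report therefore prints both, with a caveat line, and a regression test
pins the behaviour.

## Ball-strike inversion

In a ball-strike experiment the soldier snaps at a 2.25 mg metal ball;
ball and termite fly apart and the termite may spin. Assuming no loss to air
resistance, friction, or ball rotation, energy conservation gives

$$E_A = \tfrac12 M_B V_B^2 + \tfrac12 M_T V_T^2 + \tfrac12 I_T\omega_T^2,
\qquad
V_{MT} = \sqrt{\frac{2E_A}{M_A K}} .$$

`event_kinetic_energy()` implements the bookkeeping (an optional solid-
sphere ball-spin term is available for sensitivity analysis, off by default
because the published estimate deliberately omits it, making the velocity a
conservative lower bound). `invert_tip_velocity()` is the exact algebraic
inverse of the energy relation, which the tests exploit as a round-trip
property. The implied force assumes the strike happened at peak velocity
$t_A$ after initiation; the length cancels: $F_A = M_A V_{MT}/(3 t_A)$.

The measurement layer (`track_processing`) converts digitized pixel
trajectories: scale from a reference object of known size (the petri-dish
diameter), speeds from the forward difference over the first post-impact
inter-frame interval (no smoothing — none is described for the source
workflow, and adding any would bias the first-interval speed), rotation
rates from counted turns, and deflection angles from the body axis via the
normalized dot product. Image coordinates are y-down; the side label
("left"/"right", left positive) is computed after flipping to mathematical
y-up so that "left of the body axis" matches the anatomical claim. The
`y_down` flag exists because hand-constructed vectors in examples are
usually written y-up.

## Strike-angle precision

Precision is operationalised as the spread of ball deflection angles:
a precise weapon hits in a particular zone, so the angles should look like
a unimodal, roughly normal sample rather than a uniform scatter.
`strike_angle_summary()` reports n, mean, sample sd, range, and a
Shapiro–Wilk test (Royston's algorithm via `stats::shapiro.test`). Angles
are summarised as absolute deviation from the body axis in [0°, 180°]
(signed values are retained by the track layer for plotting); ordinary
rather than circular statistics are used deliberately, matching the
published analysis — defensible because the angles concentrate far from the
0°/360° wrap.

## Defence statistics

Fight trials (four termites vs four ants of one species per trial, six
trials per species) are pooled per species before analysis. Rates:
attack rate = attacks/encounters; hitting probability = hits/snaps; killing
probability = kills/hits (undefined and flagged when hits = 0). Pairwise
species comparisons use the two-sided Fisher exact test with the
point-probability definition (sum of all tables with hypergeometric
probability ≤ the observed one, with a 1e-7 relative tolerance for
floating ties — the convention of standard statistical environments, since
sidedness was not stated in the source analysis). Bonferroni correction is
applied within one outcome family (all pairs for one panel, m = 6 for four
species), not across outcomes, matching per-panel letter displays. The
compact letter display assigns letters as maximal cliques of the
"not significantly different at α = 0.05" graph.

One provenance note: the published attack counts for the second generalist
ant are 18 attacks in 107 encounters, which is 16.8%, while the prose prints
17.1%. The package reports the computed 16.8%; the printed value is treated
as a typographical inconsistency, not a target.

## The synthetic-data generator

No raw recordings are distributable, so `simulation_config()` +
`gen_*()` forward-simulate all four input tables with known ground truth.
The defaults are the stated world of the study cohort and are not tuning
knobs:

* morphometry: truncated normal (lower bound 0) per-individual draws,
  means 3.22 mg body mass, 6.06 mm body length, 1.06 mm anterior mandible
  length; sds (0.12 mg, 0.075 mm, 0.0375 mm) set to one quarter of the
  published min–max ranges, the usual range/4 heuristic for a normal-ish
  cohort of this size. Subsection masses default to 8.5/19.5 µg: the split
  is not published, so it was chosen once to reproduce the published cohort
  inertia ($K \approx 0.177$, $I_A \approx 0.56\times10^{-14}$ kg m²)
  and documented here.
* ultrahigh-speed $\omega_A$: lognormal (positivity plus the right skew
  implied by the published min/mean/max asymmetry), mean 12.8×10⁴ rad/s,
  sd 1.3×10⁴ (range/4).
* ball-strike events: a true $V_{MT}$ is drawn lognormal (mean 60.4, sd
  12.0 m/s), converted to a true $E_A$ through the cohort inertia model,
  and partitioned into (ball translation, termite translation, termite
  rotation) by a Dirichlet draw with expected shares (0.65, 0.30, 0.05)
  and concentration 40 — the simplest simplex-valued family with a
  controllable spread; no partition distribution is published. Observables
  are then exact inversions of the three energy shares.
* measurement noise: multiplicative Gaussian with cv 0.05 on the three
  tracked velocities only. Masses are weighed, velocities are tracked, and
  tracking dominates the error budget, so masses get no noise.
* strike angles: Normal(52.9°, 22.7°²) truncated to [0°, 180°].
* defence trials: encounters and snaps are Poisson per trial (encounter
  means = published totals/6; snaps default to Poisson(5) per trial since
  no snap totals are published), then attacks/hits/kills/immobilisations
  are binomial thinnings at the configured true rates, so the count
  invariants hold by construction.

Inter-individual covariance of mass, length and angular velocity is
unknown and assumed zero; consequently a green parameter-recovery test
establishes correctness of the inversion chain under independent noise, not
robustness to correlated measurement error, digitization bias, or energy
losses the conservation model excludes. Determinism: every generator seeds
R's Mersenne-Twister (inversion for normals) from `seed` plus a fixed
per-generator offset, giving byte-identical tables for a fixed seed.

## Numerical choices

* Algebraic identity tests use relative tolerance 1e-9; the Fisher
  implementation is compared to an exhaustive enumeration oracle at 1e-12.
* `round_half_up()` adds a 1e-9 relative epsilon before flooring to guard
  binary representations of exact halves (111.05 must print as 111.1).
* Truncated normals are drawn by CDF inversion (not rejection), so a draw
  consumes exactly one uniform and the stream stays aligned across
  configurations.
* Division guards: zero denominators (t_A, durations, encounters, snaps,
  hits) raise informative errors rather than returning Inf/NaN; the kill
  probability is flagged undefined rather than erroring because a species
  with zero hits is a legitimate assay outcome.

## Limitations

* The energy inversion inherits every assumption of the conservation
  model: no restitution/collision dynamics, no ball spin, no aerodynamic
  or frictional loss. Reconstructed velocities are lower bounds.
* The inertia constant comes from the published two-subsection estimator
  only; no imagery- or shape-based estimation is attempted.
* Circular statistics are intentionally not used for angles.
* The defence generator models counts as independent Poisson/binomial
  draws; real fights have within-trial dependence the model ignores.
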