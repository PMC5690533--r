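---
title: "Modeling rounded MLC leaf ends and the dynamic leaf gap"
author: "leafgap"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgap)
```

## The problem

Fixed-jaw ("beam modulator") linacs shape every field with the multileaf
collimator alone: the field-defining diaphragms do not follow the leaves.
During arc delivery the opposing leaf tips must keep a minimum dynamic leaf
gap (DLG) — on the machine modeled here, 1 mm at the MLC plane, 39 cm from
the source — and, with no backup jaw behind it, that gap irradiates tissue
outside the planned field at every control point. Treatment planning
systems describe the rounded leaf tip with two tunable quantities: the tip
radius $r$ of the circular arc machined into the leaf end, and the *MLC
offset table* — the difference between the light-field edge (tangent
projection of the tip) and the radiation edge (50% transmission point),
tabulated per leaf position at 100 cm SAD. This package implements the
full loop used to tune those parameters against measured leaf-gap doses:
forward transmission model, point-dose engine, film and gamma QA tools,
and the two-stage grid-search optimizer.

## Ray-traced tip transmission

A leaf is a tungsten slab of thickness $T$ = 7.5 cm centered on the MLC
plane, terminated by a circular arc of radius $r > T/2$ whose center sits
at mid-thickness. For a point source, the intersection of a diverging ray
with the leaf is the union of two analytic intervals — the line–circle
chord through the tip and the line–slab chord of the leaf body behind the
circle center — so the path length $L$ is exact, continuous in the ray
position, zero in the open field, and tends to $T/\cos\theta$ deep under
the leaf. Transmission is $e^{-\mu_\mathrm{eff} L}$, with
$\mu_\mathrm{eff} = -\ln(T_\mathrm{full})/T$ derived from a configured
full-leaf transmission fraction (defaults 0.02 at 6 MV, 0.025 at 10 MV);
the alloy composition never enters. The radiation edge is found by
bisection of the monotone transmission profile (tolerance $10^{-4}$ cm),
and the offset table is `light edge − radiation edge`, non-negative for a
rounded tip, about 0.043–0.045 cm across the bank at $r = 13$ cm.

Leaf placement is the one genuinely open modeling choice. Planned
positions are radiation-field edges; applying the interpolated table
offset plus the global shift retracts the modeled physical tip into the
aperture, which is the only orientation consistent with the observed
behavior that a *positive* offset shift *lowers* computed gap doses. The
retracted command is then transported **linearly along the leaf rail** to
the MLC plane (tip-circle center = scaled command − $r$), the way a leaf
drive actually positions a tip. Off-axis, this linear transport lags the
diverging tangent projection by $r(\sqrt{1+t^2}-1)$ per side ($t$ = ray
slope), so a parked gap effectively narrows away from the axis. That
single geometric term is what makes the central parked gap read higher
than the off-axis gaps, as every dosimeter in the leaf-gap experiment
shows. A divergence-corrected (tangent-consistent) parking was tried
first and rejected: it cancels the effect exactly and predicts identical
gap doses everywhere.

## The dose engine

The engine is deliberately simple: dose at a point is

$$D = \mathrm{MU}\cdot k \left[(1-s)\,(F \ast G_\sigma) + s\,S\right]$$

with $F$ the primary transmission map, $G_\sigma$ a Gaussian kernel
($\sigma$ = 0.35 cm at isocenter), $s$ a constant scatter fraction
(default 0.08), $S$ the total fluence area over the 10.4 cm
reference-field area, and $k$ a single per-energy output constant
calibrated so the 2.4 cm square at 200 MU reproduces the measured
in-field dose (131.9 cGy at 6 MV, 145.0 cGy at 10 MV, 10 cm depth). Depth
dose, TMR, and output factors are absorbed into $k$; $\sigma$ and $s$ are
declared fit parameters, not physics. This is *not* a
convolution–superposition engine — everything of interest here is a
relative gap dose or a ratio, and those live in the fluence model.

At collimator 0° the convolution is evaluated separably and nearly
exactly: leaf pairs sharing an aperture are grouped, each group
contributes a fine 1-D transmission profile (0.002 cm sampling) convolved
with the kernel along $x$, weighted by the analytic Gaussian mass over
the group's $y$-extent. The profile step matters: the tip penumbra is
only ≈ 0.04 cm wide at isocenter, and a 0.02 cm step aliases the
grid-search objectives visibly. Opposing banks multiply, with the
combined path capped at one slab traversal (physical leaves cannot
stack), so the leakage floor under both banks is the single-leaf
transmission.

## The leaf-gap experiment

Three control points, 200 MU each: a 2.4 cm open square placed left of
axis, on axis, and right of axis, with all other leaf pairs closed to the
minimum dynamic gap parked at the square's position. Gap doses A, B, C
are read on the parked-gap line 3 cm above the square; in-field doses D,
E, F at the square centers. Each point receives only its own control
point's delivery — the reading of "200 MU per control point" adopted
here.

The off-axis displacement of the outer control points is shown only
graphically in the source experiment; the package default is ±5.6 cm,
calibrated once so the modeled center/off-axis contrast at the final
published parameters (shift +0.1 cm, $r$ = 13 cm) matches the benchmark
ion-chamber measurement (model 1.40 vs measured 1.43 at 6 MV). At ±2.9 cm
— the minimal spacing that clears the squares — the tangent-lag mechanism
yields a contrast of only 1.10, too weak for a 0.01 cm offset scan to
discriminate.

## Two-stage optimization

Stage 1 scans the global offset shift in 0.01 cm steps, minimizing the
summed absolute mismatch of the center/off-axis dose ratio across
energies; stage 2 scans the tip radius in 0.1 cm steps at fixed shift,
minimizing the summed absolute dose mismatch at A, B, C. Energies are
weighted equally (no weighting is prescribed anywhere); one shift and one
radius are shared by all energies, so conflicting measurements end in a
compromise with opposite-signed residuals. The ion-chamber column is the
benchmark when several dosimeters are present; the off-axis reference is
the mean of A and C by default (comparison against A alone is selectable,
since published off-axis discrepancies appear to use it).

Grid search keeps the procedure deterministic and mirrors the manual
0.01 cm increments it automates. Two numerical safeguards were needed:

* **Presearch.** The ratio is not globally monotone in the shift — the
  central gap reaches closure near +0.08 cm and the ratio peaks — so the
  ratio scan can have two crossings for one target and, started at a
  wrong radius, the alternation can strand. A deterministic coarse scan
  of the stage-2 objective (every 2nd shift step × 1 cm radius steps)
  places the alternation in the right basin first.
* **Candidate set.** Each round, stage 2 evaluates the best few local
  minima of the stage-1 scan plus the incumbent shift and its one-step
  neighbours; an accepted round therefore never regresses the dose
  match, and the iteration can walk the diagonal shift–radius trade-off
  valley. Iteration stops when the joint objective improves by less than
  $10^{-3}$ cGy (20 rounds maximum), returning the best visited point
  and a convergence flag.

One qualitative disagreement with the source system is documented rather
than patched: in this engine the center/off-axis ratio *rises* with
positive shift until the off-axis gaps saturate, whereas the tuned
commercial system reported it falling. The commercial dose engine's
internal rounded-leaf handling is proprietary and its ratio numerics are
explicitly out of scope here; what the optimizer needs — strict local
monotonicity around the operating point — holds, and the converged ratio
at (+0.1 cm, 13 cm) agrees with the system's own calculated value (1.10).

## Film and gamma QA

Film dosimetry follows the classical logarithmic calibration
$D = a\ln(\mathrm{OD}) + b$, least-squares fit to chamber-verified doses;
the bundled reference curve is $D = 65.284\ln(\mathrm{OD}) + 88.598$ cGy.
OD is computed per pixel against the film's own unexposed grey level
(`log10(unexposed/pixel)`), profiles are band-averaged (±4 cm default),
and the synthetic film fixture inverts the calibration onto a simulated
three-gap dose map with 16-bit quantization (8-bit supported, documented
as the fidelity hazard of a JPEG-era workflow). The curve is not valid
near zero dose, so fixture doses under 0.05 cGy render as unexposed film.

The gamma index uses global normalization (dose difference as a fraction
of the reference maximum), an inclusion threshold computed on the
reference grid only, a search radius of 3 × DTA, and sub-grid refinement
by bilinear upsampling of the evaluated grid (factor 3). Upsampling was
chosen over local parabolic interpolation because it is exactly testable:
at factor 1 the search reproduces an exhaustive $O(N^2)$ brute-force
oracle node for node, and refinement can only lower gamma. Both 5% and
10% thresholds are in routine use; none is a silent default. The exact
Wilcoxon signed-rank test enumerates the full $2^n$ sign-assignment null
($n \le 20$, zeros dropped, mid-ranks for ties, two-sided tail doubled
and capped at 1) — on six uniformly improved paired scores it gives
$p = 2/64 = 0.03125$.

## Square-field arcs

`simulate_square_arc()` composes a planar dose for a 360° arc of a fixed
square aperture with the parked gap in the field and the collimator
rotated 20° to spread interleaf effects: the fluence is evaluated in
rotated coordinates per gantry angle (2° default step), averaged,
blurred, and scaled. Phantom curvature, detector cylindricity, and
angular depth variation are all collapsed into the output constant. The
composite converges to better than 1% RMS when the angular step is
halved, and the gap's relative out-of-field contribution grows as the
field shrinks — the reason small square arcs are the sensitive QA probe
for rounded-leaf-end mistuning.

## What the synthetic data does and does not show

`make_measurements()` replays the forward model at chosen ground-truth
parameters plus i.i.d. Gaussian noise (default sd 0.5 cGy, a plausible
micro-chamber repeatability; no error model is published). Passing
recovery tests therefore demonstrates that the *procedure* identifies the
parameters of *this* transmission model under realistic noise — it cannot
certify agreement with any commercial engine's internals, detector volume
averaging, film energy response, or interleaf (tongue-and-groove)
leakage, all of which are out of scope. Problem sizes used in the test
suite: 0.002 cm transmission profiles (0.004 cm in the 20-replicate noisy
recovery), shift grid −0.12…0.16 cm, radius grid 11…15 cm, 20×20 gamma
grids, 24–72 arc angles.

## Known limitations

* Leaf sides, tongue-and-groove leakage, and interdigitation constraints
  are not modeled; validation plans rotate the collimator precisely to
  minimize them.
* The scatter model is a single aperture-area term; out-of-field scatter
  gradients are not captured.
* One offset table serves all energies, as in the planning system being
  emulated; per-energy tables would fit each energy better and remain a
  configuration extension only.
* Absolute dose rests on one calibration point per energy; nothing off
  the 10 cm measurement depth is predicted.
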