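---
title: "Direct signal control for 3D FSE FLAIR at 7T: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct signal control for 3D FSE FLAIR at 7T: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscflair)
```

## The problem

At 7T the transmit field $B_1^+$ of a head coil is strongly nonuniform:
the quadrature mode is bright in the centre of the brain and can lose half
or more of its amplitude inferiorly (cerebellum) and peripherally. A 3D
fast-spin-echo (FSE) FLAIR sequence — a long train of refocusing pulses
after a T2-preparation and an inversion — translates that flip-angle
nonuniformity into signal voids and contrast variation.

With a parallel-transmit (pTx) array the complex weight $w_{jk}$ applied to
channel $k$ for pulse $j$ can be changed *per pulse* through the echo
train. Arbitrary per-pulse weights violate the CPMG condition, so they
cannot be chosen from field maps alone; instead the package optimizes them
through a full signal model of the echo train — *direct signal control*
(DSC).

## Signal model

The echo amplitudes are computed with the extended phase graph (EPG)
formalism, evaluated per voxel with the local channel sensitivities
("spatially resolved" EPG). For voxel $i$ with complex sensitivities
$S_{ik}$, pulse $j$ is applied with an effective complex scale

$$s_{ij} = \sum_k w_{jk}\, S_{ik},$$

i.e. flip angle $a_j |s_{ij}|$ and phase offset $\arg s_{ij}$ on top of the
base sequence $a_j$. One echo period is: relaxation + crusher dephasing
over half an echo spacing, the RF rotation, relaxation + dephasing over the
second half, and the echo $I_{ij} = |F_0|$. $B_0$ does not enter the
readout model: the hard readout pulses are under 1 ms long, so their
bandwidth is large compared with the observed off-resonance.

The *target* $T_j$ is the same train simulated with unit scale — the
behaviour of the sequence on an ideal uniform transmitter — for a reference
tissue ($T_1^{ref} = 1500$ ms, $T_2^{ref} = 50$ ms, indicative of average
brain tissue at 7T). The base sequence is the vendor-style 3D-FLAIR
protocol: a 90° excitation followed by 191 refocusing pulses whose flip
angles ramp down quickly to a constant 50°, echo spacing 3 ms, TR 8 s,
TI 2250 ms, centre of k-space at echo 100.

Two numerical checks pin the engine down:

* the EPG kernel agrees with an independent Bloch isochromat-ensemble
  simulation to better than $10^{-6}$ (machine precision in practice) for
  arbitrary complex per-pulse scales, because a uniformly spaced discrete
  dephasing ensemble reproduces the configuration-state expansion exactly
  while the highest populated order is below the ensemble size;
* ideal-CPMG and pure-$T_2$-decay closed forms are reproduced exactly.

### Truncation order

EPG states are truncated at order $K$. `simulate_echo_train()`,
`target_signal()` and `forward_model()` default to the exact $K = N_p$.
Inside the optimizer the default is $K = 96$: on the 192-pulse protocol
train the worst-case echo error of $K = 96$ against the exact expansion is
$3\times10^{-5}$ (measured under random complex per-pulse scales, which
spread configuration orders faster than optimized shims do), while roughly
halving the cost of an objective evaluation. $K$ is exposed in
`dsc_control()`.

## Magnetization preparation

The preparation is simulated with single-isochromat Bloch integration
(piecewise-constant rotations, 5 µs steps by default; halving the step
changes the result by less than $10^{-4}$). The module is: hard 90°
tip-down, $n \in \{2, 4\}$ adiabatic hyperbolic-secant refocusing pulses
(9 ms, 15 µT, 706 Hz frequency sweep) at CPMG spacings, hard 90° tip-up,
perfect spoiling, adiabatic sech inversion (17.1 ms, 15 µT, 700 Hz), TI
recovery, the FSE readout (whose consumption of longitudinal magnetization
is taken from the EPG $Z_0$ trajectory — the train response is affine in
the entering $Z_0$, which the implementation exploits), and free recovery
to the end of TR. Steady state is reached by cycling this period from
equilibrium; for CSF (T1 4.3 s, T2 2 s) the pre-inversion magnetization
settles to within 1% in 3 periods, and the protocol timings null CSF at
the start of the readout to $|M_z| \approx 0.01$.

Design choices where the underlying protocol is not fully specified:

* **Sech truncation.** The dimensionless truncation $\beta\tau/2$ of the
  sech pulses is not part of the protocol description; the package uses
  5.3, the standard full-passage parameterization (edge amplitude about 1%
  of peak).
* **T2-prep duration.** The tip-down to tip-up time is not published;
  default 100 ms, exposed in the API. With 4 pulses of 9 ms this leaves
  comfortable CPMG gaps.
* **Hard tip pulses.** Modelled as instantaneous rotations (durations
  unpublished) that scale with the local $B_1$ like every other pulse.
* **Phase cycling.** The 4-pulse module uses MLEV-4 phases
  (0, 0, 180, 180); the 2-pulse module is uncycled. This was initially an
  open choice, but simulation settles it: without MLEV-4 the 4-pulse module
  shows *no* off-resonance robustness advantage at low $B_1$ (Mz variation
  over ±300 Hz at $B_1$ scale 0.4: 1.94 uncycled vs 1.72 for 2 pulses),
  whereas with MLEV-4 — the scheme used by the 4-pulse T2-prep designs this
  module follows — it is clearly more robust (1.14 vs 1.72, and 0.48 vs
  1.06 at scale 0.5). The fringe-like artefact of the 2-pulse module
  (rapid Mz oscillation with $B_0$, period set by the inter-pulse spacing)
  is reproduced by `prep_grid()`.
* **Ramp shape.** The vendor flip-angle ramp is unspecified beyond
  "quickly ramp down to a constant 50°"; the default is a geometric
  descent from 140° reaching the plateau at pulse 14, aligning the ramp
  with the 13 individually shimmed pulses. Start angle and length are
  arguments.
* **Excitation.** Whether the excitation is one of the "192 pulses" and
  whether it is shimmed is ambiguous; both default to yes (pulse 1 of the
  train, first row of the shim matrix), so the mapping covers 192 pulses.

## The optimization

$$\min_{w'} \sum_{i,j} \| C_j (I_{ij}(w) - T_j) \|_2^2
\quad \text{s.t.} \quad
\sum_j \frac{|w_{jk} b_j|^2\, t_{RMS,j}\, A}{TR} \le P_{avg} - P_{MP}
\;\;\forall k, \qquad
|w_{jk} b_j|^2 A \le P_{peak} \;\;\forall j,k,$$

with $b_j$ the peak B1 of pulse $j$ (from its flip angle and 0.8 ms
duration), $t_{RMS,j}$ its RMS-equivalent duration (equal to the duration
for hard pulses), $A = 0.35$ W/µT² the coil power conversion factor, and
per-channel limits $P_{avg} = 1$ W, $P_{peak} = 85$ W. The average-power
budget of the readout is reduced by the preparation module's contribution
$P_{MP}$ (0.34 W for the 4-pulse prep, 0.15 W for the 2-pulse one),
interpreted per channel and exposed in `power_model()`. The echo weighting
$C_j$ ramps linearly from a floor (default 0.2; the published description
fixes only the shape) to 1 at the centre-of-k-space echo and back.

The full $192\times8$ complex weight matrix is reduced to
$w' \in \mathbb{C}^{16\times8}$: pulses 1–13 individually, then blocks of
60, 60 and 59 — 256 real parameters. All entries start at 0.6 (quadrature
mode at reduced amplitude, safely inside the power constraints).

Implementation choices:

* **Gradients.** The cost gradient is computed by an adjoint-state sweep
  through the (real-)linear EPG operator chain, at a cost of about two
  forward simulations *independent of the number of parameters*; central
  finite differences over 256 parameters would cost 512 forward runs per
  gradient, which is why the adjoint is the default (`gradient = "fd"`
  remains available and the adjoint is verified against central
  differences to $10^{-4}$ relative on a toy problem in the test suite).
* **Constraints.** In reduced coordinates both constraint families are
  convex quadratics (an ellipsoid per channel for average power, a disk
  per entry for peak power). They are enforced by an augmented-Lagrangian
  scheme with L-BFGS inner solves, followed by an exact projection onto
  the feasible set (entrywise magnitude clipping, then per-channel
  rescaling), so returned solutions always satisfy both limits as
  evaluated by `channel_powers()` — the same code path the report uses.
* **Monotonicity.** The returned solution never has higher cost than the
  initial point; if the polish were ever to regress past it, the initial
  point is returned and the fit flagged unconverged.
* **Termination.** Relative cost change below $10^{-6}$ with feasible
  iterates, or the iteration budget (`outer_iters` ×
  `inner_maxit`).
* **Echo magnitude.** The optimized quantity is $|F_0|$; the published
  description optimizes "echo amplitudes" and receiver phase is corrected
  in practice. A phase-referenced complex comparison would be a one-line
  change in the C++ kernel but is intentionally not exposed.
* **Universal solutions.** `dsc(list_of_subjects)` concatenates the
  subjects' sensitivity rows and minimizes the pooled error; nothing else
  changes.
* **Steady-state effects** over multiple TRs are not part of the readout
  cost: with TR = 8 s the short-$T_2$ reference tissue recovers almost
  fully, and the long-$T_2$ fluid that would need such treatment is nulled
  by the FLAIR preparation.

The static magnitude-least-squares shim baseline alternates a phase-target
update with a convex power-constrained least-squares solve (variable
exchange). For a *static* shim the two power limits collapse to a single
amplitude cap per channel, so the inner problem is solved by projected
gradient descent; the exchange objective is non-increasing. The magnitude
target defaults to the mean quadrature combination over the mask (the
published description does not state a target level). Under a binding
average-power limit the solution drives every channel at the cap and only
the phases differ — the regime reported for heavily power-limited 7T
protocols.

## Synthetic fields

No field-map data ship with the package; `synth_b1()` generates an
8-channel ellipsoidal head at desk scale (24³ grid, 8 mm synthetic voxels,
~550 masked voxels — the optimization cost scales with masked voxels, and
this size exercises every code path in minutes on one core). Channels sit
azimuthally around the head with Gaussian-lobed amplitudes and
propagation-like phase ($-\beta d$ from the port; $\beta$ sized so
destructive interference darkens the periphery to roughly half the central
quadrature value). The quadrature combination is normalized to 1 at the
mask centroid; an inferior-posterior attenuation blob pulls the in-mask
minimum to `dropout_depth` (default 0.35) of the centre, emulating the
cerebellar dropout. B0 is a smooth polynomial plus localized
inferior-frontal blobs within ±600 Hz. `synth_cohort()` varies head size
(±10%), channel gains (15%) and dropout depth per subject.

With these defaults the quadrature centre-echo prediction has CoV ≈
0.12–0.17 and P10 ≈ 0.3–0.4 across seeds — the regime in which dynamic
shimming is worth doing — and DSC fits roughly double P10 while lowering
CoV, with the average-power limit binding at the optimum. The constrained
optimum on these phantoms plateaus near P10 ≈ 0.65: quadrupling the
iteration budget improves the cost by only a further 7% and P10 by less
than 0.01, which is why the default budget (6 outer × 40 inner
iterations) is kept modest.

What the generator does **not** emulate: electromagnetic field physics
(no curl constraints, no tissue loading asymmetries), realistic tissue
segmentation, receive fields, measurement noise in the maps, or
registration error. Tests passing on these phantoms therefore demonstrate
the correctness and the qualitative behaviour of the method, not its
in-vivo performance.

## Degenerate inputs and numerical edges

* A voxel with all-zero sensitivity contributes zero signal and zero
  gradient (the flip-angle magnitude is non-differentiable at exactly zero
  scale; the gradient is defined as 0 there).
* `coefficient_of_variation()` refuses a zero mean; `p10()` a non-positive
  target; the static shim refuses all-zero sensitivities.
* An infeasible starting point is rescaled into the feasible set before
  optimization rather than rejected.
* Fixed inputs give bitwise-identical solver trajectories (no stochastic
  elements in the optimizer); the field generator is deterministic given
  its seed and restores the caller's RNG state.

## Problem sizes used by the tests

The test suite runs EPG cross-checks on 8–28-pulse trains, optimizer
contract checks on toy problems, one full-protocol fit (192 pulses,
$N_s = 16$, ~550 voxels) at a reduced iteration budget, and the
5-subject method-ordering study on 16³ grids (~160 voxels per subject)
with reduced iteration budgets. These sizes were chosen so the entire
suite exercises the full model chain in a few minutes on a single core;
they are the package's desk-scale study conditions, with grid, mapping and
iteration budgets all exposed for larger runs.

## Known limitations

* The preparation module is optimized nowhere: it is transmitted in
  quadrature, matching the finding that the readout dominates the signal
  nonuniformity; only its average-power cost enters the optimization.
* No SAR model — the per-channel power limits stand in for SAR, which is
  the conservative institutional practice the protocol used.
* Magnitude targets only; complex (phase-referenced) echo matching is not
  exposed.
* The Bloch prep model is single-isochromat: intra-voxel dephasing,
  diffusion, flow and magnetization transfer are out of scope, and CSF
  pulsation — an alternative explanation for fringe artefacts — is not
  modelled.
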