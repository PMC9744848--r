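---
title: "placegrid: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{placegrid: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`placegrid` simulates the coupled dynamics of hippocampal place cells and
medial-entorhinal grid cells while a virtual animal explores a square arena.
The grid network performs path integration from self-motion (idiothetic)
input alone; the place network binds allothetic input — noisy proximity
sensing and salient visual features — into place fields; and the coupling
loop lets emerging place fields correct the grid network's accumulated
position error. This vignette describes the model components, the choices
made where the design was genuinely open, and what the synthetic environment
does and does not emulate.

## The environment and trajectory generators

The arena is a square of side `L = 100` a.u. with about 40 visually distinct
landmarks placed just beyond the walls. No images are rendered: landmark
appearance is summarised by parametric blob features. Solidity and axis
orientation are identity-linked (constant across viewpoints); apparent area
falls off as one over squared distance and the image centroid follows the
bearing and distance, so they are pose-linked. These two classes realise the
two functions a feature space needs for landmark-based localisation: one that
separates landmarks but not viewpoints, and one that varies with the
observer's position relative to the landmark.

Two bounded correlated random walks stand in for open-field exploration
styles commonly seen in rodents: a center-biased walk (S1) with a weak pull
towards the middle and strong wall avoidance, and a wall-following walk (S2)
that steers to the nearest wall, travels tangentially inside a 10 a.u. band,
and occasionally crosses the arena so that coverage is eventually complete.
Both start at the center with random orientation; per-step displacement is
capped at 1.5 a.u. Generator parameters were calibrated once against their
occupancy contracts — at 10,000 steps the S1 walk visits at least 95% of the
10 x 10 occupancy bins and the S2 walk spends at least 70% of its time
within 15 a.u. of a wall — and are not tied to any downstream result. The
generators do not emulate running-speed rhythms, thigmotaxis ontogeny, or
goal-directed segments of real exploration; conclusions that depend on those
features are outside what passing tests can show.

## Place network

Each of the `N_pc = 2000` place cells receives the `N_s = 3` proximity
sensors (the position along the left-right, back-front and constant down-up
axes, with multiplicative noise `X' = X (1 + alpha eta)`, `eta ~ U(-1, 1)`,
`alpha = 0.1`) through a weight vector, and carries a firing power

    P_j = C_j R_m exp( -((1/n) ||X'/L - w_j||)^2 / (2 sigma_j^2) )

with spike energy `C_j ~ N(188, 10)` nJ, maximum rate `R_m = 20` Hz and
tuning width `sigma_j ~ N(0.03, 0.005)`. Responding cells
(`P_j > P_thr = 0.3`) move their weights towards the input,
`w <- w + mu (X'/L - w)`, `mu = 0.001`. Weights are initialised through the
logistic `w = (1 + exp((gamma - 1/2)/(2 sigma^2)))^{-1}`, `gamma ~ U(0,1)`.
The shape parameter sigma is not fixed by the model description; the default
0.25 was chosen because it spreads initial position preferences over the
whole arena, walls included — sharper values collapse the weights to binary
corner preferences, flatter values exclude the wall band entirely, and
either extreme contradicts the intended property that fields can emerge both
near and far from the boundary.

Each cell also owns a Hodgkin-Huxley unit integrated by forward Euler
(`dt = 0.01`, 100 sub-steps per simulation step; gating variables clamped to
[0, 1] after each sub-step). The rate functions and reversal potentials are
the classic squid-axon set written for the depolarisation `v = V_m - V_r`
with `V_r = -65` mV (E_Na = 115, E_K = -12, E_l = 10.6 rest-relative,
conductances 120/36/0.3 mS/cm^2, C_m = 1). Every unit receives the constant
reference current `I = 10`, placing it on the repetitive-firing limit cycle;
initial membrane potentials are drawn from U(-75, -55) mV so the population
phases decorrelate. A cell "fires" in a step when its membrane crosses 0 mV
upwards during the sub-integration. The model description does not state how
proximity input maps onto the H-H current; the constant-drive reading keeps
the printed `I = 10` and leaves spatial selectivity to the firing power, the
field membership rule and the feature-matching pathway, all of which do
receive proximity or visual input.

Visual selectivity uses two preferred feature sets M1, M2 per cell. The
response to a blob is the product of Gaussian similarities
(`sigma_f = 0.5`) over area, orientation, solidity and the 2-D centroid,
and the activation is the best ordered pair of distinct blobs,
`A = max_i A1_i * max_{j != i} A2_j`; fewer than two visible blobs give
`A = 0`, since the conjunction needs two distinct blobs. At each position
the most activated cell ("winner") adapts its preferred features towards
the observed pair by the convex rule `mu_f <- 0.5 x_f + 0.5 mu_f`. (The
additive form with coefficient `1 + alpha` diverges for any positive rate
and is read as a misprint for the convex combination.)

A place field emerges at the current position when three conditions hold
simultaneously — the H-H unit fired, the grid drive exceeds 1.1 a.u., and
`A` exceeds the feature threshold `A_thr` — and the position is "uncertain"
(below). `A_thr` has no reference value; the default 0.1 was calibrated
against the described field dynamics — several fields appearing within a
100-step segment and a field population that forms mostly by `t = 2000` of
a 10,000-step exploration and then changes little. The plateau this model
reaches is softer than that description: per-cell emergence rates are
static and heavy-tailed, so cells with improbable feature preferences
trickle in throughout a long run (roughly two thirds of the final field
count is in place by `t = 2000`, and the count still drifts by a few
percent over the final fifth of the run). Field membership
and the field-center integrals accumulate over every supra-threshold step:
the center is the firing-power-weighted average of the noisy positions,
so it converges on the true field location as visits accumulate. Population
decoding averages responding cells' centers weighted by current power; the
decoding error is normalised by `L/sqrt(2)` and clipped to [0, 1], so an
unselective population (estimate pinned near the arena center) scores
errors of order one.

## Grid network

Five modules of 20 x 20 neurons live on a twisted torus: neuron coordinates
`c_x = (l_x - 1/2)/N_x`, `c_y = (sqrt(3)/2)(l_y - 1/2)/N_x`, with the plane
tiled by the triangular lattice generated by `(1, 0)` and `(1/2, sqrt(3)/2)`.
Recurrent weights are center-surround Gaussians of the minimal-lattice-norm
displacement, shifted into inhibition:

    w_ij = I_a exp(-||c_i - c_j + v_R||^2 / sigma_w^2) - T

with velocity entering the weights as `v_R = gain * R_beta v`. The update is
`B_j = sum_i A_i w_ij` followed by `A <- max(0, B + tau (B/mean(B) - B))`,
`tau = 0.95`. The weight constants are not given numerically in the model
description (`I_a = 0.3`, `sigma_w = 0.24`, `T = 0.05` follow the
twisted-torus attractor lineage it builds on and are config-exposed).
Because the neurons sit on a uniform torus grid, the weights take only
`N_x N_y` distinct values per step; the compiled kernel evaluates those 400
values and applies them through a displacement-class table, which is exactly
the per-pair computation, not an approximation. Activity is initialised
`U(0, 1/sqrt(N))` and settles into a single bump after a few hundred
zero-velocity steps.

The bump center is the activity-weighted circular mean per periodic
coordinate; path integration accumulates `gamma * delta` of the bump-center
displacement between consecutive steps. `gamma` is estimated per module by
least squares on two straight constant-velocity calibration legs; the
gains 0.04-0.08 give `gamma ~ 1/gain`. The printed inter-module "spacing
(0.95)" is ambiguous; it is applied as `gamma_m = gamma_cal * 0.95^m` for
modules m = 1..5, so every module carries a share of the mis-scale,
smallest dorsally and largest ventrally. This is the model's source of
uncorrected error accumulation: position error grows in proportion to the
displacement integrated since the last anchor point, module 5 fastest. The
bump readout itself contributes only a bounded residual (displacement
quantisation telescopes), so closed-loop return error without correction is
positive but does not grow appreciably with loop length in this
implementation.

## Coupling loop

The grid-to-place drive multiplies each module's maximum activity by a
Gaussian place-cell-index weight matrix (five columns spread evenly over a
[0, 10] index coordinate, width 2.5) and averages across modules. With the
default attractor constants the settled bump maximum is ~17 a.u., so the
1.1 a.u. drive threshold is met by most cells; the threshold and the
activity scale are coupled through `I_a`, `sigma_w`, `T`, and changing those
constants rescales the drive. The printed plasticity of this matrix
(towards the raw noisy sensor signal, broadcast as its scalar mean) is
implemented as stated; it inflates drives over a long run and so relaxes
the grid-input condition late in exploration. A per-component broadcast
variant is config-exposed.

Cross-module uncertainty is `E = sqrt(sd(pos_x)^2 + sd(pos_y)^2)` (sample
sd over the five module estimates). `E > 1.5` a.u. marks the position
uncertain: only then may fields emerge, and only then is a correction
applied — if the nearest field center lies within 2.5 a.u. of the animal's
current position, every module's estimate is reset to that center.
Corrections therefore fire exactly when the modules disagree, and the reset
re-anchors all subsequent drift. Emerging fields affect only the position
estimates, never the grid firing itself, which is why the attractor
dynamics can be computed in a single pass per trajectory and shared between
switch settings of the same seed (the comparisons are paired).

The error-reduction and field-density recipes follow the reference
protocols: place input ON against the uncorrected integrals of the same run
(the OFF arm re-anchored at the measured window's start), and 20 against
200 fixed random field centers on identical trajectories. Because the
comparison presumes a developed field population, the error-reduction
recipe precedes its 1000-step measured window with a 2000-step formation
phase — the plateau time — mirroring the post-navigation training used to
speed statistics in the reference workflow.

## Analysis battery

Rate maps use 2.5 a.u. bins (40 x 40), occupancy normalisation, missing
unvisited bins, and NA-aware Gaussian smoothing of one bin. The spatial
autocorrelogram is the lag-wise Pearson correlation over overlapping valid
bins (computed via FFT cross-correlation sums; lags with fewer than 20
overlapping bins are missing). Gridness crops an annulus — inner radius
half the nearest autocorrelogram peak distance, outer radius 1.25 times the
mean distance of the six peaks closest to the center — resamples it on a
polar grid with 2.5 degree angular steps, and correlates it with rotated
copies (rotation is an exact circular shift of the angular samples).
Hexagonal score: `(C60 + C120)/2 - (C30 + C90 + C150)/3`; square score:
`C90 - (C45 + C135)/2`. When every rotation correlates equally the scores
vanish identically; on discretised radially-symmetric maps the pixel-grid
anisotropy of bilinear interpolation leaves a residual of order 0.05.
Cells whose autocorrelogram shows no usable peaks score `NA` and are
excluded from population means.

The entropy suite takes the per-cell event probabilities `p_i` (cumulative
H-H spike counts among cells with at least one field, recomputed each
step); `entropy_suite()` itself accepts any event distribution, so
per-location probabilities can be supplied just as well. It reports Shannon
entropy `H` (natural log; `0 log 0 = 0`), entropy ratio `r = H / log n`,
complexity ratio `R = 1 - r`, information difference `I = log n - H`, and
the decomposition `H = S + Z` with spatial entropy
`S = -sum p_i log(p_i / dx_i)` and information density
`Z = -sum p_i log dx_i` at the fixed event size `dx = 20` a.u. The
cross-entropy measures against a reference distribution and the Euclidean /
cross-module variance error summaries complete the battery.

## Reproducibility and problem sizes

A single experiment seed fans out into fixed, named per-component streams
(trajectory, landmarks, place init, grid init, sensory noise, fixed
fields), so switching one component on or off never shifts another's
draws; identical configurations reproduce byte-identical outputs. The
standard experiment sizes used throughout the package's own checks are
10,000-step explorations for gridness and entropy dynamics, 2000 + 1000
steps for the error-reduction comparison, and 1000 steps for the
field-density comparison, at the full 2000-cell, five-module scale.

## Known limitations

The attractor's path integration is more accurate than a biological system
plausibly is: velocity input is noiseless, so uncorrected error stems
almost entirely from the deliberate spacing mis-scale, and closed-loop
return error is bounded rather than diffusive. The synthetic trajectories
produce near-ideal grid tessellations; population-mean gridness is
correspondingly high (about 1.3 hexagonal, strongly negative square) and
both styles score similarly — degraded, partially square-like patterns
require exploration statistics and analysis details that the synthetic
stand-ins do not reproduce. The blob generator is deterministic and
noise-free; visual ambiguity between similar landmarks is not modelled.
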