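---
title: "Somatotopic map plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatotopic map plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

## The scientific problem

The primary somatosensory cortical map of the hand is both orderly and
discontinuous: within a digit's representation, neighboring cortical sites
have small, overlapping receptive fields that progress smoothly over the
skin, while between digit representations the receptive-field location
jumps abruptly.  These representational discontinuities are plastic: when
two fingers are fused (syndactyly), so that touch inputs on the two digits
become temporally correlated, the cortical border between them dissolves;
when the fingers are separated again the border re-forms.

`somatomap` implements a mechanistic account of these phenomena in which
*nothing* about the borders is built in.  A lattice of skin inputs drives a
lattice of cortical columns, each column holding one excitatory (E) and
one inhibitory (I) cell; every connection type — afferent and lateral,
excitatory and inhibitory — adapts under one simple covariance rule with
competitive normalization.  Borders, the characteristic double-digit
inhibitory receptive fields that straddle them, and their reversible
reorganization under syndactyly all emerge from the statistics of
stimulation alone.

## Model

### Populations and connectivity

Two square `N x N` lattices (default `N = 45`).  Each input-layer (S) node
is a skin point; the rows are partitioned into three contiguous bands
representing digits D1–D3 (15 rows each at full scale), and the column axis
is the proximal–distal axis of the digits.  Each cortical node is a column
containing an E and an I cell.  Four connection types link the lattices,
each through a centered `M x M` mask (default `M = 7`) truncated at the
lattice edge (planar boundaries, no wrap-around):

* `ES` — afferent: S nodes onto E cells;
* `EE` — lateral excitation, including the self-connection;
* `IE` — lateral excitation of I cells by E cells;
* `EI` — lateral inhibition of E cells by I cells (there is no I-to-I type,
  so inhibitory cells have no self-connection).

Every (postsynaptic, presynaptic) pair occurs at most once.  Interior cells
have fan-in `M^2 = 49`; a corner cell keeps the `((M+1)/2)^2 = 16`
surviving mask slots.  No delays, no distance-dependent fall-off, and no
spatial preconditioning of weights: all four weight sets start i.i.d.
uniform.

### Dynamics

Each unit is a lumped RC membrane receiving one unit of synaptic drive per
1-ms step.  Writing `I_i` for the *fan-in-averaged* drive of cell `i`, the
Euler-mode update is the discrete network map

```
v_i(t+1) = alpha_m v_i(t) + I_i(t) + eps(t),   alpha_m = 1 - h/tau_m = 0.96,
I_i^E = (1/N_i) [ sum_j w_ij^ES r_j^S + sum_j w_ij^EE r_j^E - sum_j w_ij^EI r_j^I ],
I_i^I = (1/N_i)   sum_j w_ij^IE r_j^E,      (delta_i(t) in place of I for S units)
r = g(v) = (1 + tanh(beta_m (v - 1/2))) / 2,   beta_m = 4,  tau_m = 25 ms,
```

with i.i.d. uniform noise `eps` on `[-0.01, 0.01]` added to every membrane
potential at every step.  Stored weights are all nonnegative; the minus
sign of inhibition lives in the E-cell equation.  Because the drive is
delivered per step while the leak drains only `h/tau_m` of the potential
per step, the steady state under constant drive is `v* = (tau_m/h) I`:
the system is strongly overdriven, so a stimulated unit crosses the
sigmoid's active range within a few milliseconds.  This is what gives the
model its characteristic low-latency, saturating responses and — through
the slower inhibitory feedback loop — a sharp winner-take-all competition
among excitatory cells.  The E/I loop delay is also why a strong stimulus
is followed by deep E-cell hyperpolarization while inhibition decays with
the RC time constant.

Two structural choices make these dynamics well-posed, and the package
treats them as design decisions of its own:

* **Fan-in-averaged drive.**  Dividing each cell's weighted input sum by
  its actual (edge-clipped) fan-in `N_i`, together with per-cell
  mean-resource normalization (below), makes edge cells statistically
  equivalent to interior cells — the operational meaning of "normalization
  enforces planar boundary conditions".  Without the averaging, the raw
  sum of ~49 weighted inputs (mean weight 2) turns the baseline firing of
  `g(0) ~ 0.018` into a super-threshold drive: the resting network
  saturates within a few steps regardless of stimulus, and no map can
  form.  We verified this by direct simulation before adopting the
  averaged form.
* **Postsynaptic resource balance.**  Resources are assigned per
  postsynaptic cell type: all inputs to E cells (afferent, lateral
  excitatory *and* inhibitory) are normalized to the same mean, 2.0, and
  inputs to I cells to 1.0.  At full activity, lateral inhibition can then
  exactly cancel lateral excitation, so the saturated state is not
  self-sustaining and the network returns to rest after every stimulus.
  Assigning inhibition a smaller budget than lateral excitation creates a
  second, stable saturated fixed point that the first strong stimulus
  locks in permanently; destabilizing the balance in other ways (boosting
  `EE`, weakening `EI`) produces 20–40 Hz at-the-limit oscillation, the
  classic pathological regime of this model family.

### Integration

The reference integrator is classical fourth-order Runge–Kutta on
`dv/dt = -v/tau_m + I/h` with `h = 1` ms.  Rates — and hence the synaptic
drive — are frozen over each step, exactly as in the discrete-time network
map; each membrane then obeys an affine ODE over the step, for which the
four RK4 stages collapse to

```
v(t+1) = P v(t) + (1-P)(tau_m/h) I(t),  P = 1 - a + a^2/2 - a^3/6 + a^4/24,  a = h/tau_m,
```

which the kernel applies directly (the test suite checks it against a
literal four-stage implementation, and against `exp(-t/tau_m)` free decay
to better than 1e-6 over 100 steps).  `mode = "euler"` uses `P = 1 - a`
and reproduces the network map above exactly.  Noise is added after the
deterministic update, outside the stages.

Trials within a block are independent events starting from a common
resting state: each block first relaxes the zero state for `settle_ms`
(default 500 ms; no stimulus, no plasticity) and snapshots the result, and
every trial is reset to that snapshot.  Starting trials at `v = 0` instead
triggers a spurious network-wide ignition transient (every unit firing at
the baseline rate through the overdriven couplings), which contaminates
the pre-stimulus window that receptive-field statistics are normalized
against.

The compiled kernel evaluates `g(v)` by linear interpolation in a dense
table (40001 knots on `beta_m (v - 1/2)` in `[-20, 20]`; max absolute
error < 1.5e-7, four orders of magnitude below the membrane noise).  The
R-level `firing_rate()` is the exact formula; cross-checks between the
kernel and the R reference use tolerances of about 1e-5.

### Plasticity

While the plasticity gate is on, every connection updates at every step:

```
w_ij(t+1) = alpha_w w_ij(t) + beta_w(T) r_i(t) r_j(t),
alpha_w = 1 - h/tau_w,  tau_w = 100 tau_m = 2.5 s,
beta_w(T+1) = 0.99 beta_w(T),  beta_w(0) = 2.5e-4,
```

where `T` counts completed stimulation cycles and `r_i`, `r_j` are the
postsynaptic and presynaptic rates at the step being applied.  The decay
term applies at every step of a gated trial, including pre- and
post-stimulus periods.  At the end of every gated trial, each cell's
incoming weights of each type are rescaled multiplicatively so their mean
equals the type's resource (`ES`, `EE`, `EI`: 2.0; `IE`: 1.0) — the
competitive step: a synapse can only grow at the expense of its
postsynaptic cell's other inputs of the same type.  Probe trials are never
followed by normalization (the gate controls both), so receptive-field
mapping is exactly weight-neutral.  `beta_w` resets to `beta_w(0)` at the
start of each phase by default (`beta_reset = FALSE` continues the decay
across phases instead).

Positivity is preserved automatically: decay and the Hebb term keep
positive weights positive, and normalization is multiplicative.
A cell whose incoming weights were all zero would make normalization
ill-defined; this is reported as a degenerate-normalization error rather
than silently repaired.

## Stimulation protocol (the synthetic-data generator)

All inputs are generated internally; there is no external data.  A *trial*
lasts 350 ms: 100 ms pre-stimulus, 50 ms stimulus, 200 ms relaxation, with
the network state reset to the settled resting snapshot at trial start so
trials are independent events.
During the stimulus a contiguous `7 x 7` patch of S nodes is ON, the drive
vector scaled each step to Euclidean norm 4.0 (each node receives 4/7); a
*receptive-field probe* drives a single node at magnitude 1.0 without
renormalization.  A *cycle* presents every admissible patch placement
exactly once in seeded random order — 351 placements per 15-row digit at
full scale (1053 per baseline cycle; the fused D1+D2 band yields 936, so
1287 per syndactyly cycle).  A *phase* is 15 cycles; the *experimental
track* chains baseline refinement, syndactyly (patches ignore the D1–D2
boundary), and release (baseline stimulation of the syndactyly-refined
network), while the *control track* branches after baseline into two more
baseline phases, so the control digit D3 sees identical trial counts on
both tracks.  Uniform-stimulation and large-patch (up to `15 x 15`)
controls are configuration options of the same machinery
(`boundary_mode = "uniform"`, `patch_h`, `patch_w`).

What the generator emulates is the *correlational structure* of touch:
co-activation is confined to (fused) digit bands, equal per-digit
stimulation counts control for use effects.  What it does not emulate:
skin and mechanoreceptor biophysics, stimulus shapes other than one
rectangle per trial, temporal stimulus sequences, or subcortical loops.
Passing tests therefore demonstrate properties of this correlational
mechanism, not of skin mechanics.

## Receptive-field analysis

Mapping is two-step: probe every S node once (plasticity off), storing each
cortical cell's mean pre-stimulus rate, mean stimulus-period rate and peak
rate per probe; then post-process.  A cell's receptive field is the set of
probes driving its response above 50% of that cell's maximum across all
probes; the default response statistic is the stimulus-period mean
(`statistic = "peak"` is available).  Response magnitude is the maximum
ratio of stimulus-period to pre-stimulus mean rate.  Centroid and
covariance are the unweighted sample moments of the member coordinates
(response-weighted variants are exposed but non-default); the 50%-level
Gaussian ellipse is a display convention under which multi-peaked fields
show as single large fields, so `n_modes` (8-connected components of the
member set) and `digit_span` should always be consulted alongside it.
Overlap between receptive fields is the Jaccard index of member sets.
Intracolumnar *divergence* is the Euclidean distance between a column's E
and I centroids; a column is classified divergent above two diagonal units
(`2 sqrt(2) ~ 2.83`).  The divergence *band width* at a digit boundary
counts, per side, the consecutive boundary-adjacent rows containing at
least one divergent column; the complementary extent-based measure
(`double_digit_band()`) counts the boundary-adjacent rows in which the
majority of columns have inhibitory receptive fields spanning two digit
bands, which is the more sensitive band statistic on small lattices where
the attainable centroid divergence is geometrically bounded.  The topographic-order score is the fraction
of adjacent column pairs whose centroid displacement preserves lattice
orientation — a deliberately simple stand-in for more elaborate map-order
measures, and labeled as such.

Columns within 3 nodes of the lateral lattice edges are excluded from the
band-width and border-centroid summaries: with `M = 7` masks, truncation
effects are confined to the outermost one to three nodes, and only for
lattices well above `N = 20` is the interior unaffected — one reason the
scaled-down study uses `N = 30`, not less.

## Study sizes and numerical choices

The distributed test-and-acceptance suite exercises the full-scale
`45 x 45` lattice for everything combinatorial and algebraic, and runs the
emergent-structure study on a `30 x 30` lattice with three 10-row digits
(the smallest configuration with a comfortable margin over the edge-effect
zone), 15 cycles per phase, default parameters, noise on, receptive-field
maps at phase ends.  In this configuration the double-digit inhibitory
band occupies the *two* rows on either side of each boundary and nothing
outside them, and the intracolumnar E–I centroid divergence at the band
peaks near — but, at 15 cycles, just under — two diagonal units.  A band
confined to a *single* flanking row per side at this scale is not
produced by this implementation under these conditions; with 10-row
digits an excitatory centroid can retreat at most about two rows from the
border, which bounds the attainable divergence, and the inhibitory
receptive-field radius (about four nodes) makes the row next-but-one to
the border double-digit as well.  The corresponding acceptance check is
deliberately left failing rather than weakened.  The full-scale three-phase track is provided as
`scripts/full_scale_run.R`, an optional regression taking on the order of
hours.  Tie-breaks and edge
cases are fixed as follows: receptive-field membership uses a strict `>`
threshold; nearest-node row assignment of a centroid uses half-up
rounding; singleton receptive fields report zero covariance and a
degenerate-orientation flag; covariance uses the maximum-likelihood
(divide-by-n) estimator.

Reproducibility: one R RNG stream per run (`set.seed`) drives initial
weights, per-cycle permutations and two per-trial draws that seed the
kernel's internal counter-based noise generator; identical seeds and
configurations give bit-identical trajectories, weights and maps.  With
noise disabled the noise generator is bypassed entirely (trials consume
seeding draws but no noise values), so deterministic runs remain
deterministic under either integrator.

## Limitations

Rate-based lumped columns, not spiking neurons; a single stimulus per
trial; fixed mask sizes; no subcortical feedback; map pathology (seizure-
like oscillation, degenerate high-magnification maps) is reachable under
parameter changes and is reported by the integrator only when potentials
become non-finite.  The orientation-preservation score is a coarse
summary; it is not a substitute for inspecting centroid maps.
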