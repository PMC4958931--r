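# somatomap

Self-organizing somatotopic map plasticity with excitatory **and**
inhibitory synaptic learning.

`somatomap` is a firing-rate simulation of primary somatosensory cortical
area 3b for computational neuroscientists studying how representational
borders in cortical maps emerge, dissolve, and re-form.  A three-digit
"hand" — an `N x N` input lattice partitioned into digit bands — is
forward-connected to an `N x N` lattice of cortical columns, each holding
one excitatory (E) and one inhibitory (I) cell.  Nothing about the digit
borders is wired in: all four connection types (`ES` afferent, `EE`
lateral excitatory, `EI` inhibitory-to-excitatory, `IE`
excitatory-to-inhibitory) start from i.i.d. uniform weights and adapt
under one covariance rule with competitive resource normalization.

## Model

Membrane potentials follow the leaky discrete-time map (Euler mode; a
collapsed fourth-order Runge–Kutta integrator is the default)

    v_i(t+1) = alpha_m v_i(t) + I_i(t) + eps(t),      alpha_m = 1 - h/tau_m
    I_i^E = (1/N_i) [ Σ_j w_ij^ES r_j^S + Σ_j w_ij^EE r_j^E - Σ_j w_ij^EI r_j^I ]
    r = g(v) = (1 + tanh(beta_m (v - 1/2))) / 2

with `h = 1` ms, `tau_m = 25` ms, `beta_m = 4`, uniform membrane noise
±0.01, and `N_i` the cell's edge-clipped fan-in (a centered 7 × 7 mask).
While plasticity is gated on, every connection updates at every step,

    w_ij(t+1) = alpha_w w_ij(t) + beta_w(T) r_i(t) r_j(t),   tau_w = 100 tau_m

with `beta_w` decaying by 0.99 per stimulation cycle, and at the end of
each trial every cell's incoming weights of each type are rescaled to a
fixed mean resource (2.0 for inputs to E cells, 1.0 for inputs to I
cells) — the competitive step.  The experimental protocol chains
*trials* (350 ms, one 7 × 7 skin patch) into *cycles* (every admissible
patch once, in random order), cycles into 15-cycle *phases* (baseline
refinement → simulated digital syndactyly of D1–D2 → release), and
phases into experimental and stimulation-matched control *tracks*.
Receptive fields are mapped by probing every input node one at a time
(plasticity off) and thresholding each cell's response at 50% of its
maximum; centroids, extents, orientation, Jaccard overlap, intracolumnar
E–I centroid divergence, and representational border band widths are
derived from the maps.

## Worked example

```r
library(somatomap)

## a scaled-down three-digit network
spec <- lattice_spec(N = 15, M = 7, digit_rows = c(5, 5, 5))
net  <- somatonet(spec, seed = 1)

## one stimulation trial, recording the column over the patch center
trial <- run_trial(net, patch = c(5, 5), height = 7, width = 7,
                   record_cells = data.frame(row = 8, col = 8))
round(trial$series$cell_8_8[c(100, 110, 150, 200, 300), ], 3)
#>     time_ms    v_s   r_s     v_e   r_e    v_i   r_i
#> 100     100 -0.010 0.017  -0.300 0.002  0.017 0.021
#> 110     110  4.701 1.000  15.405 1.000  6.044 1.000
#> 150     150 12.356 1.000  38.789 1.000 19.202 1.000
#> 200     200  1.670 1.000  26.498 1.000 14.420 1.000
#> 300     300  0.062 0.029 -33.573 0.000  0.696 0.827
```

Row by row: a quiet pre-stimulus baseline (t = 100 ms), a low-latency
saturating E response once the patch switches on, the delayed strong I
response, inhibition outlasting the stimulus, and the deep E
hyperpolarization (t = 300 ms) before the column relaxes back to rest.

```r
## three cycles of baseline refinement, then a receptive-field map
set.seed(1)
ph  <- run_phase(net, phase_spec("baseline", n_cycles = 3,
                                 patch_h = 3, patch_w = 3, rf_every = 3))
map <- ph$rf_maps[["3"]]
summary(map$area[map$type == "E"])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   10.00   17.00   20.00   19.22   22.00   29.00
topographic_order(map, "E")
#> [1] 0.938
```

After three cycles the excitatory receptive fields are already small
(median 20 of 225 input nodes) and the centroid map is topographically
ordered (94% of adjacent column pairs preserve lattice orientation; 0.5
is chance).  On this toy lattice the 5-row digits are narrower than the
inhibitory receptive fields, so inhibition stays double-digit everywhere;
the study-scale behavior — double-digit inhibition confined to narrow
bands straddling the digit borders, its disappearance under syndactyly
and reappearance after release — is exercised on a 30 × 30 lattice by the
acceptance suite below, and at full 45 × 45 scale by
`scripts/full_scale_run.R` (hours).

See the methods vignette (`vignettes/somatotopic-map-plasticity.Rmd`) for
the model's assumptions, parameter meanings, and numerical choices, and
`inst/cli/somatomap.R` for a command-line front end
(`init-config` / `run` / `map-rf` / `report`).

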