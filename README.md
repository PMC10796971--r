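# arborcsr

Subcellular center–surround analysis in retinal bipolar cell axonal arbors.

Two ON-sustained retinal ganglion cell (RGC) types that draw excitation
from the *same* bipolar cells (BCs) show very different surround
suppression. `arborcsr` implements the modelling pipeline for asking
whether this divergence can arise inside a single BC axonal arbor: a
compartmental cable model of a BC with stochastic conductance-based
synapses, a per-ribbon **center-to-surround ratio** (CSR) analysis, a
**difference-of-Gaussians (DoG) subunit model** of RGC excitation across
spot sizes with constrained fitting and cross-validation, and the combined
step that predicts each RGC type's surround suppression from the BC
model's CSR quartiles. Synthetic generators for BC and RGC morphologies
and spot-size response curves make every stage testable without external
data.

## The statistics at the core

* **Surround suppression** of a spot-size response curve (12 diameters,
  log-spaced 30–1200 μm, normalized to max 1):
  `Suppression = 1 − R_fullfield / R_preferred`.
* **Ribbon CSR** from paired cable simulations: center = mean
  depolarization from the −45 mV baseline under light excitation; surround
  = additional mean hyperpolarization when an inhibitory synapse set is
  co-activated; CSR = center/surround. Quartile summaries (84 ribbons →
  21 per quartile) give the **CSR range** = mean(Q4) − mean(Q1).
* **DoG subunit field** `G(r; σ_c) − (1/CSR)·G(r; σ_s)` (unit-volume
  Gaussians, σ_c fixed at 22 μm), fitted by minimizing the mean absolute
  error across cells and spot sizes from the initialization
  (σ_s = 100 μm, CSR = 1).

## Worked example

```r
library(arborcsr)

# synthetic T6-scale bipolar cell: 84 ribbons, 120 inhibitory, 8 excitatory
gen   <- gen_bc_morphology(bc_gen_params(seed = 7))
model <- build_bc_model(gen$morphology, gen$sites, active = TRUE,
                        cfg = sim_config(seed = 11))
model <- calibrate_rates(model)   # dark -45 mV, light -30 mV, Q1 CSR 1.1
model
#> bc_model: active membrane; 84 ribbons, 120 inhibitory, 8 excitatory sites; 343 compartments
#>   calibrated rates (ev/s): dark 31.2, light 2531.2, inh 9.4

# single-anchor inhibitory activation, 6 anchors
sw <- sweep_inhibitory_sets(model, n_active = 1,
                            anchors = model$inhibitory$site_id[1:6], seed = 3)
sw
#> csr_sweep: n_active 1, 6 anchors; CSR range median 2.372 [0.987, 3.035]
```

The sweep says that when one inhibitory synapse is active, ribbons of the
*same* BC differ widely in how much surround they inherit (CSR range ≈ 2.4
in the active model); the same sweep on a passive model gives a range
around 0.26 — voltage-gated channels are what compartmentalize the arbor.
Feeding the quartile means into the subunit model predicts the two RGC
types' suppression:

```r
pix <- lapply(1:6, function(i) gen_rgc_skeleton(
  rgc_gen_params(seed = i, field_diameter = 250, total_dendrite_length = 2500)))
ona <- lapply(1:6, function(i) gen_rgc_skeleton(
  rgc_gen_params(seed = 10 + i, field_diameter = 350, total_dendrite_length = 3000)))
predict_pair(q1_csr = 1.1, q4_csr = 2.4, pix, ona, sigma_s = 75)
#>   q1_csr q4_csr predicted_pixon_suppression predicted_onalpha_suppression
#> 1    1.1    2.4                   0.7357355                    0.09033494
```

Low-CSR ribbons drive strong predicted suppression (≈0.74), high-CSR
ribbons much weaker suppression (≈0.09) — the subcellular mechanism can,
in principle, serve both RGC types from one BC.

The DoG fitting side works the same way from data frames of spot
responses; `fit_dog()` returns a classed model object with
`print`/`summary`/`coef`/`predict`/`plot`/`residuals` methods, and
`cross_validate()` reports held-out suppression errors over random fitting
combinations.

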