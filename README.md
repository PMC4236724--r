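# igfnet

Mass-action modelling of the extracellular IGF1–IGFBP–IGF1R network in
cultured cells.

Ovarian cancer cells (and many other cell types) respond to insulin-like
growth factor 1 (IGF1) in proportion to how many IGF1–IGF1R receptor
complexes form on each cell — not in proportion to the nominal treatment
concentration. Two mechanisms set that occupancy: cell-secreted
IGF-binding proteins (IGFBPs) that sequester free ligand with
sub-nanomolar affinity, and slow cell-mediated depletion of free IGF1
from the media. igfnet implements the mass-action model of this network
for quantitative cell biologists and modellers who want to predict
receptor occupancy and proliferation from measurable quantities, and to
compare anti-IGF therapeutic strategies in silico.

The core model is five coupled mass-action ODEs over free IGF1 ($C_1$),
free receptor ($C_{1R}$), the signalling complex ($C_{1:1R}$), free
binding protein ($C_{BP}$) and the sequestered complex ($C_{1:BP}$):

$$\dot C_1 = k_{-1}C_{1:1R} + k_{-2}C_{1:BP} - k_1 C_1 C_{1R}
  - k_2 C_1 C_{BP} - k_3 C_1,$$

with the remaining species following the matching association /
dissociation terms, $k_3 = k_{3,0} N/N_0$ scaling depletion with cell
number, and optional extensions for an IGF1-neutralizing or an
IGF1R-blocking antibody. The package provides:

* stiff integration to the quasi-steady-state receptor-occupancy readout
  (`steady_state()`), verified against an independent closed-form
  binding-equilibrium solver (`equilibrium_oracle()`);
* calibration from bench measurements: the depletion rate from a
  time course (`estimate_k3_0()`), the total IGFBP level from one
  free-IGF1 measurement (`estimate_total_igfbp()`), and the linear
  occupancy-to-proliferation map with its receptor-saturation cap
  (`fit_proliferation_map()`);
* antibody intervention sweeps over Kd × dose × IGF1 × IGFBP grids
  (`run_test_matrix()`) and conditioned- vs fresh-media contrasts
  (`compare_media_scenarios()`);
* seeded synthetic-data generators mirroring each calibration input
  (`sim_depletion_timecourse()`, `sim_free_igf1_measurements()`,
  `sim_proliferation_dataset()`);
* YAML/JSON scenario configs (`load_scenario()`), tidy results
  (`tidy()`, `glance()`) and ggplot2 graphics (`plot_timecourse()`,
  `plot_inhibition_matrix()`, `autoplot()`).

## Worked example

A 0.25 nM IGF1 treatment spiked into conditioned media at the reference
density of 116,000 cells in 1 mL:

```r
library(igfnet)

ss <- steady_state(treatment(concentration = 0.25), cellular_context())
ss
#> <igf_steady_state> at 8 h (residual 0.000285 nM/hr, converged)
#>       c1      c1r    c1_1r      cbp    c1_bp
#> 0.018919 0.002538 0.000049 1.177915 0.225685
#>   IGF1-IGF1R complexes per cell: 4.183e-13 nmol/cell

100 * ss$state[["c1_bp"]] / 0.25
#> [1] 90.27399
```

Ninety percent of the applied dose ends up held in IGF1–IGFBP complexes;
free IGF1 falls to ~0.019 nM and only ~2% of the receptor pool is
occupied. The independent equilibrium oracle puts the pure binding
equilibrium at 92.1% sequestered; the dynamic readout sits just below it
because the slow cellular drain removes a little ligand while binding
equilibrates.

Comparing the two antibody strategies across the full test matrix
(antibody Kd ∈ {0.1, 1, 10} nM, four doses, low/high IGF1, IGFBP at
0.1–10× the measured level, 67,000 cells/well):

```r
res <- run_test_matrix(scenario_grid())
max(res$inhibition_ratio, na.rm = TRUE)
#> [1] 0.9990335
```

The neutralizing-to-blocking inhibition ratio never reaches 1: in every
scenario the IGF1R-blocking antibody suppresses receptor occupancy at
least as strongly as the IGF1-neutralizing antibody, and high IGFBP
levels widen the gap (the neutralizing antibody must out-compete the
binding-protein pool for ligand; the blocker is helped by it).

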