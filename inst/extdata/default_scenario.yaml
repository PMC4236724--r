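# Reference OVCAR5 scenario: all values are the package defaults, spelled
# out for documentation. Concentrations nM, time hours, volume mL,
# per-cell endowments nmol/cell.
rates:
  k1: 1        # IGF1 + IGF1R association, nM^-1 hr^-1
  k_neg1: 1    # IGF1-IGF1R dissociation, hr^-1  (Kd = 1 nM)
  k2: 1        # IGF1 + IGFBP association, nM^-1 hr^-1
  k_neg2: 0.1  # IGF1-IGFBP dissociation, hr^-1  (Kd = 0.1 nM)
  k3_0: 0.017  # cell-mediated depletion at the reference density, hr^-1
context:
  n_cells: 116000
  n_ref: 116000
  volume: 1
  igfbp_per_cell: 1.21e-8
  igf1r_per_cell: 2.23e-11
treatment:
  concentration: 0.25
  media: conditioned
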