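# External validation: dilution series of the four analytes in triplicate on
# a held-out, well-calibrated instrument. Levels are glucose concentrations
# (g/L); the other analytes are co-diluted from the stock composition.
seed: 20220726
dilution:
  levels: [100, 50, 40, 30, 20, 11, 9, 7, 5, 3]
  replicates: 3
  stock: {glucose: 100, lactate: 20, glutamine: 8, glutamate: 3}
  profile: {grid_start: 200, grid_end: 3600, grid_increment: 2,
            wavenumber_offset: 0.0, broadening: 1.02, noise_sd: 0.30,
            baseline_degree: 3, baseline_scale: 10, scatter_sd: 0.06,
            name: probe785_V}
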