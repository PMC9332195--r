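# Desk-scale corpus (~10% of full): 30/96/30/15 spectra in 5/8/5/5 batches.
# Enough batches per site that a 70/30 batch split still leaves >= 3 training
# batches for grouped cross-validation.
seed: 20220726
sites:
  - name: site1
    n_batches: 5
    n_spectra: 30
    profile: {grid_start: 100, grid_end: 3425, grid_increment: 1,
              wavenumber_offset: 2.0, broadening: 1.00, noise_sd: 0.25,
              baseline_degree: 3, baseline_scale: 8, scatter_sd: 0.08,
              name: disp785_A1}
  - name: site2
    n_batches: 8
    n_spectra: 96
    profile: {grid_start: 100, grid_end: 3425, grid_increment: 1,
              wavenumber_offset: -1.2, broadening: 1.06, noise_sd: 0.35,
              baseline_degree: 3, baseline_scale: 12, scatter_sd: 0.08,
              name: disp785_A2}
  - name: site3
    n_batches: 5
    n_spectra: 30
    profile: {grid_start: 100, grid_end: 4000, grid_increment: 3,
              wavenumber_offset: 1.0, broadening: 0.97, noise_sd: 0.30,
              baseline_degree: 3, baseline_scale: 10, scatter_sd: 0.10,
              name: compact785_B1}
  - name: site4
    n_batches: 5
    n_spectra: 15
    profile: {grid_start: 100, grid_end: 4000, grid_increment: 3,
              wavenumber_offset: -1.6, broadening: 1.08, noise_sd: 0.40,
              baseline_degree: 3, baseline_scale: 14, scatter_sd: 0.10,
              name: compact785_B2}
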