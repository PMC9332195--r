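# Full-scale synthetic multi-site calibration corpus:
# 305/958/295/148 spectra in 6/22/4/7 batches (1699 spectra total),
# two instrument families on different native grids.
seed: 20220726
sites:
  - name: site1
    n_batches: 6
    n_spectra: 305
    profile: {grid_start: 100, grid_end: 3425, grid_increment: 1,
              wavenumber_offset: 2.0, broadening: 1.00, noise_sd: 0.25,
              baseline_degree: 3, baseline_scale: 8, scatter_sd: 0.08,
              name: disp785_A1}
  - name: site2
    n_batches: 22
    n_spectra: 958
    profile: {grid_start: 100, grid_end: 3425, grid_increment: 1,
              wavenumber_offset: -1.2, broadening: 1.06, noise_sd: 0.35,
              baseline_degree: 3, baseline_scale: 12, scatter_sd: 0.08,
              name: disp785_A2}
  - name: site3
    n_batches: 4
    n_spectra: 295
    profile: {grid_start: 100, grid_end: 4000, grid_increment: 3,
              wavenumber_offset: 1.0, broadening: 0.97, noise_sd: 0.30,
              baseline_degree: 3, baseline_scale: 10, scatter_sd: 0.10,
              name: compact785_B1}
  - name: site4
    n_batches: 7
    n_spectra: 148
    profile: {grid_start: 100, grid_end: 4000, grid_increment: 3,
              wavenumber_offset: -1.6, broadening: 1.08, noise_sd: 0.40,
              baseline_degree: 3, baseline_scale: 14, scatter_sd: 0.10,
              name: compact785_B2}
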