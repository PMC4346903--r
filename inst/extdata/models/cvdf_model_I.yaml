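sbo: CVDF
name: Model I
sigma_fit_reported: 2.14
sites:
- id: Hcvdf1
  logbeta: [5.69, 9.83]
  sd_logbeta: [0.02, 0.03]
  conc_mmol_per_g: 3.0
  sd_conc: 0.4
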