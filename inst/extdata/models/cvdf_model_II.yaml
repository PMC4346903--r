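sbo: CVDF
name: Model II
sigma_fit_reported: 2.55
sites:
- id: Hcvdf1
  logbeta: [5.42, 9.41]
  sd_logbeta: [0.02, 0.04]
  conc_mmol_per_g: 2.6
  sd_conc: 0.2
- id: Hcvdf2
  logbeta: [7.78]
  sd_logbeta: [0.04]
  conc_mmol_per_g: 0.8
  sd_conc: 0.2
- id: Hcvdf3
  logbeta: [10.23]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 0.9
  sd_conc: 0.1
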