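sbo: CVDF
name: Model III
sigma_fit_reported: 1.73
sites:
- id: Hcvdf1
  logbeta: [4.34]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 1.70
  sd_conc: 0.08
- id: Hcvdf2
  logbeta: [6.03]
  sd_logbeta: [0.03]
  conc_mmol_per_g: 1.0
  sd_conc: 0.1
- id: Hcvdf3
  logbeta: [8.33]
  sd_logbeta: [0.04]
  conc_mmol_per_g: 0.7
  sd_conc: 0.1
- id: Hcvdf4
  logbeta: [10.40]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 0.9
  sd_conc: 0.2
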