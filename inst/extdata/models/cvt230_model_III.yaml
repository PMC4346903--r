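sbo: CVT230
name: Model III
sigma_fit_reported: 1.75
sites:
- id: Hcvt1
  logbeta: [3.87]
  sd_logbeta: [0.01]
  conc_mmol_per_g: 1.76
  sd_conc: 0.03
- id: Hcvt2
  logbeta: [5.76]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 1.07
  sd_conc: 0.07
- id: Hcvt3
  logbeta: [8.26]
  sd_logbeta: [0.04]
  conc_mmol_per_g: 0.71
  sd_conc: 0.08
- id: Hcvt4
  logbeta: [10.16]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 1.2
  sd_conc: 0.2
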