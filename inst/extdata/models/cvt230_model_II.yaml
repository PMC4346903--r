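sbo: CVT230
name: Model II
sigma_fit_reported: 3.03
sites:
- id: Hcvt1
  logbeta: [5.10, 8.61]
  sd_logbeta: [0.02, 0.06]
  conc_mmol_per_g: 2.70
  sd_conc: 0.05
- id: Hcvt2
  logbeta: [7.58]
  sd_logbeta: [0.04]
  conc_mmol_per_g: 0.8
  sd_conc: 0.1
- id: Hcvt3
  logbeta: [9.97]
  sd_logbeta: [0.03]
  conc_mmol_per_g: 1.3
  sd_conc: 0.2
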