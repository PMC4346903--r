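sbo: CVT230
name: Model I
sigma_fit_reported: 2.43
sites:
- id: Hcvt1
  logbeta: [5.29, 8.86]
  sd_logbeta: [0.01, 0.04]
  conc_mmol_per_g: 3.0
  sd_conc: 0.1
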