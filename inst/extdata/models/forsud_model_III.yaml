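sbo: FORSUD
name: Model III
sigma_fit_reported: 1.43
sites:
- id: Hforsud1
  logbeta: [4.50]
  sd_logbeta: [0.04]
  conc_mmol_per_g: 1.015
  sd_conc: 0.006
- id: Hforsud2
  logbeta: [6.77]
  sd_logbeta: [0.06]
  conc_mmol_per_g: 0.67
  sd_conc: 0.04
- id: Hforsud3
  logbeta: [9.37]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 1.58
  sd_conc: 0.01
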