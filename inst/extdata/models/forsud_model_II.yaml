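sbo: FORSUD
name: Model II
sigma_fit_reported: 1.80
sites:
- id: Hforsud1
  logbeta: [6.37, 10.65]
  sd_logbeta: [0.05, 0.08]
  conc_mmol_per_g: 1.67
  sd_conc: 0.04
- id: Hforsud2
  logbeta: [9.34]
  sd_logbeta: [0.02]
  conc_mmol_per_g: 1.602
  sd_conc: 0.004
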