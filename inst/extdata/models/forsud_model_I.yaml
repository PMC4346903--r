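sbo: FORSUD
name: Model I
sigma_fit_reported: 1.66
sites:
- id: Hforsud1
  logbeta: [6.12, 10.32]
  sd_logbeta: [0.03, 0.07]
  conc_mmol_per_g: 1.61
  sd_conc: 0.02
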