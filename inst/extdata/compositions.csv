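sbo,ash_pct,pct_C,pct_N,f_aliphatic,f_nr,f_or,f_ar,f_phoy,f_coy,cmc_g_per_L
CVDF,0.56,48.5,5.2,0.31,0.06,0.16,0.23,0.12,0.11,2.76
CVT230,0.81,52.5,5.2,0.28,0.07,0.02,0.22,0.11,0.11,4.2
FORSUD,0.01,57.5,8.8,0.43,0.09,0.15,0.15,0.06,0.13,1.02
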