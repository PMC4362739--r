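treatment,kappa,kappa_sd,kappa_pct_reduction_printed,brightness_iso,brightness_sd,brightness_pct_increase_printed
control,12.71,0.29,NA,25.00,0.056,NA
laccase,9.147,0.21,28.05,26.00,0.028,7.69
lms,6.701,0.28,47.29,28.00,0.016,12.00
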