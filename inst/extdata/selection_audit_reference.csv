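city,n_initial,n_missing_geocoding,n_missing_exposure,n_malformation,n_missing_outcome,printed_n_analysed,printed_pct_linkage,printed_pct_of_initial
Turin,46376,502,195,803,32,44844,98.5,96.7
Bologna,16817,524,157,145,110,15881,96.0,94.4
Modena,9502,16,14,46,5,9421,99.7,99.1
Reggio Emilia,10188,704,140,90,2,9252,91.7,90.8
Rome,144614,6182,3724,2251,2,132455,93.1,91.6
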