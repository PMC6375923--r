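analyte,rsd_r_observed,rsd_R_observed,horwitz_rsd_r,horwitz_rsd_R
CA,1.10,4.34,3.79,5.68
TF1,0.67,3.54,2.92,4.37
TF2,0.26,2.92,2.58,3.86
FL,1.32,4.77,4.23,6.34
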