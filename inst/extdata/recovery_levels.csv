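analyte,level_pct,recovery_pct
CA,75,101.41
CA,100,100.10
CA,125,99.96
VX1,75,99.77
VX1,100,99.55
VX1,125,100.21
VX2,75,100.40
VX2,100,99.02
VX2,125,100.06
RU,75,100.09
RU,100,100.40
RU,125,100.22
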