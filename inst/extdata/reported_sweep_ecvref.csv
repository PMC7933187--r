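muscle_ecv,lesion_ecv,lesion_cic_mM
0.10,0.25,33.5
0.11,0.28,30.5
0.12,0.30,26.8
0.13,0.33,23.0
0.14,0.35,19.3
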