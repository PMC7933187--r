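parameter,value_ms,lesion_tsc_mM,lesion_cic_mM
T1,16,41.2,18.5
T1,24,43.6,22.3
T1,32,47.0,29.6
T1,40,50.9,34.6
T1,48,55.1,41.7
T2s,0.25,57.2,43.8
T2s,0.38,50.3,33.5
T2s,0.5,47.0,29.6
T2s,0.63,44.9,24.4
T2s,1,41.9,22.2
T2l,8,47.3,30.2
T2l,12,47.1,29.8
T2l,16,47.0,29.6
T2l,20,47.0,29.6
T2l,24,47.0,29.6
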