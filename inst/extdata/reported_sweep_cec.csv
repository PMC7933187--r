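c_ec_mM,lesion_cic_mM
130,30.6
135,28.8
140,26.8
145,24.8
150,22.9
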