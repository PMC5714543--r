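patient,structure,d1_ck_gy,d1_vmat_gy
10,cord,21.5,30.1
10,esophagus,24.5,53.2
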