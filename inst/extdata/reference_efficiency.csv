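patient,mu_per_gy_ck,mu_per_gy_vmat,beam_on_min_ck,beam_on_min_vmat,dose_gy,fractions
1,167,68,16.7,11.2,60,3
2,259,58,25.9,11.5,60,3
3,172,65,17.2,14.3,60,3
4,236,61,23.6,10.9,60,3
5,204,60,20.4,12.5,60,3
6,205,46,20.5,8.5,60,3
7,200,53,20.0,10.8,60,3
8,195,46,19.5,8.3,60,3
9,357,54,35.7,10.7,60,3
10,193,82,15.5,14.3,48,6
11,287,55,28.7,9.9,60,3
12,271,88,21.7,13.3,48,6
13,190,57,19.0,10.7,60,3
14,199,54,19.9,9.9,60,3
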