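patient,location,gtv_cc,ptv_ck_cc,ptv_vmat_cc,dose_gy,fractions,motion3d_mm,posterior
1,RUL attached to anterior chest wall,1.2,6.1,11.2,60,3,7.6,FALSE
2,RUL anteriorly located,73.8,118.7,188.1,60,3,22.8,FALSE
3,RUL anteriorly located,7.5,20.3,34.8,60,3,4.6,FALSE
4,RML anteriorly located,2.5,9.2,16.7,60,3,8.5,FALSE
5,RUL anteriorly located,31.7,63.1,88.1,60,3,2.1,FALSE
6,RML anteriorly located,7.8,22.7,40.8,60,3,4.6,FALSE
7,RML anteriorly located,3.7,12.7,21.0,60,3,3.7,FALSE
8,RLL posteriorly located,0.6,4.2,8.2,60,3,6.0,TRUE
9,RLL posteriorly located,4.2,16.7,27.5,60,3,9.2,TRUE
10,LLL posteriorly located proximal to esophagus aorta and cord,77.9,109.0,130.7,48,6,4.0,TRUE
11,RLL posteriorly located,13.0,31.5,46.9,60,3,3.6,TRUE
12,LUL attached to posterior chest wall close to esophagus and aorta,15.4,33.4,60.2,48,6,11.0,TRUE
13,RUL posteriorly located,8.1,23.1,32.8,60,3,7.2,TRUE
14,RLL attached to posterior chest wall,10.2,27.8,53.3,60,3,20.0,TRUE
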