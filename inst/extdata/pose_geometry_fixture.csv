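complex,intermediate,d_cn_c4,delta_theta,ncbe
wt,4PT,0.42,36.7,-42.4
wt,5PT,0.25,-6.7,-33.5
wt,24I,0.49,28.8,-40.0
wt,25I,0.43,36.1,-23.6
E103G/F176A,24I,0.45,35.6,-39.6
E103G/F176A,25I,0.25,-7.6,-35.3
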