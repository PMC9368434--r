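sample,dg_288,dg_303,dg_313,dg_323,dh_288,dh_303,dh_313,dh_323,mean_delta_s,sd_delta_s
NPNS-VD,75.111,78.346,80.907,83.066,9.202,9.077,8.994,8.911,-229.200,0.555
NPNS-VDCa,75.128,78.279,80.861,82.920,10.387,10.262,10.179,10.096,-225.139,0.612
NPNS-Ca,75.014,78.283,80.836,82.962,9.129,9.004,8.921,8.838,-229.165,0.544
NPNS,75.083,78.460,80.960,83.072,8.918,8.793,8.710,8.627,-230.244,0.502
No Palm,75.372,78.407,81.405,83.086,10.105,9.980,9.897,9.814,-226.940,1.103
RB,75.848,79.933,81.918,83.550,12.089,11.965,11.882,11.798,-222.901,1.369
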