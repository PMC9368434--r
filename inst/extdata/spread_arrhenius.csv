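sample,slope,intercept,ea_kJ_mol,k_293,k_298,q10,r_squared,shelf_days_293,shelf_days_298
NPNS-VD,-1394.8,2.9172,11.5963,0.1583,0.1715,1.1584,0.96,59.5,55.0
NPNS-VDCa,-1537.3,3.4057,12.7811,0.1586,0.1732,1.1760,0.95,59.4,54.4
NPNS-Ca,-1386.0,2.9212,11.5232,0.1638,0.1773,1.1574,0.96,59.1,54.6
NPNS,-1360.6,2.7915,11.3120,0.1569,0.1696,1.1543,0.97,59.4,54.9
No Palm,-1503.4,3.189,12.4992,0.1434,0.1563,1.1718,0.79,65.6,60.2
RB,-1742.1,3.6748,14.4838,0.1032,0.1140,1.2016,0.76,107.3,97.1
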