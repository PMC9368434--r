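sample,temperature_K,k,intercept,r_squared,duplicate_flag
NPNS-VD,288.15,0.1428,-6.9104,0.94,FALSE
NPNS-VDCa,288.15,0.1418,-6.845,0.93,FALSE
NPNS-Ca,288.15,0.1487,-6.8993,0.94,FALSE
NPNS,288.15,0.1445,-6.8506,0.92,FALSE
No Palm,288.15,0.1281,-6.7932,0.82,FALSE
RB,288.15,0.105,-7.8284,0.72,FALSE
NPNS-VD,303.15,0.1966,-6.1561,0.86,FALSE
NPNS-VDCa,303.15,0.2019,-6.1671,0.86,FALSE
NPNS-Ca,303.15,0.2016,-6.0942,0.86,FALSE
NPNS,303.15,0.1879,-5.9261,0.87,FALSE
No Palm,303.15,0.1919,-6.0538,0.89,FALSE
RB,303.15,0.1047,-7.3513,0.66,TRUE
NPNS-VD,313.15,0.205,-6.1991,0.95,FALSE
NPNS-VDCa,313.15,0.2087,-6.1843,0.95,FALSE
NPNS-Ca,313.15,0.2107,-6.1757,0.93,FALSE
NPNS,313.15,0.2009,-6.1026,0.95,FALSE
No Palm,313.15,0.1693,-6.0933,0.89,FALSE
RB,313.15,0.1047,-7.3513,0.72,TRUE
NPNS-VD,323.15,0.2479,-6.0102,0.90,FALSE
NPNS-VDCa,323.15,0.2618,-5.9565,0.89,FALSE
NPNS-Ca,323.15,0.2577,-5.9401,0.90,FALSE
NPNS,323.15,0.2474,-6.0628,0.91,FALSE
No Palm,323.15,0.2461,-6.1799,0.91,FALSE
RB,323.15,0.2070,-7.176,0.88,FALSE
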