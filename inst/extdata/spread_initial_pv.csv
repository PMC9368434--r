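sample,a0,measured
NPNS-VD,7.0e-4,FALSE
NPNS-VDCa,7.0e-4,FALSE
NPNS-Ca,7.0e-4,FALSE
NPNS,9.0e-4,TRUE
No Palm,7.0e-4,FALSE
RB,4.9e-4,TRUE
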