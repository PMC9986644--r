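element,background,toxic_response,mdl,DSQS,CSQS,TRV,ASQS
As,4.90,10,0.0003,29.00,12.00,6.00,20.00
Cd,0.30,30,0.004,0.80,1.40,0.60,3.00
Pb,20.00,5,0.070,85.00,70.00,31.00,300.00
Cr,41.00,2,0.013,100.00,64.00,26.00,50.00
Ni,22.00,6,0.013,35.00,50.00,16.00,60.00
Cu,27.00,5,0.030,36.00,63.00,16.00,60.00
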