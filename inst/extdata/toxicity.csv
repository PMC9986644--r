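element,route,rfd,csf
As,ingestion,3.0e-4,1.5
As,dermal,1.23e-4,1.5
As,inhalation,3.0e-4,15.1
Cd,ingestion,1.0e-3,
Cd,dermal,1.0e-5,
Cd,inhalation,1.0e-3,6.3
Pb,ingestion,3.5e-3,8.5e-3
Pb,dermal,5.25e-4,
Pb,inhalation,3.52e-3,
Cr,ingestion,3.0e-3,
Cr,dermal,6.0e-5,
Cr,inhalation,2.86e-5,42
Ni,ingestion,2.0e-2,
Ni,dermal,5.4e-3,
Ni,inhalation,2.06e-2,0.84
Cu,ingestion,4.0e-2,
Cu,dermal,1.2e-2,
Cu,inhalation,4.02e-2,
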