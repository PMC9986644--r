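table,land_use,element,value,label
cf,PA,As,1.74,
cf,PA,Cd,2.83,
cf,PA,Pb,0.34,
cf,PA,Cr,0.95,
cf,PA,Ni,0.59,
cf,PA,Cu,0.58,
cf,PG,As,1.61,
cf,PG,Cd,2.58,
cf,PG,Pb,0.43,
cf,PG,Cr,0.74,
cf,PG,Ni,0.71,
cf,PG,Cu,0.62,
cf,M,As,1.05,
cf,M,Cd,3.26,
cf,M,Pb,1.22,
cf,M,Cr,1.19,
cf,M,Ni,0.42,
cf,M,Cu,1.19,
cf,BF,As,2.07,
cf,BF,Cd,3.62,
cf,BF,Pb,1.44,
cf,BF,Cr,0.98,
cf,BF,Ni,0.94,
cf,BF,Cu,1.24,
cf,IA,As,1.36,
cf,IA,Cd,4.03,
cf,IA,Pb,3.92,
cf,IA,Cr,0.72,
cf,IA,Ni,0.75,
cf,IA,Cu,0.71,
cf,PP,As,1.39,
cf,PP,Cd,3.14,
cf,PP,Pb,0.77,
cf,PP,Cr,0.82,
cf,PP,Ni,0.46,
cf,PP,Cu,1.05,
cf,MW,As,2.32,
cf,MW,Cd,6.84,
cf,MW,Pb,3.22,
cf,MW,Cr,0.82,
cf,MW,Ni,2.34,
cf,MW,Cu,4.62,
cf,BS,As,1.42,
cf,BS,Cd,4.16,
cf,BS,Pb,1.39,
cf,BS,Cr,1.00,
cf,BS,Ni,0.65,
cf,BS,Cu,1.56,
cf,PS,As,1.58,
cf,PS,Cd,3.14,
cf,PS,Pb,0.47,
cf,PS,Cr,0.92,
cf,PS,Ni,0.78,
cf,PS,Cu,0.97,
cf,RA,As,1.15,
cf,RA,Cd,2.01,
cf,RA,Pb,0.20,
cf,RA,Cr,0.14,
cf,RA,Ni,0.46,
cf,RA,Cu,0.46,
cf,WDA,As,1.27,
cf,WDA,Cd,4.15,
cf,WDA,Pb,1.49,
cf,WDA,Cr,0.94,
cf,WDA,Ni,0.86,
cf,WDA,Cu,1.22,
cd,PA,,7.03,Moderate
cd,PG,,6.69,Moderate
cd,M,,8.33,Moderate
cd,BF,,10.29,Considerable
cd,IA,,11.49,Considerable
cd,PP,,7.63,Moderate
cd,MW,,20.16,High
cd,BS,,10.18,Considerable
cd,PS,,7.86,Moderate
cd,RA,,4.42,Low
cd,WDA,,9.93,Moderate
igeo,PA,As,0.22,
igeo,PA,Cd,0.92,
igeo,PA,Pb,-2.15,
igeo,PA,Cr,-0.66,
igeo,PA,Ni,-1.34,
igeo,PA,Cu,-1.37,
igeo,PG,As,0.11,
igeo,PG,Cd,0.78,
igeo,PG,Pb,-1.80,
igeo,PG,Cr,-1.01,
igeo,PG,Ni,-1.07,
igeo,PG,Cu,-1.27,
igeo,M,As,-0.51,
igeo,M,Cd,1.12,
igeo,M,Pb,-0.29,
igeo,M,Cr,-0.34,
igeo,M,Ni,-1.83,
igeo,M,Cu,-0.33,
igeo,BF,As,0.47,
igeo,BF,Cd,1.27,
igeo,BF,Pb,-0.06,
igeo,BF,Cr,-0.61,
igeo,BF,Ni,-0.67,
igeo,BF,Cu,-0.27,
igeo,IA,As,-0.14,
igeo,IA,Cd,1.42,
igeo,IA,Pb,1.39,
igeo,IA,Cr,-1.06,
igeo,IA,Ni,-1.00,
igeo,IA,Cu,-1.07,
igeo,PP,As,-0.11,
igeo,PP,Cd,1.07,
igeo,PP,Pb,-0.95,
igeo,PP,Cr,-0.87,
igeo,PP,Ni,-1.72,
igeo,PP,Cu,-0.51,
igeo,MW,As,0.63,
igeo,MW,Cd,2.19,
igeo,MW,Pb,1.10,
igeo,MW,Cr,-0.88,
igeo,MW,Ni,0.64,
igeo,MW,Cu,1.62,
igeo,BS,As,-0.08,
igeo,BS,Cd,1.47,
igeo,BS,Pb,-0.10,
igeo,BS,Cr,-0.58,
igeo,BS,Ni,-1.21,
igeo,BS,Cu,0.05,
igeo,PS,As,0.08,
igeo,PS,Cd,1.07,
igeo,PS,Pb,-1.66,
igeo,PS,Cr,-0.70,
igeo,PS,Ni,-0.95,
igeo,PS,Cu,-0.63,
igeo,RA,As,-0.37,
igeo,RA,Cd,0.42,
igeo,RA,Pb,-2.87,
igeo,RA,Cr,-3.39,
igeo,RA,Ni,-1.70,
igeo,RA,Cu,-1.69,
igeo,WDA,As,-0.23,
igeo,WDA,Cd,1.47,
igeo,WDA,Pb,-0.01,
igeo,WDA,Cr,-0.67,
igeo,WDA,Ni,-0.80,
igeo,WDA,Cu,-0.30,
er,PA,As,17.46,
er,PA,Cd,85.0,
er,PA,Pb,1.69,
er,PA,Cr,1.89,
er,PA,Ni,3.54,
er,PA,Cu,2.90,
er,PG,As,16.14,
er,PG,Cd,77.5,
er,PG,Pb,2.15,
er,PG,Cr,1.48,
er,PG,Ni,4.29,
er,PG,Cu,3.11,
er,M,As,10.52,
er,M,Cd,97.75,
er,M,Pb,6.12,
er,M,Cr,2.38,
er,M,Ni,2.53,
er,M,Cu,5.95,
er,BF,As,20.74,
er,BF,Cd,108.63,
er,BF,Pb,7.22,
er,BF,Cr,1.96,
er,BF,Ni,5.64,
er,BF,Cu,6.20,
er,IA,As,13.64,
er,IA,Cd,120.75,
er,IA,Pb,19.59,
er,IA,Cr,1.44,
er,IA,Ni,4.50,
er,IA,Cu,3.56,
er,PP,As,13.90,
er,PP,Cd,94.25,
er,PP,Pb,3.87,
er,PP,Cr,1.64,
er,PP,Ni,2.74,
er,PP,Cu,5.27,
er,MW,As,23.24,
er,MW,Cd,205.13,
er,MW,Pb,16.09,
er,MW,Cr,1.63,
er,MW,Ni,14.05,
er,MW,Cu,23.09,
er,BS,As,14.20,
er,BS,Cd,124.67,
er,BS,Pb,6.97,
er,BS,Cr,2.01,
er,BS,Ni,3.89,
er,BS,Cu,7.79,
er,PS,As,15.85,
er,PS,Cd,94.25,
er,PS,Pb,2.37,
er,PS,Cr,1.85,
er,PS,Ni,4.66,
er,PS,Cu,4.85,
er,RA,As,11.57,
er,RA,Cd,60.25,
er,RA,Pb,1.02,
er,RA,Cr,0.29,
er,RA,Ni,2.77,
er,RA,Cu,2.32,
er,WDA,As,12.80,
er,WDA,Cd,124.40,
er,WDA,Pb,7.44,
er,WDA,Cr,1.88,
er,WDA,Ni,5.18,
er,WDA,Cu,6.09,
peri,PA,,112.49,Moderate
peri,PG,,104.67,Moderate
peri,M,,125.25,Moderate
peri,BF,,150.39,Considerable
peri,IA,,163.49,Considerable
peri,PP,,121.68,Moderate
peri,MW,,283.22,Very high
peri,BS,,159.53,Considerable
peri,PS,,123.84,Moderate
peri,RA,,78.23,Moderate
peri,WDA,,157.78,Considerable
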