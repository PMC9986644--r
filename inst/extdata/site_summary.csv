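land_use,n,element,mean,sd,min,max
PA,3,As,8.56,4.32,3.32,13.90
PA,3,Cd,0.85,0.18,0.70,1.05
PA,3,Pb,6.78,6.48,1.16,13.87
PA,3,Cr,38.85,18.27,20.09,56.58
PA,3,Ni,12.99,6.23,5.98,17.88
PA,3,Cu,15.64,7.03,9.13,23.10
PG,8,As,7.91,3.61,2.13,13.86
PG,8,Cd,0.78,0.40,0.10,1.20
PG,8,Pb,8.60,4.19,2.74,15.34
PG,8,Cr,30.44,9.70,18.03,43.01
PG,8,Ni,15.72,6.31,5.32,23.10
PG,8,Cu,16.79,6.18,5.58,28.35
M,8,As,5.15,2.31,1.80,8.88
M,8,Cd,0.98,0.45,0.30,1.80
M,8,Pb,24.50,10.44,11.37,38.93
M,8,Cr,48.75,16.52,17.09,72.09
M,8,Ni,9.29,4.18,2.19,14.23
M,8,Cu,32.14,9.61,11.91,43.14
BF,8,As,10.16,3.27,4.60,14.50
BF,8,Cd,1.09,0.61,0.23,2.10
BF,8,Pb,28.87,10.65,13.79,45.76
BF,8,Cr,40.24,14.52,12.01,59.09
BF,8,Ni,20.68,7.54,7.18,29.11
BF,8,Cu,33.48,8.70,14.51,44.10
IA,4,As,6.69,3.01,3.76,11.54
IA,4,Cd,1.21,0.58,0.70,2.03
IA,4,Pb,78.36,35.04,34.58,113.26
IA,4,Cr,29.51,7.39,21.04,37.09
IA,4,Ni,16.50,5.78,8.10,21.30
IA,4,Cu,19.25,3.98,15.10,24.30
PP,8,As,6.81,2.75,2.45,11.21
PP,8,Cd,0.94,0.31,0.30,1.20
PP,8,Pb,15.48,9.44,5.66,28.70
PP,8,Cr,33.69,10.58,19.77,50.08
PP,8,Ni,10.05,5.28,2.10,18.88
PP,8,Cu,28.47,14.03,10.24,52.15
MW,8,As,11.39,4.23,5.99,18.09
MW,8,Cd,2.05,0.84,1.02,3.58
MW,8,Pb,64.36,27.69,33.10,102.78
MW,8,Cr,33.45,14.62,15.02,55.12
MW,8,Ni,51.52,12.03,29.89,68.23
MW,8,Cu,124.67,48.49,65.97,212.57
BS,3,As,6.96,4.40,2.13,12.78
BS,3,Cd,1.25,0.86,0.40,2.11
BS,3,Pb,27.90,15.02,13.68,43.60
BS,3,Cr,41.15,19.11,24.55,62.04
BS,3,Ni,14.27,4.41,9.19,17.13
BS,3,Cu,42.04,24.38,21.82,69.12
PS,8,As,7.77,3.90,2.56,14.69
PS,8,Cd,0.94,0.64,0.10,1.87
PS,8,Pb,9.49,6.29,2.07,19.06
PS,8,Cr,37.88,12.96,13.99,58.09
PS,8,Ni,17.09,6.98,3.19,25.87
PS,8,Cu,26.18,11.52,4.23,42.11
RA,8,As,5.67,2.72,1.90,10.70
RA,8,Cd,0.60,0.35,0.10,1.03
RA,8,Pb,4.09,4.30,0.40,12.09
RA,8,Cr,5.87,4.73,0.90,12.09
RA,8,Ni,10.17,5.00,2.98,18.23
RA,8,Cu,12.53,7.89,3.82,28.30
WDA,5,As,6.27,2.49,3.66,10.87
WDA,5,Cd,1.24,0.56,0.69,2.01
WDA,5,Pb,29.75,11.20,12.09,41.01
WDA,5,Cr,38.54,13.47,18.03,55.08
WDA,5,Ni,19.00,8.14,11.94,32.12
WDA,5,Cu,32.88,10.87,22.89,51.32
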