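system,model,T_K,parameter,value
ZnCl2,mono_ideal,285,n,0.75
ZnCl2,mono_ideal,285,P_M,299.2
ZnCl2,mono_ideal,285,c_half,0.007
ZnCl2,mono_ideal,290,n,0.84
ZnCl2,mono_ideal,290,P_M,351.6
ZnCl2,mono_ideal,290,c_half,0.008
ZnCl2,mono_ideal,295,n,0.91
ZnCl2,mono_ideal,295,P_M,379.5
ZnCl2,mono_ideal,295,c_half,0.009
ZnCl2,mono_ideal,300,n,0.94
ZnCl2,mono_ideal,300,P_M,421.4
ZnCl2,mono_ideal,300,c_half,0.008
NiCl2,mono_real,285,n,0.55
NiCl2,mono_real,285,P_M,239.6
NiCl2,mono_real,285,w_half,0.006
NiCl2,mono_real,285,a,9.9e-09
NiCl2,mono_real,285,b,1.4e-12
NiCl2,mono_real,290,n,0.64
NiCl2,mono_real,290,P_M,259.2
NiCl2,mono_real,290,w_half,0.0067
NiCl2,mono_real,290,a,8.2e-09
NiCl2,mono_real,290,b,2.1e-12
NiCl2,mono_real,295,n,0.72
NiCl2,mono_real,295,P_M,317.5
NiCl2,mono_real,295,w_half,0.0073
NiCl2,mono_real,295,a,7.6e-09
NiCl2,mono_real,295,b,3.8e-12
NiCl2,mono_real,300,n,0.84
NiCl2,mono_real,300,P_M,355.2
NiCl2,mono_real,300,w_half,0.0069
NiCl2,mono_real,300,a,7.13e-09
NiCl2,mono_real,300,b,4.4e-12
CrCl2,double_ideal,285,n,0.41
CrCl2,double_ideal,285,P_M,147.9
CrCl2,double_ideal,285,c1,0.0029
CrCl2,double_ideal,285,c2,0.026
CrCl2,double_ideal,290,n,0.52
CrCl2,double_ideal,290,P_M,184.8
CrCl2,double_ideal,290,c1,0.0032
CrCl2,double_ideal,290,c2,0.025
CrCl2,double_ideal,295,n,0.64
CrCl2,double_ideal,295,P_M,239.5
CrCl2,double_ideal,295,c1,0.0034
CrCl2,double_ideal,295,c2,0.024
CrCl2,double_ideal,300,n,0.73
CrCl2,double_ideal,300,P_M,279.4
CrCl2,double_ideal,300,c1,0.0031
CrCl2,double_ideal,300,c2,0.025
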