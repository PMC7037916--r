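compound_id,name,p_ec50,p_loec,composite_printed,split,flag
PIP,Pipemidic acid,-4.59,4.80,-0.94,train,
CIN,Cinoxacin,-2.24,6.52,-0.17,test,
NOR,Norfloxacin,-3.64,7.67,-0.48,train,
BAL,Balofloxacin,-2.83,7.31,-0.28,test,
CIP,Ciprofloxacin,-3.45,7.85,-0.41,train,
DAN,Danofloxacin,-3.17,7.66,-0.35,train,
DIF,Difloxacin,-2.64,8.06,-0.17,test,
ENR,Enrofloxacin,-3.00,8.75,-0.23,train,
FLE,Fleroxacin,-3.46,6.77,-0.49,train,
GAT,Gatifloxacin,-3.16,8.28,-0.30,train,
LOM,Lomefloxacin,-3.26,7.54,-0.38,train,
MOX,Moxifloxacin,-0.32,8.89,0.53,train,
NAD,Nadifloxacin,-1.62,8.08,0.11,train,
OFL,Ofloxacin,-3.62,7.96,-0.45,train,
PAZ,Pazufloxacin,-3.52,8.54,-0.38,test,
RUF,Rufloxacin,-3.55,6.89,-0.51,train,
SAR,Sarafloxacin,-2.77,7.92,-0.22,train,
SPA,Sparfloxacin,-3.44,7.37,-0.44,test,
LEV,Levofloxacin,-3.62,7.75,-0.47,train,
ENO,Enoxacin,-3.58,7.08,-0.50,test,
PEF,Pefloxacin,-3.51,7.96,-0.42,train,
AMI,Amifloxacin,-4.39,8.00,-0.66,test,
BES,Besifloxacin,-2.43,7.50,-0.15,test,
CLI,Clinafloxacin,-3.08,7.19,-0.36,train,
GRE,Grepafloxacin,-2.81,7.47,-0.26,train,
MAR,Marbofloxacin,-4.26,8.46,-0.60,train,
ORB,Orbifloxacin,-2.67,7.51,-0.22,test,
SIT,Sitafloxacin,-2.69,7.28,-0.24,test,
TEM,Temafloxacin,-2.38,8.47,-0.07,train,
1-CH3-PAZ,1-CH3-PAZ,-0.98,8.05,0.29,train,
1-H-PAZ,1-H-PAZ,-1.27,7.67,0.18,train,
5-OH-PAZ,5-OH-PAZ,-4.87,8.38,-0.77,train,
5-F-PAZ,5-F-PAZ,-3.90,7.57,-0.56,train,
1-C2H3-5-F-PAZ,1-C2H3-5-F-PAZ,-1.14,7.13,0.18,train,
1-CO-5-OH-PAZ,1-CO-5-OH-PAZ,-3.39,7.72,-0.41,train,
1-CO-5-F-PAZ,1-CO-5-F-PAZ,-2.42,7.14,-0.18,train,
7-OH-CIP,7-OH-CIP,-4.53,8.25,-0.69,train,
7-C2H5-CIP,7-C2H5-CIP,-2.85,7.98,-0.24,train,
7-CN-CIP,7-CN-CIP,-3.86,8.07,-0.51,train,
7-NO-CIP,7-NO-CIP,-3.66,8.14,-0.45,train,
7-OCH3-CIP,7-OCH3-CIP,-3.68,8.38,-0.44,train,
7-C2H3-CIP,7-C2H3-CIP,-2.94,8.34,-0.24,train,
7-COOH-CIP,7-COOH-CIP,-4.70,8.31,-0.73,train,
9-F-NAD,9-F-NAD,-1.73,8.33,0.10,train,
9-Cl-NAD,9-Cl-NAD,-1.53,8.32,0.15,train,
9-Br-NAD,9-Br-NAD,-1.52,8.28,0.15,train,
2-C2H3-NAD,2-C2H3-NAD,-1.02,8.32,0.29,train,
2-C2H3-9-F-NAD,2-C2H3-9-F-NAD,-1.13,8.18,0.25,train,
2-C2H-9-F-NAD,2-C2H-9-F-NAD,-1.57,8.29,0.14,train,
2-C2H3-9-Cl-NAD,2-C2H3-9-Cl-NAD,-1.37,8.29,-0.17,train,inconsistent
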