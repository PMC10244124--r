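[states]
IR 1 INSR
IRp 0 INSR
PKB 1 AKT1
PKBp 0 AKT1
ACp 0 ADCY3
cAMP 0.1 -
PDE3Bp 0 PDE3B
HSLp 0 LIPE
GLUT4 1 SLC2A4
GLUT4m 0 SLC2A4
[parameters]
k_ir 0.3 0.0001 10000
kd_ir 0.1 0.0001 10000
k_pkb 1 0.0001 10000
kd_pkb 0.3 0.0001 10000
k_ac 1 0.0001 10000
kd_ac 0.3 0.0001 10000
k_camp 0.5 0.0001 10000
kd_camp 0.3 0.0001 10000
k_pde 3 0.0001 10000
k_pde3b 0.5 0.0001 10000
kd_pde3b 0.2 0.0001 10000
k_hsl 1 0.0001 10000
kd_hsl 0.3 0.0001 10000
k_g4 0.15 0.0001 10000
kd_g4 0.05 0.0001 10000
s_glu 50 0 100
s_lip 1 0 100
s_exo 1 0 100
[rates]
IR = -k_ir*insulin*IR + kd_ir*IRp
IRp = k_ir*insulin*IR - kd_ir*IRp
PKB = -k_pkb*IRp*PKB + kd_pkb*PKBp
PKBp = k_pkb*IRp*PKB - kd_pkb*PKBp
ACp = k_ac*adrenaline*(1-ACp) - kd_ac*ACp
cAMP = k_camp*ACp + 0.03 - kd_camp*cAMP - k_pde*PDE3Bp*cAMP
PDE3Bp = k_pde3b*PKBp*(1-PDE3Bp) - kd_pde3b*PDE3Bp
HSLp = k_hsl*cAMP*(1-HSLp) - kd_hsl*HSLp
GLUT4 = -k_g4*PKBp*GLUT4 + kd_g4*GLUT4m
GLUT4m = k_g4*PKBp*GLUT4 - kd_g4*GLUT4m
[inputs]
insulin 1 0:60
adrenaline 0 0:60
[observables]
IR_active = 1 * IRp
PKB_activity = 1 * PKBp
AC_activity = 1 * ACp
cAMP_level = 1 * cAMP
PDE3B_activity = 1 * PDE3Bp
HSL_phospho = 1 * HSLp
glucose_uptake = s_glu * GLUT4m
lipolysis = s_lip * HSLp
exocytosis = s_exo * cAMP
[activity]
INSR IR_active
AKT1 PKB_activity
ADCY3 AC_activity
PDE3B PDE3B_activity
LIPE HSL_phospho
SLC2A4 glucose_uptake
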