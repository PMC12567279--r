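name,value,units
molecular_weight,324.39,g/mol
logp,1.34,
pka,9.5,
blood_to_plasma,2.0,
fu_plasma,0.44,
f_absorbed,1.0,
k_absorption,0.19,1/h
fu_gut,1.0,
q_gut,5.69,L/h
kp_scalar,0.92,
clint_cyp2c19,0.774,uL/min/pmol
clint_cyp2d6,0.505,uL/min/pmol
clint_cyp3a4,0.0155,uL/min/pmol
cl_renal_adult,4.0,L/h
cl_pdm,0.80902,L/h
cl_pdf,0.80902,L/h
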