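name,baseline,b1,b2,b3,b4,units
cyp2c19_activity,1,0,0,0,0,ratio
cyp2d6_activity,1,0.0163,0.0009,0,0,ratio
cyp3a4_activity,1,0.0129,0.0005,0,0,ratio
cardiac_output,1,0.02,-0.0003,0,0,ratio
gfr,1,0.035,-0.0006,0,0,ratio
binding_protein,1,-0.0045,0,0,0,ratio
plasma_volume,1,0,0.00028,0,0,ratio
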