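name,value,units
body_weight,60,kg
cardiac_output,300,L/h
gfr,121,mL/min
hematocrit,0.40,
liver_weight,1500,g
mppgl,40,mg/g
abundance_cyp2c19,14,pmol/mg
abundance_cyp2d6,8,pmol/mg
abundance_cyp3a4,137,pmol/mg
gut_cyp3a4_total,70000,pmol
volume_adipose,19.5,L
volume_bone,6,L
volume_brain,1.3,L
volume_gut,1.1,L
volume_heart,0.30,L
volume_kidney,0.28,L
volume_liver,1.5,L
volume_lung,0.5,L
volume_muscle,17.5,L
volume_skin,2.6,L
volume_spleen,0.18,L
volume_rest,3.0,L
volume_plasma,2.4,L
flowfrac_adipose,0.085,
flowfrac_bone,0.05,
flowfrac_brain,0.12,
flowfrac_gut,0.15,
flowfrac_heart,0.05,
flowfrac_kidney,0.17,
flowfrac_hepatic_artery,0.065,
flowfrac_muscle,0.12,
flowfrac_skin,0.05,
flowfrac_spleen,0.03,
flowfrac_rest,0.11,
fetal_weight_term,3.7,kg
amniotic_volume_term,0.75,L
fetal_plasma_volume_per_kg,0.08,L/kg
placenta_volume,0.5,L
fetal_protein_ratio,0.37,
fetal_swallowed_volume,750,mL/day
fetal_gfr,4.92,mL/min
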