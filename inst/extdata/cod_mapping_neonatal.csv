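cause,group
sepsis,1
infections,1
meningitis,1
pneumonia,1
tetanus,1
diarrhoea,1
prematurity,2
intrauterine_growth_restriction,2
intrapartum,3
birth_asphyxia,3
birth_trauma,3
congenital,other
other,other
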