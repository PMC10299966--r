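cause,group
infections,1
syphilis,1
malaria,1
maternal_conditions,2
fetal_growth_restriction,2
placental_disorders,2
intrapartum,3
other,other
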