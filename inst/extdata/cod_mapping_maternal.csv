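cause,group
abortion_complications,1
sepsis,1
indirect,2
haemorrhage,3
hypertensive_disorders,3
obstructed_labour,3
embolism,3
other_direct,other
other,other
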