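source,class,count
V_R1,0,52
V_R1,1,8
V_R2,0,37
V_R2,1,23
V_R1R2,0,45
V_R1R2,1,15
Rc,0,44
Rc,1,16
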