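,CAF,TAM,Cancer,Tcell,Bcell,EC
CAF,7.9,9.2,5.1,2.8,1.6,3.9
TAM,4.1,1.8,3.4,2.2,0.9,1.1
Cancer,5.6,6.3,4.8,1.2,0.4,2.7
Tcell,0.8,1.4,0.6,0.9,1.0,0.2
Bcell,0.3,0.9,0.2,1.1,0.4,0.1
EC,1.2,1.0,0.8,0.3,0.2,0.6
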