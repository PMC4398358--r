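case_study,machine,characteristic,lwa,p_on,p_off,p_idle,label
1,Exhaust pipe,S,103.9,0.9,0.0,0.1,S1
1,Generator,S,119.7,0.9,0.0,0.1,S2
1,Oil purifier,S,105.0,0.9,0.0,0.1,S3
1,Conveyor 1,S,105.0,0.9,0.0,0.1,S4
1,Conveyor 2,S,109.2,0.9,0.0,0.1,S5
1,Silo fan 1,S,106.5,0.5,0.5,0.0,S6
1,Silo fan 2,S,106.5,0.5,0.5,0.0,S7
1,Narrow gauges,EM,96.8,0.7,0.0,0.3,D1
2,Piling machine,EM,111.1,0.3,0.1,0.6,D2
3,Excavator,EM,98.8,0.7,0.0,0.3,D3
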