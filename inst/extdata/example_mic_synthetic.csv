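strain,agent,concentration_mM,growth
G18,AgNO3,0.1,1
G18,AgNO3,0.3,0
G18,AgNO3,0.5,0
G18,AgNO3,1.0,0
G18,CuCl2,0.1,1
G18,CuCl2,0.3,1
G18,CuCl2,0.5,1
G18,CuCl2,1.0,1
G18,CuCl2,2.0,0
G18,CuCl2,4.0,0
G18,NiCl2,0.5,1
G18,NiCl2,1.0,1
G18,NiCl2,2.0,1
G18,NiCl2,4.0,1
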