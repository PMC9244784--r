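substance,unit,per_kg_n,per_m3_water
CO2,kg,8.3,0.55
CH4,kg,0.012,0.0008
N2O,kg,0.0226,0
NH3,kg,0.12,0
NOx,kg,0.012,0.002
SO2,kg,0.02,0.003
NO3,kg,0.24,0
PM2.5,kg,0.004,0.0003
NMVOC,kg,0.003,0.0002
primary_energy,MJ,52,6.5
antimony,kg,0.00001,0.0000012
toxicant,kg,0.9,0.004
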