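substance,unit,GWP,PED,AP,ADP,EP,RI,POFP,ETx
unit,,kg CO2 eq,MJ,kg SO2 eq,kg antimony eq,kg P3O4 eq,kg PM2.5 eq,kg NMVOC eq,CTUe
CO2,kg,1,0,0,0,0,0,0,0
CH4,kg,28,0,0,0,0,0,0.014,0
N2O,kg,265,0,0,0,0,0,0,0
NH3,kg,0,0,1.88,0,0.35,0.64,0,0
NOx,kg,0,0,0.7,0,0.13,0.88,1,0
SO2,kg,0,0,1,0,0,0.54,0.081,0
NO3,kg,0,0,0,0,0.42,0,0,0
PM2.5,kg,0,0,0,0,0,1,0,0
NMVOC,kg,0,0,0,0,0,0,1,0
primary_energy,MJ,0,1,0,0,0,0,0,0
antimony,kg,0,0,0,1,0,0,0,0
toxicant,kg,0,0,0,0,0,0,0,1
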