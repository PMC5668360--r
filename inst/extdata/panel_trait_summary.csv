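trait,scale,mean,sd
GrowthHabit,visual 1-9,2.4,1.0
LeafWidth,visual 1-9,4.8,1.4
Biomass,visual 1-9,6.9,1.3
NDVI,NDVI,0.68,0.1
Yellows,visual 1-9,1.7,0.9
Maturity,Zadoks scale,53,5.7
Greenness,visual 1-9,5.7,1.5
Glaucousness,visual 1-9,3.5,2.0
LeafLoss,visual 1-9,4.6,1.7
PlantHeight,visual 1-9,5.2,1.1
GrainYield,kg/ha,5124,655
TestWeight,kg/hl,84.4,1.8
TKW,g,37.5,4.6
GrainProtein,percent,11.1,0.9
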