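trait,Biomass,Glaucousness,GrainProtein,GrainYield,Greenness,GrowthHabit,PlantHeight,LeafLoss,LeafWidth,Maturity,NDVI,TestWeight,TKW,Yellows
Biomass,1,-0.24,-0.39,0.49,-0.44,-0.45,0.1,0.69,0.49,0.76,0.51,0.15,0.19,-0.34
Glaucousness,-0.18,1,0.41,-0.01,0.73,-0.23,-0.04,-0.41,0.24,-0.3,-0.28,-0.04,0.13,0.41
GrainProtein,-0.14,0.15,1,-0.55,0.5,0.1,0.02,-0.4,-0.08,-0.39,-0.34,-0.22,-0.23,0.35
GrainYield,0.27,-0.03,-0.3,1,0.06,-0.06,0.11,0.01,0.1,0.19,0.16,0.28,0.23,-0.19
Greenness,-0.14,0.23,0.22,-0.15,1,-0.14,-0.05,-0.61,0.02,-0.43,-0.45,-0.02,-0.01,0.49
GrowthHabit,-0.15,0.07,0.2,-0.3,0.11,1,0.15,-0.36,-0.59,-0.48,0.25,-0.1,-0.3,-0.25
PlantHeight,0.19,-0.14,-0.04,-0.27,-0.08,0.05,1,-0.1,-0.01,-0.1,0.12,0.09,-0.04,-0.16
LeafLoss,0.32,-0.16,-0.22,0.28,-0.26,-0.23,-0.05,1,0.33,0.75,0.31,0.1,0.23,-0.18
LeafWidth,0.22,-0.04,-0.05,0.3,-0.03,-0.11,0.06,0.13,1,0.43,0.04,0.05,0.37,0.09
Maturity,0.42,-0.19,-0.3,0.36,-0.19,-0.32,0.01,0.45,0.19,1,0.24,0.24,0.29,-0.2
NDVI,0.34,-0.13,-0.01,0.43,-0.1,0.12,0.2,0.14,0.05,0.08,1,0.04,0.06,-0.51
TestWeight,0.12,-0.1,-0.43,0.29,-0.09,-0.17,0.01,0.02,0.02,0.21,0.12,1,0.37,0
TKW,0.14,-0.08,-0.33,0.39,-0.08,-0.2,0.06,0.12,0.15,0.35,-0.06,0.52,1,0.11
Yellows,-0.11,0.04,0,-0.25,-0.04,-0.07,-0.15,0.06,-0.01,-0.06,-0.04,-0.01,-0.05,1
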