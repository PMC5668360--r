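trait,H2_baseline,logL_baseline,H2_genomic,h2_genomic,logL_genomic,additive_proportion
Biomass,0.56,-4113,0.75,0.56,-2401,75
Glaucousness,0.81,-12424,0.89,0.76,-8370,86
GrainProtein,0.57,-1119,0.75,0.62,1517,82
GrainYield,0.44,-76861,0.63,0.45,-75322,72
Greenness,0.64,-9271,0.75,0.58,-6479,77
GrowthHabit,0.71,-4148,0.89,0.78,-1781,88
PlantHeight,0.74,-5212,0.91,0.81,-2655,89
LeafLoss,0.67,-10067,0.83,0.69,-7648,82
LeafWidth,0.71,-7888,0.86,0.75,-4674,87
Maturity,0.92,-24045,0.98,0.91,-20562,93
NDVI,0.45,25269,0.62,0.36,26160,58
TestWeight,0.75,-10566,0.91,0.82,-7546,90
TKW,0.79,-21047,0.93,0.85,-17076,91
Yellows,0.73,-3662,0.82,0.53,-2418,65
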