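trait,genomic_additive,genomic_total,qtl1_additive,qtl1_total,qtl5_additive,qtl5_total
Biomass,0.97,0.72,0.26,0.20,0.46,0.48
Glaucousness,0.98,0.82,0.49,0.45,0.76,0.68
GrainProtein,0.97,0.84,0.16,0.16,0.59,0.54
GrainYield,0.97,0.71,0.19,0.16,0.64,0.51
Greenness,0.98,0.80,0.54,0.44,0.78,0.65
GrowthHabit,0.96,0.75,0.36,0.30,0.59,0.50
PlantHeight,0.96,0.76,0.28,0.24,0.48,0.43
LeafLoss,0.97,0.77,0.41,0.37,0.55,0.54
LeafWidth,0.98,0.81,0.26,0.24,0.54,0.46
Maturity,0.96,0.77,0.26,0.25,0.59,0.55
NDVI,0.96,0.56,0.20,0.15,0.42,0.31
TestWeight,0.96,0.80,0.10,0.11,0.43,0.39
TKW,0.97,0.85,0.38,0.33,0.52,0.49
Yellows,0.97,0.55,0.17,0.15,0.63,0.41
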