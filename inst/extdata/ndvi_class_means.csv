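code,name,mean
1,remnant_forest,0.79
2,savanna,0.53
3,farmland,0.584
4,coffee_plantation,0.83
5,disturbed_forest,0.75
6,grassland,0.71
7,wetland,0.74
8,builtup,0.20
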