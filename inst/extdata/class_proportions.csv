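code,name,proportion
1,remnant_forest,0.3098
2,savanna,0.2447
3,farmland,0.1923
4,coffee_plantation,0.08
5,disturbed_forest,0.0653
6,grassland,0.0608
7,wetland,0.0435
8,builtup,0.0037
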