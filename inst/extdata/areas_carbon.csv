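class,area_ha
remnant_forest,146251.59
disturbed_forest,30832.15
coffee_plantation,37768.27
savanna,28720.98
grassland,28720.98
wetland,20513.97
farmland,90778.37
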