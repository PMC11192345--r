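class,area_ha
remnant_forest,146929.5
disturbed_forest,28241.54
coffee_plantation,41893.27
savanna,113093.5
grassland,26716.23
wetland,18396.11
farmland,94844.59
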