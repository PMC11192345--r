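class,carbon_stock_t_ha
wetland,279.5
remnant_forest,461
disturbed_forest,396
coffee_plantation,259.4
savanna,286.8
grassland,286.8
farmland,246.5
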