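class,service,original_value,adjusted_value
remnant_forest,honey,76,85.74
disturbed_forest,forest_products,196,221.11
coffee_plantation,coffee_production,3423.57,3423.57
wetland,livestock_food_water_mulching,839.98,1102.24
farmland,crop_production,638,719.75
savanna,livestock_feed_forage,41.73,41.73
grassland,livestock_feed,11.62,12.16
grassland,forage,0.204,0.23
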