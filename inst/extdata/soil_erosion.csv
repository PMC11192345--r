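class,production_cost_usd_ha_yr,sediment_cost_usd_ha_yr,original_value,adjusted_value
remnant_forest,4,64.5,68.5,84.31
disturbed_forest,3.87,62.3,66.17,81.39
coffee_plantation,1.08,17.44,18.52,22.78
savanna,3.94,63.52,67.46,82.98
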