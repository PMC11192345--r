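class,category,service,original_value,adjusted_value
remnant_forest,supporting,nutrient_cycling,922.00,1913.70
remnant_forest,supporting,soil_formation,10.00,20.76
remnant_forest,supporting,pollination,623.07,890.32
remnant_forest,regulating,flood_regulation,6.00,12.45
remnant_forest,regulating,water_treatment,87.00,180.57
remnant_forest,regulating,biological_pest_control,2.00,4.15
remnant_forest,cultural,medicinal_plants,3.00,4.71
remnant_forest,cultural,recreation,112.00,232.46
remnant_forest,supporting,habitat,2.00,4.15
remnant_forest,provisioning,genetic_resource,41.00,85.10
disturbed_forest,supporting,nutrient_cycling,361.00,749.28
disturbed_forest,supporting,soil_formation,10.00,20.76
disturbed_forest,supporting,pollination,668.80,955.67
disturbed_forest,regulating,water_treatment,87.00,180.57
disturbed_forest,regulating,biological_pest_control,2.00,4.15
disturbed_forest,cultural,medicinal_plants,3.00,4.71
disturbed_forest,cultural,recreation,66.00,136.99
disturbed_forest,supporting,habitat,2.00,4.15
disturbed_forest,provisioning,genetic_resource,16.00,33.21
coffee_plantation,supporting,pollination,939.50,1342.90
coffee_plantation,regulating,biological_pest_control,181.25,248.08
savanna,supporting,soil_formation,1.00,2.08
savanna,supporting,pollination,730.00,1043.62
savanna,regulating,flood_regulation,3.00,6.23
savanna,regulating,water_treatment,87.00,180.57
savanna,regulating,biological_pest_control,23.00,47.74
savanna,cultural,recreation,2.00,4.15
grassland,supporting,soil_formation,1.00,2.08
grassland,supporting,pollination,730.00,1043.62
grassland,regulating,flood_regulation,3.00,6.23
grassland,regulating,water_treatment,87.00,180.57
grassland,regulating,biological_pest_control,23.00,47.74
grassland,cultural,recreation,2.00,4.15
farmland,supporting,pollination,192.84,275.68
farmland,regulating,biological_pest_control,24.00,49.81
wetland,supporting,pollination,196.20,280.47
wetland,regulating,flood_regulation,15.00,31.13
wetland,regulating,water_treatment,1659.00,3443.30
wetland,cultural,recreation,491.00,1019.10
wetland,supporting,habitat,439.00,911.17
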