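class,category,service,value_usd_ha_yr
remnant_forest,supporting,nutrient_cycling,1913.70
remnant_forest,supporting,soil_formation,20.80
remnant_forest,supporting,pollination,890.60
remnant_forest,supporting,habitat,4.20
disturbed_forest,supporting,nutrient_cycling,749.30
disturbed_forest,supporting,soil_formation,20.80
disturbed_forest,supporting,pollination,955.90
disturbed_forest,supporting,habitat,4.20
savanna,supporting,soil_formation,2.10
savanna,supporting,pollination,1043.40
grassland,supporting,soil_formation,2.10
grassland,supporting,pollination,1043.40
coffee_plantation,supporting,pollination,1342.90
wetland,supporting,pollination,280.50
farmland,supporting,pollination,275.70
remnant_forest,regulating,carbon_sequestration,2484.80
disturbed_forest,regulating,carbon_sequestration,2134.40
savanna,regulating,carbon_sequestration,1545.90
grassland,regulating,carbon_sequestration,1545.90
coffee_plantation,regulating,carbon_sequestration,1398.20
wetland,regulating,carbon_sequestration,1506.50
farmland,regulating,carbon_sequestration,1328.60
remnant_forest,regulating,soil_erosion_control,84.30
disturbed_forest,regulating,soil_erosion_control,81.40
savanna,regulating,soil_erosion_control,83.00
grassland,regulating,soil_erosion_control,83.00
coffee_plantation,regulating,soil_erosion_control,22.80
wetland,regulating,soil_erosion_control,83.00
remnant_forest,regulating,flood_regulation,12.50
disturbed_forest,regulating,flood_regulation,4.20
savanna,regulating,flood_regulation,6.20
grassland,regulating,flood_regulation,6.20
wetland,regulating,flood_regulation,31.10
remnant_forest,regulating,water_treatment,180.60
disturbed_forest,regulating,water_treatment,180.60
savanna,regulating,water_treatment,180.60
grassland,regulating,water_treatment,180.60
wetland,regulating,water_treatment,3443.30
remnant_forest,regulating,biological_pest_control,4.20
disturbed_forest,regulating,biological_pest_control,4.20
savanna,regulating,biological_pest_control,47.70
grassland,regulating,biological_pest_control,47.70
coffee_plantation,regulating,biological_pest_control,248.10
farmland,regulating,biological_pest_control,49.80
remnant_forest,provisioning,honey,85.70
remnant_forest,provisioning,genetic_resource,85.10
disturbed_forest,provisioning,forest_products,221.10
disturbed_forest,provisioning,genetic_resource,33.20
coffee_plantation,provisioning,coffee_production,3423.60
wetland,provisioning,livestock_food_water_mulching,1102.20
farmland,provisioning,crop_production,719.80
savanna,provisioning,livestock_feed_forage,41.70
grassland,provisioning,livestock_feed,12.20
grassland,provisioning,forage,0.20
remnant_forest,cultural,medicinal_plants,4.70
remnant_forest,cultural,recreation,232.50
remnant_forest,cultural,cultural_value,4.20
disturbed_forest,cultural,medicinal_plants,4.70
disturbed_forest,cultural,recreation,137.00
disturbed_forest,cultural,cultural_value,4.20
savanna,cultural,recreation,4.20
grassland,cultural,recreation,4.20
coffee_plantation,cultural,cultural_value,4.20
wetland,cultural,recreation,1019.10
wetland,cultural,cultural_value,1828.60
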