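component,group,sex,max_points,standard_max,standard_min,kind,basis,group_rank
total_veg_fruit,2-3,both,10,4,0,adequacy,absolute_servings,1
total_veg_fruit,4-8,both,10,5,0,adequacy,absolute_servings,2
total_veg_fruit,9-13,both,10,6,0,adequacy,absolute_servings,3
total_veg_fruit,14-18,female,10,7,0,adequacy,absolute_servings,4
total_veg_fruit,14-18,male,10,8,0,adequacy,absolute_servings,4
total_veg_fruit,19-50,female,10,7.5,0,adequacy,absolute_servings,5
total_veg_fruit,19-50,male,10,10,0,adequacy,absolute_servings,5
total_veg_fruit,51+,female,10,7,0,adequacy,absolute_servings,6
total_veg_fruit,51+,male,10,7,0,adequacy,absolute_servings,6
whole_fruit,2-3,both,5,0.84,0,adequacy,absolute_servings,1
whole_fruit,4-8,both,5,1.05,0,adequacy,absolute_servings,2
whole_fruit,9-13,both,5,1.26,0,adequacy,absolute_servings,3
whole_fruit,14-18,female,5,1.47,0,adequacy,absolute_servings,4
whole_fruit,14-18,male,5,1.68,0,adequacy,absolute_servings,4
whole_fruit,19-50,female,5,1.575,0,adequacy,absolute_servings,5
whole_fruit,19-50,male,5,2.1,0,adequacy,absolute_servings,5
whole_fruit,51+,female,5,1.47,0,adequacy,absolute_servings,6
whole_fruit,51+,male,5,1.47,0,adequacy,absolute_servings,6
greens_beans,2-3,both,5,0.42,0,adequacy,absolute_servings,1
greens_beans,4-8,both,5,0.525,0,adequacy,absolute_servings,2
greens_beans,9-13,both,5,0.63,0,adequacy,absolute_servings,3
greens_beans,14-18,female,5,0.735,0,adequacy,absolute_servings,4
greens_beans,14-18,male,5,0.84,0,adequacy,absolute_servings,4
greens_beans,19-50,female,5,0.7875,0,adequacy,absolute_servings,5
greens_beans,19-50,male,5,1.05,0,adequacy,absolute_servings,5
greens_beans,51+,female,5,0.735,0,adequacy,absolute_servings,6
greens_beans,51+,male,5,0.735,0,adequacy,absolute_servings,6
whole_grains,2-3,both,10,1.5,0,adequacy,absolute_servings,1
whole_grains,4-8,both,10,2,0,adequacy,absolute_servings,2
whole_grains,9-13,both,10,3,0,adequacy,absolute_servings,3
whole_grains,14-18,female,10,3,0,adequacy,absolute_servings,4
whole_grains,14-18,male,10,3.5,0,adequacy,absolute_servings,4
whole_grains,19-50,female,10,3,0,adequacy,absolute_servings,5
whole_grains,19-50,male,10,4,0,adequacy,absolute_servings,5
whole_grains,51+,female,10,3,0,adequacy,absolute_servings,6
whole_grains,51+,male,10,3.5,0,adequacy,absolute_servings,6
dairy,2-3,both,10,2,0,adequacy,absolute_servings,1
dairy,4-8,both,10,2,0,adequacy,absolute_servings,2
dairy,9-13,both,10,3.5,0,adequacy,absolute_servings,3
dairy,14-18,female,10,3.5,0,adequacy,absolute_servings,4
dairy,14-18,male,10,3.5,0,adequacy,absolute_servings,4
dairy,19-50,female,10,2,0,adequacy,absolute_servings,5
dairy,19-50,male,10,2,0,adequacy,absolute_servings,5
dairy,51+,female,10,3,0,adequacy,absolute_servings,6
dairy,51+,male,10,3,0,adequacy,absolute_servings,6
total_protein,2-3,both,5,1,0,adequacy,absolute_servings,1
total_protein,4-8,both,5,1,0,adequacy,absolute_servings,2
total_protein,9-13,both,5,1.5,0,adequacy,absolute_servings,3
total_protein,14-18,female,5,2,0,adequacy,absolute_servings,4
total_protein,14-18,male,5,3,0,adequacy,absolute_servings,4
total_protein,19-50,female,5,2,0,adequacy,absolute_servings,5
total_protein,19-50,male,5,3,0,adequacy,absolute_servings,5
total_protein,51+,female,5,2,0,adequacy,absolute_servings,6
total_protein,51+,male,5,3,0,adequacy,absolute_servings,6
seafood_plant_protein,2-3,both,5,0.32,0,adequacy,absolute_servings,1
seafood_plant_protein,4-8,both,5,0.32,0,adequacy,absolute_servings,2
seafood_plant_protein,9-13,both,5,0.48,0,adequacy,absolute_servings,3
seafood_plant_protein,14-18,female,5,0.64,0,adequacy,absolute_servings,4
seafood_plant_protein,14-18,male,5,0.96,0,adequacy,absolute_servings,4
seafood_plant_protein,19-50,female,5,0.64,0,adequacy,absolute_servings,5
seafood_plant_protein,19-50,male,5,0.96,0,adequacy,absolute_servings,5
seafood_plant_protein,51+,female,5,0.64,0,adequacy,absolute_servings,6
seafood_plant_protein,51+,male,5,0.96,0,adequacy,absolute_servings,6
fatty_acids,2-3,both,10,2.5,1.2,adequacy,fat_ratio,1
fatty_acids,4-8,both,10,2.5,1.2,adequacy,fat_ratio,2
fatty_acids,9-13,both,10,2.5,1.2,adequacy,fat_ratio,3
fatty_acids,14-18,female,10,2.5,1.2,adequacy,fat_ratio,4
fatty_acids,14-18,male,10,2.5,1.2,adequacy,fat_ratio,4
fatty_acids,19-50,female,10,2.5,1.2,adequacy,fat_ratio,5
fatty_acids,19-50,male,10,2.5,1.2,adequacy,fat_ratio,5
fatty_acids,51+,female,10,2.5,1.2,adequacy,fat_ratio,6
fatty_acids,51+,male,10,2.5,1.2,adequacy,fat_ratio,6
refined_grains,2-3,both,10,50,50,moderation,percent_grains,1
refined_grains,4-8,both,10,50,50,moderation,percent_grains,2
refined_grains,9-13,both,10,50,50,moderation,percent_grains,3
refined_grains,14-18,female,10,50,50,moderation,percent_grains,4
refined_grains,14-18,male,10,50,50,moderation,percent_grains,4
refined_grains,19-50,female,10,50,50,moderation,percent_grains,5
refined_grains,19-50,male,10,50,50,moderation,percent_grains,5
refined_grains,51+,female,10,50,50,moderation,percent_grains,6
refined_grains,51+,male,10,50,50,moderation,percent_grains,6
sodium,2-3,both,10,1000,3000,moderation,sodium_band,1
sodium,4-8,both,10,1200,3800,moderation,sodium_band,2
sodium,9-13,both,10,1500,4400,moderation,sodium_band,3
sodium,14-18,female,10,1500,4600,moderation,sodium_band,4
sodium,14-18,male,10,1500,4600,moderation,sodium_band,4
sodium,19-50,female,10,1500,4600,moderation,sodium_band,5
sodium,19-50,male,10,1500,4600,moderation,sodium_band,5
sodium,51+,female,10,1300,4600,moderation,sodium_band,6
sodium,51+,male,10,1300,4600,moderation,sodium_band,6
empty_calories,2-3,both,20,19,50,moderation,percent_energy,1
empty_calories,4-8,both,20,19,50,moderation,percent_energy,2
empty_calories,9-13,both,20,19,50,moderation,percent_energy,3
empty_calories,14-18,female,20,19,50,moderation,percent_energy,4
empty_calories,14-18,male,20,19,50,moderation,percent_energy,4
empty_calories,19-50,female,20,19,50,moderation,percent_energy,5
empty_calories,19-50,male,20,19,50,moderation,percent_energy,5
empty_calories,51+,female,20,19,50,moderation,percent_energy,6
empty_calories,51+,male,20,19,50,moderation,percent_energy,6
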