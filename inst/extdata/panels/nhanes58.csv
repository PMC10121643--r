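nutrient_id,unit
protein,g
total_fat,g
carbohydrate,g
sugars,g
fiber,g
water,g
alcohol,g
saturated_fat,g
monounsaturated_fat,g
polyunsaturated_fat,g
cholesterol,mg
fa_4_0,g
fa_6_0,g
fa_8_0,g
fa_10_0,g
fa_12_0,g
fa_14_0,g
fa_16_0,g
fa_18_0,g
fa_16_1,g
fa_18_1,g
fa_18_2,g
fa_18_3,g
fa_20_4,g
fa_22_6,g
calcium,mg
phosphorus,mg
magnesium,mg
iron,mg
zinc,mg
copper,mg
sodium,mg
potassium,mg
selenium,ug
vitamin_a_rae,ug
retinol,ug
alpha_carotene,ug
beta_carotene,ug
beta_cryptoxanthin,ug
lycopene,ug
lutein_zeaxanthin,ug
thiamin,mg
riboflavin,mg
niacin,mg
vitamin_b6,mg
folate_total,ug
vitamin_b12,ug
vitamin_c,mg
vitamin_e,mg
vitamin_k,ug
caffeine,mg
theobromine,mg
pantothenic_acid,mg
manganese,mg
fluoride,ug
betaine,mg
fa_20_3,g
fa_22_5,g
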