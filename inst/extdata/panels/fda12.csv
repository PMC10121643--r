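nutrient_id,unit
protein,g
total_fat,g
saturated_fat,g
cholesterol,mg
sodium,mg
carbohydrate,g
fiber,g
sugars,g
vitamin_d,ug
calcium,mg
iron,mg
potassium,mg
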