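nutrient,unit
energy,kcal
fat,g
carbohydrate,g
protein,g
water,g
dietary fiber,g
vitamin b1,mg
ca,mg
fe,mg
na,mg
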