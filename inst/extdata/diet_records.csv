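date,food_name,weight_g
2024-03-01,Rice,150
2024-03-01,Chicken,120
2024-03-02,Pork Fried Rice,300
2024-03-02,Oatmeal,40
2024-03-04,Tomato,200
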