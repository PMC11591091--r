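name,energy,fat,carbohydrate,protein,na
Oatmeal,377,6.7,66.9,15,3.7
Biscuit,435,12.7,71.7,9,204.1
Fried Chips,615,48.4,41.9,4,60.9
Spicy Kelp,57.9,1.7,8.5,3.1,2590
Cheese,328,23.5,3.5,25.7,584
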