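name,energy,fat,carbohydrate,protein,water,dietary fiber,vitamin b1,ca,fe,na
Rice,116,0.3,25.9,2.6,70.9,0.3,0.02,7,1.3,2.5
Potato,77,0.2,17.2,2,79.8,0.7,0.08,8,0.8,2.7
Pork,395,37,2.4,13.2,46.8,-,0.22,6,1.6,59.4
Chicken,167,9.4,1.3,19.3,69,-,0.05,9,1.4,63.3
Mushroom,24,0.1,4.1,2.7,92.4,2.1,0.08,6,1.2,8.3
Tomato,20,0.2,4,0.9,94.4,0.5,0.03,10,0.4,5
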