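name,ingredient,amount_g
Roast Chicken,Rice,250
Roast Chicken,Chicken,200
Mushroom Chicken Stew,Chicken,150
Mushroom Chicken Stew,Mushroom,100
Mushroom Chicken Stew,Tomato,50
Tomato Potato Soup,Tomato,120
Tomato Potato Soup,Potato,150
Pork Fried Rice,Rice,200
Pork Fried Rice,Pork,80
Stuffed Tomato,Tomato,150
Stuffed Tomato,Pork,60
Stuffed Tomato,Mushroom,40
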