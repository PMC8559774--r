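code,name,carb_g_per_100g,protein_g_per_100g,fat_g_per_100g,exchange_group,grams_per_exchange,carb_g_per_piece
11001,steamed white rice,30,2.5,0.3,rice,55,
11002,fried rice,29,6,8,rice,55,
11003,sticky rice,38,3,0.5,rice,35,
12001,wheat noodles,25,5,1,noodle,60,
12002,rice noodles,22,2,0.5,noodle,60,
13001,coconut rice dessert,45,4,8,dessert,45,
13002,glutinous rice with custard,42,5,7,dessert,45,
13003,banana fritter,55,2,12,dessert,40,
13004,candied jackfruit,80,1,0.2,dessert,25,
14001,ripe mango,17,0.6,0.3,fruit,90,
14002,pineapple,13,0.5,0.1,fruit,115,
14003,banana,23,1.1,0.3,fruit,60,
15001,steamed taro,28,1.5,0.2,starchy_vegetable,55,
15002,sweet corn kernels,19,3.3,1.4,starchy_vegetable,80,
16001,raisins,72,3,0.5,fruit,20,1
17001,boiled chicken breast,0,31,3.5,meat,40,
17002,sweet pork sausage,5,14,30,meat,40,
17003,boiled egg,1.1,13,11,meat,50,
18001,cucumber,2.5,0.6,0.1,vegetable,100,
18002,stir-fried morning glory,4,2.5,3,vegetable,80,
19001,dried shrimp topping,8,60,3,meat,15,
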