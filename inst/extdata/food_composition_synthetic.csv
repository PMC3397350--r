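food_item,zinc_mg_per_100g,energy_kcal_per_100g
rice,1.7,346
wheat_flour,1.6,352
fresh_vegetables,0.4,25
root_vegetable,0.3,80
pickled_vegetables,0.5,30
pork,2.1,395
beef_lamb,4.7,190
poultry,1.1,167
liver,5.8,129
fish,1.2,113
eggs,1.1,144
milk,0.4,54
yoghurt,0.5,72
milk_powder,3.1,478
cheese,3.5,328
tofu,1.1,82
whole_grains,1.8,340
fruits,0.2,52
nuts,2.2,580
cake,0.7,347
juice,0.1,45
beverage,0.1,40
beer,0.2,32
alcohol,0.3,250
deep_fried_products,0.9,420
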