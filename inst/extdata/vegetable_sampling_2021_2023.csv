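vegetable,batches
pepper,34475
chinese cabbage,29299
tomato,28721
eggplant,26328
celery,22615
potato,20162
cowpea,17199
leek,16526
ginger,14556
bean sprout,12928
cucumber,11392
radish,11369
leaf-used lettuce,8657
spinach,8426
mushroom,6685
head cabbage,6634
yam,4849
kidney bean,4755
lotus root,2239
shallot,2023
balsam pear,911
onion,719
sweet potato,308
broccoli,308
garlic sprout,267
lettuce,247
cucurbita pepo,239
cauliflower,227
day-lily flower,218
lettuce (stem),205
pumpkin,179
wax gourd,170
water spinach,160
chrysanthemum,138
luffa,127
garlic,124
mustard,81
colocasia esculenta,68
amaranth,49
bottle gourd,47
snow peas,38
others,35
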