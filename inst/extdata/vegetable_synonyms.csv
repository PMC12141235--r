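alias,canonical
pepper,pepper
chili,pepper
chilli,pepper
hot pepper,pepper
chinese cabbage,chinese cabbage
napa cabbage,chinese cabbage
tomato,tomato
tomatoes,tomato
eggplant,eggplant
aubergine,eggplant
celery,celery
potato,potato
cowpea,cowpea
yardlong bean,cowpea
leek,leek
chinese chive,leek
ginger,ginger
bean sprout,bean sprout
beansprout,bean sprout
cucumber,cucumber
radish,radish
leaf-used lettuce,leaf-used lettuce
leaf lettuce,leaf-used lettuce
spinach,spinach
mushroom,mushroom
head cabbage,head cabbage
cabbage,head cabbage
yam,yam
kidney bean,kidney bean
lotus root,lotus root
shallot,shallot
scallion,shallot
balsam pear,balsam pear
bitter gourd,balsam pear
onion,onion
sweet potato,sweet potato
broccoli,broccoli
garlic sprout,garlic sprout
lettuce,lettuce
cauliflower,cauliflower
pumpkin,pumpkin
wax gourd,wax gourd
winter melon,wax gourd
water spinach,water spinach
luffa,luffa
garlic,garlic
mustard,mustard
amaranth,amaranth
bottle gourd,bottle gourd
snow peas,snow peas
chrysanthemum,chrysanthemum
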