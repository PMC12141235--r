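vegetable,p_percent,s,ir
leek,9.29,8.779,0.815
cowpea,7.38,8.265,0.610
ginger,8.09,4.618,0.374
celery,3.64,8.222,0.300
shallot,6.23,3.777,0.235
spinach,2.49,7.659,0.191
bean sprout,0.82,17.592,0.144
kidney bean,2.23,6.123,0.136
pepper,2.91,3.655,0.106
chinese cabbage,1.35,7.625,0.103
leaf-used lettuce,1.93,5.064,0.098
yam,1.59,5.309,0.084
sweet potato,1.95,3.837,0.075
luffa,2.36,3.072,0.073
lettuce,1.46,3.581,0.052
balsam pear,0.77,5.067,0.039
eggplant,1.11,3.179,0.035
radish,0.43,7.570,0.033
chrysanthemum,1.45,1.825,0.026
cucumber,0.50,4.764,0.024
mushroom,0.33,6.871,0.023
wax gourd,0.59,2.550,0.015
head cabbage,0.26,4.440,0.011
potato,0.16,4.374,0.007
cucurbita pepo,0.42,1.540,0.006
lettuce (stem),0.40,1.450,0.006
broccoli,0.32,1.800,0.006
tomato,0.13,3.011,0.004
lotus root,0.09,1.925,0.002
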