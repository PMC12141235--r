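province,batches,noncompliant
Chongqing,39327,687
Guizhou,20410,305
Yunnan,20288,685
Beijing,19835,453
Shandong,19823,835
Henan,18298,513
Xinjiang,12094,271
Shaanxi,11129,108
Guangxi,10501,172
Guangdong,9786,210
Anhui,9231,181
Heilongjiang,8422,150
Hunan,7633,268
Sichuan,7208,196
Jiangsu,6824,313
Shanxi,6818,335
Fujian,6713,307
Jilin,6381,186
Hainan,6138,228
Zhejiang,5861,252
Hubei,5608,171
Jiangxi,5045,150
Liaoning,4464,68
Qinghai,4422,146
Ningxia,4318,46
Hebei,4256,17
Tianjin,4229,79
Inner Mongolia,3628,102
Shanghai,3020,29
Gansu,2993,75
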