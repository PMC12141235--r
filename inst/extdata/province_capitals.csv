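province,longitude_e,latitude_n
Beijing,116.41,39.90
Tianjin,117.20,39.08
Hebei,114.51,38.04
Shanxi,112.55,37.87
Inner Mongolia,111.75,40.84
Liaoning,123.43,41.80
Jilin,125.32,43.90
Heilongjiang,126.63,45.75
Shanghai,121.47,31.23
Jiangsu,118.78,32.04
Zhejiang,120.15,30.27
Anhui,117.28,31.86
Fujian,119.30,26.08
Jiangxi,115.89,28.68
Shandong,117.00,36.65
Henan,113.62,34.75
Hubei,114.30,30.59
Hunan,112.94,28.23
Guangdong,113.26,23.13
Guangxi,108.37,22.82
Hainan,110.32,20.03
Chongqing,106.55,29.56
Sichuan,104.07,30.67
Guizhou,106.63,26.65
Yunnan,102.71,25.04
Shaanxi,108.94,34.34
Gansu,103.83,36.06
Qinghai,101.78,36.62
Ningxia,106.23,38.49
Xinjiang,87.62,43.83
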