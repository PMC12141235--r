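scope,year,longitude_e,latitude_n
all vegetables,2021,114.48,33.70
all vegetables,2023,113.28,32.97
leek,2021,113.58,34.08
leek,2023,114.80,35.10
cowpea,2021,114.48,29.94
cowpea,2023,113.60,29.46
ginger,2021,111.88,30.61
ginger,2023,113.81,33.57
celery,2021,111.82,33.50
celery,2023,111.44,31.45
spinach,2021,109.41,31.54
spinach,2023,109.58,30.45
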