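alias,canonical
clothianidin,clothianidin
procymidone,procymidone
chlorpyrifos,chlorpyrifos
chlorpyriphos,chlorpyrifos
imidacloprid,imidacloprid
carbendazim,carbendazim
abamectin,abamectin
avermectin,abamectin
acetamiprid,acetamiprid
cypermethrin,cypermethrin
difenoconazole,difenoconazole
dimethoate,dimethoate
omethoate,omethoate
thiamethoxam,thiamethoxam
phoxim,phoxim
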