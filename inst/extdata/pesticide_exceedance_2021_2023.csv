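pesticide,batches
clothianidin,1403
procymidone,972
chlorpyrifos,909
others,4254
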