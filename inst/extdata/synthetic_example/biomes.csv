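unit,biome
sp01,forest
sp02,woodland
sp03,forest
sp04,woodland
sp05,semi_arid
sp06,forest
sp07,woodland
sp08,semi_arid
sp09,forest
sp10,semi_arid
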