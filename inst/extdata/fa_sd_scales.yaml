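alpha-linolenic acid: 0.05
eicosapentaenoic acid: 0.3
docosapentaenoic acid: 0.17
docosahexaenoic acid: 0.89
linoleic acid: 2.69
arachidonic acid: 1.96
palmitoleic acid: 0.18
oleic acid: 1.17
palmitic acid: 1.64
stearic acid: 1.19
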