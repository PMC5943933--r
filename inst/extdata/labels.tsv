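sample	condition
T01	tumor
T02	tumor
T03	tumor
T04	tumor
T05	tumor
T06	tumor
N01	normal
N02	normal
N03	normal
N04	normal
N05	normal
N06	normal
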