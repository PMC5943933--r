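g001
g002
g005
g006
g007
g010
g011
g012
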