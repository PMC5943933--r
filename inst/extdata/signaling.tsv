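g002	g006
g011	g005
g005	g010
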