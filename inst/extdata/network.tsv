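g001	g002
g001	g003
g001	g004
g001	g006
g001	g008
g001	g009
g001	g012
g002	g003
g002	g004
g002	g005
g002	g008
g003	g005
g003	g007
g004	g006
g004	g010
g005	g012
g006	g007
g006	g009
g009	g010
g009	g011
g010	g011
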