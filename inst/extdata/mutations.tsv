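gene	sample
g001	M001
g001	M002
g001	M005
g001	M006
g001	M007
g001	M011
g001	M012
g001	M019
g001	M022
g001	M023
g002	M001
g002	M002
g002	M003
g002	M004
g002	M007
g002	M016
g002	M019
g002	M020
g002	M022
g005	M004
g005	M005
g005	M006
g005	M008
g005	M010
g005	M011
g005	M013
g005	M017
g005	M019
g005	M022
g006	M011
g006	M012
g006	M013
g006	M017
g006	M021
g006	M022
g007	M001
g007	M005
g007	M006
g007	M007
g007	M010
g007	M015
g007	M016
g007	M019
g007	M023
g010	M001
g010	M006
g010	M010
g010	M011
g010	M013
g010	M018
g010	M019
g010	M021
g010	M023
g011	M001
g011	M002
g011	M006
g011	M008
g011	M009
g011	M013
g011	M015
g011	M016
g011	M017
g011	M019
g011	M020
g011	M021
g011	M023
g012	M004
g012	M005
g012	M006
g012	M008
g012	M010
g012	M011
g012	M013
g012	M017
g012	M019
g012	M022
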