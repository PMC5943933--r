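gene	T01	T02	T03	T04	T05	T06	N01	N02	N03	N04	N05	N06
g001	-0.9064659174106932	-1.9862690834507224	0.11242574912910683	-0.02293885788307526	0.09588803214331292	0.5884787570158745	0.9422894485305513	1.216542549879913	-1.4891782542203398	0.7242431279033216	0.858234485564724	-0.13325003720197273
g002	0.02222301385570438	0.8595615569551914	0.8291262178417879	-1.4497436485752844	-1.761162310285802	-0.24888138661577563	-0.15398386327812186	1.2729226865722147	0.19342482391474572	1.214301402376677	-1.040567778063229	0.2627792853018918
g003	-0.5802146964425566	0.24003026570633124	-1.1689481106669861	0.26025647290187387	0.018936405746020693	-1.8797037810679955	0.8826697985955625	1.3377660556721598	0.6611349154958647	-0.0028696896916184855	1.2568343090351062	-1.025891945283763
g004	0.31373871238299006	0.6277846230549591	0.7752433555014209	0.738350295175336	1.3070139482297192	1.459918072927866	-1.3503130970228445	-0.06400388129914254	-1.1445352970788885	-0.8145886428069058	-0.8468081262354266	-1.0017999628290835
g005	0.6356921611328665	1.2945520636781245	-0.5508284359254294	0.29973679156279015	0.2272322958546047	-0.7011683052766977	0.47532149223340875	-2.1128865480261956	0.14466314696800853	0.8188734729879482	0.8436225744348049	-1.3748107096242332
g006	-0.33266249377169715	0.6171083307585169	0.2182599000691712	-0.5946088258338454	0.7509586075088879	-0.6462133777698962	-1.912059903601432	-0.4827244427540928	-0.5211001166508441	0.15082917991774997	0.6161210290047184	2.1360921131227633
g007	0.83215816716004	0.047628933712767274	1.0722820708201541	1.5171860282971241	-0.7909395069652256	0.5319900298874566	-0.3317771549112429	-0.4086364408118719	-1.7613835621128362	-0.34113615881816345	0.9075553591766368	-1.2749277654348388
g008	0.41201348171919766	0.1466049634586054	-1.440833249350118	0.4978890250695938	1.2019822942496396	-1.6020759067428174	-0.5235306071132141	1.722104602697256	-1.00189780194182	0.2843844322895441	0.3786526794611757	-0.07529391379704298
g009	1.58736477553158	0.8545822196812732	-0.0033738006399022837	0.4582100720619308	1.275680498564502	0.7212063443204513	-0.2489639081615523	-0.9676514720353793	-0.8030619342666766	-1.0477094524846295	-0.21174886715951027	-1.6145344754120854
g010	1.14802716065606	1.4553775380409286	0.783579910112417	1.2813748340694948	0.03818987174293592	0.40681201488065893	-0.9873590083822793	-1.1800433918479611	-1.2215218192718156	-0.13884074974173993	-0.8438177931817249	-0.7417785670769736
g011	0.6602130874580111	0.7641449755104809	1.3283066408661552	0.29310060364917034	1.115565085238938	1.2622920930903132	-0.8857866598497066	-0.7625602746404799	-0.43829257481687983	-1.032155671587863	-1.2309996191896233	-1.0738276857285172
g012	-0.7559491216649286	-0.5616460317058145	0.1752725443364037	0.3213243157575073	2.217835073524041	-1.798720789267307	0.9459934139498685	0.0450312386468153	0.14671233966468658	-0.9336055758256251	0.1863626131710417	0.011389979413310908
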