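species	gene	phenotype
F.graminearum	FGSG_00426	WT
F.graminearum	FGSG_00565	Stage-1
F.graminearum	FGSG_01108	Stage-5
F.graminearum	FGSG_02102	asynchronous
F.graminearum	FGSG_02751	WT
F.graminearum	FGSG_03028	Stage-1
F.graminearum	FGSG_03813	WT
F.graminearum	FGSG_04001	Stage-5
F.graminearum	FGSG_04180	WT
F.graminearum	FGSG_04417	Stage-3
F.graminearum	FGSG_04997	Stage-5
F.graminearum	FGSG_05166	Stage-1
F.graminearum	FGSG_05652	asynchronous
F.graminearum	FGSG_06651	Stage-1
F.graminearum	FGSG_07111	Stage-3
F.graminearum	FGSG_07376	WT
F.graminearum	FGSG_07478	Stage-1
F.graminearum	FGSG_08695	Stage-1
F.graminearum	FGSG_09006	WT
F.graminearum	FGSG_09475	WT
F.graminearum	FGSG_10094	Stage-5
F.graminearum	FGSG_12680	WT
F.graminearum	FGSG_13162	Stage-2
F.graminearum	FGSG_16340	Stage-1
F.graminearum	FGSG_17494	Stage-5
F.graminearum	FGSG_17499	Stage-3
N.crassa	NCU09140	WT
N.crassa	NCU02496	WT
N.crassa	NCU03098	WT
N.crassa	NCU07748	WT
N.crassa	NCU08856	Stage-3
N.crassa	NCU04197	WT
N.crassa	NCU09775	WT
N.crassa	NCU04520	WT
N.crassa	NCU07924	Stage-1
N.crassa	NCU01496	Stage-5
N.crassa	NCU06316	Stage-5
N.crassa	NCU03490	WT
N.crassa	NCU06985	WT
N.crassa	NCU00329	WT
N.crassa	NCU07508	Stage-3
N.crassa	NCU01374	WT
N.crassa	NCU01451	Stage-3
N.crassa	NCU07432	WT
N.crassa	NCU01140	WT
N.crassa	NCU09788	Stage-5
N.crassa	NCU01009	WT
N.crassa	NCU07009	WT
N.crassa	NCU06930	WT
N.crassa	NCU00552	other
N.crassa	NCU02908	WT
N.crassa	NCU06136	WT
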