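cohort	characteristic	category	count
IMvigor210	sex	Female	50
IMvigor210	sex	Male	194
IMvigor210	sex	NA	0
UC-GENOME	sex	Female	47
UC-GENOME	sex	Male	143
UC-GENOME	sex	NA	1
TCGA	sex	Female	108
TCGA	sex	Male	304
TCGA	sex	NA	0
MSK2022	sex	Female	296
MSK2022	sex	Male	980
MSK2022	sex	NA	2
MSK2015	sex	Female	28
MSK2015	sex	Male	54
MSK2015	sex	NA	1
Tongji	sex	Female	7
Tongji	sex	Male	14
Tongji	sex	NA	0
IMvigor210	smoking	Former	145
IMvigor210	smoking	Never	74
IMvigor210	smoking	Current	25
IMvigor210	smoking	NA	0
UC-GENOME	smoking	Former	112
UC-GENOME	smoking	Never	62
UC-GENOME	smoking	Current	16
UC-GENOME	smoking	NA	1
TCGA	smoking	Former	198
TCGA	smoking	Never	111
TCGA	smoking	Current	90
TCGA	smoking	NA	13
MSK2022	smoking	Former	650
MSK2022	smoking	Never	433
MSK2022	smoking	Current	141
MSK2022	smoking	NA	54
MSK2015	smoking	Former	44
MSK2015	smoking	Never	22
MSK2015	smoking	Current	16
MSK2015	smoking	NA	1
Tongji	smoking	Former	8
Tongji	smoking	Never	7
Tongji	smoking	Current	6
Tongji	smoking	NA	0
IMvigor210	os	Event	159
IMvigor210	os	Censored	85
IMvigor210	os	NA	0
UC-GENOME	os	Event	78
UC-GENOME	os	Censored	85
UC-GENOME	os	NA	28
TCGA	os	Event	158
TCGA	os	Censored	250
TCGA	os	NA	4
MSK2022	os	Event	445
MSK2022	os	Censored	793
MSK2022	os	NA	40
MSK2015	os	Event	25
MSK2015	os	Censored	43
MSK2015	os	NA	15
Tongji	os	Event	6
Tongji	os	Censored	15
Tongji	os	NA	0
IMvigor210	ms_subtype	MUT1	150
IMvigor210	ms_subtype	MUT2	94
UC-GENOME	ms_subtype	MUT1	63
UC-GENOME	ms_subtype	MUT2	128
TCGA	ms_subtype	MUT1	161
TCGA	ms_subtype	MUT2	251
MSK2022	ms_subtype	MUT1	833
MSK2022	ms_subtype	MUT2	445
MSK2015	ms_subtype	MUT1	37
MSK2015	ms_subtype	MUT2	46
Tongji	ms_subtype	MUT1	12
Tongji	ms_subtype	MUT2	9
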