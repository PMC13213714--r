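cohort	n
IMvigor210	244
UC-GENOME	191
TCGA	412
MSK2022	1278
MSK2015	83
Tongji	21
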