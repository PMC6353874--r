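condition	source	code
cancer	hospital	C
cancer	interview	1001
diabetes	hospital	E10
diabetes	hospital	E11
diabetes	hospital	E12
diabetes	hospital	E13
diabetes	hospital	E14
diabetes	interview	1220
mi	hospital	I21
mi	hospital	I22
mi	interview	1075
stroke	hospital	I60
stroke	hospital	I61
stroke	hospital	I63
stroke	hospital	I64
stroke	interview	1081
copd	hospital	J43
copd	hospital	J44
copd	interview	1112
dementia	hospital	F00
dementia	hospital	F01
dementia	hospital	F03
dementia	hospital	G30
dementia	interview	1263
chf	hospital	I50
chf	interview	1076
death	death_registry	DTH
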