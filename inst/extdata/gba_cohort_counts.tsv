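cohort	arm	N	n409s	severe	total	total_excl
1kGP	all	2504	3	14	53	50
PD	case	2325	128	38	296	171
PD	control	1255	158	9	200	43
LBD	case	2598	59	79	353	298
LBD	control	1941	19	2	86	67
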