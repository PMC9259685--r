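group	with_gbap1_like_variant	total
CNG	7	146
no_CNG	71	10407
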