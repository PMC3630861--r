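condition	firefly	renilla	is_control	replicate
empty_vector	2100	10500	TRUE	1
empty_vector	1950	10100	TRUE	2
empty_vector	2250	10900	TRUE	3
HsNFkB_p50	2600	10400	FALSE	1
HsNFkB_p50	2400	9800	FALSE	2
HsNFkB_p50	2700	10600	FALSE	3
HsNFkB_p50+HsIkBzeta	31500	10200	FALSE	1
HsNFkB_p50+HsIkBzeta	35800	10700	FALSE	2
HsNFkB_p50+HsIkBzeta	29400	9900	FALSE	3
NvNFkB_p50+HsIkBzeta	8900	10300	FALSE	1
NvNFkB_p50+HsIkBzeta	7600	9700	FALSE	2
NvNFkB_p50+HsIkBzeta	9800	10800	FALSE	3
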