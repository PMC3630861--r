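pair_id	eluate_lum	lysate_lum	is_control
BAP_control	5200	410000	TRUE
HsNFkB_p50-HsIkBzeta	96000	380000	FALSE
NvNFkB_p50-HsIkBzeta	7100	350000	FALSE
HsNFkB_p50-NvBcl3	6900	420000	FALSE
NvNFkB_p50-NvBcl3	88000	390000	FALSE
HsNFkB_p50-HsIkBalpha	152000	400000	FALSE
NvNFkB_p50-HsIkBalpha	143000	385000	FALSE
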