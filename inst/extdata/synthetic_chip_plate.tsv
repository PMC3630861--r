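target_region	antibody_ct	control_ct	efficiency
TNF_promoter_HsP50	24.1	27.6	2
TNF_promoter_NvP50	24.4	27.6	2
IL10_promoter_HsP50	25.0	27.9	2
IL10_promoter_NvP50	25.3	27.9	2
GAPDH_negative_HsP50	27.5	27.6	2
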