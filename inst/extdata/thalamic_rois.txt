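Thal_AV_L
Thal_AV_R
Thal_LP_L
Thal_LP_R
Thal_VA_L
Thal_VA_R
Thal_VL_L
Thal_VL_R
Thal_VPL_L
Thal_VPL_R
Thal_IL_L
Thal_IL_R
Thal_MDm_L
Thal_MDm_R
Thal_MDl_L
Thal_MDl_R
Thal_LGN_L
Thal_LGN_R
Thal_MGN_L
Thal_MGN_R
Thal_PuA_L
Thal_PuA_R
Thal_PuM_L
Thal_PuM_R
Thal_PuL_L
Thal_PuL_R
Thal_PuI_L
Thal_PuI_R
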