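name,extraction_ratio,fu,binding_protein,f_cyp3a
synthA_hsa_bound,0.30,0.05,HSA,0.90
synthB_hsa_free,0.50,0.95,HSA,0.85
synthC_aag_tight,0.30,0.02,AAG,0.80
synthD_aag_loose,0.50,0.50,AAG,0.80
synthE_low_fcyp,0.30,0.05,HSA,0.50
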