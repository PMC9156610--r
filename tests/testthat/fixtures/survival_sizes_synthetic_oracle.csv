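scenario_id,rate_4dp,n_shrinkage,n_optimism,n_risk_precision,final_n
nb_death_tte,0.0063,1394,924,176,1394
hr_nb_relapse_tte,0.0132,1052,696,260,1052
dipg_death_tte,0.0077,1272,843,200,1272
dipg_prog_tte,0.0214,1126,745,238,1126
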