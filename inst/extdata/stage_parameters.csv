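stage,incidence_count,incidence_share,median_pfs,median_os,mean_age_dx,mean_weight,mean_height,hosp_per_6mo,pct_hospitalized,er_per_6mo,pct_er,mix_none,mix_surgery,mix_neoadjuvant,mix_adjuvant,surg_laparotomy,surg_omentectomy,surg_hysterectomy,surg_salpingo,surg_lymphadenectomy
I,1155,0.37,18.33,19.50,57.4,65,159,1.2,0.154,1.5,0.231,0,0.667,0,0.333,1,0,1,0,0
II,195,0.06,6.25,7.50,62.4,67,160,1.2,0.154,1.5,0.231,0,0.198,0,0.802,1,0.0638,1,1,0
III,1116,0.35,2.00,3.20,64.9,65,159,2.1,0.482,1.7,0.222,0.031,0.113,0.144,0.711,1,1,1,1,0.75
IV,681,0.22,1.60,1.90,68.1,66,160,2.1,0.482,1.7,0.222,0.088,0.088,0.242,0.582,1,1,1,1,1
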