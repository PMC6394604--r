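# Printed stage-by-category results table, transcribed verbatim for
# aggregation-layer verification only (never used as model input).
# One anomaly normalized: the stage IV hospitalizations total was printed
# with dot thousands separators ("315.441.267") and is stored as 315441267.
# pct_* columns are the printed within-stage percentages; avg_* columns are
# the printed average annual cost per patient (euros).
row,cost_type,total_I,pct_I,avg_I,total_II,pct_II,avg_II,total_III,pct_III,avg_III,total_IV,pct_IV,avg_IV
screening_patients,DHC,3088335,0.66,88.90,519790,0.45,92.46,2984717,0.23,103.10,2569116,0.21,119.03
genetic_relatives,DHC,1477440,0.32,26.63,248570,0.21,28.78,1427697,0.11,35.33,1105642,0.09,35.09
diagnosis,DHC,6845283,1.46,197.04,1152114,0.99,204.94,15650937,1.23,540.63,13471654,1.08,624.17
followup,DHC,12550184,2.68,230.70,2448326,2.10,288.28,16131636,1.27,414.67,7449071,0.60,260.89
surgery,DHC,33386327,7.12,794.29,9138573,7.84,1550.41,87624527,6.89,2879.72,73843438,5.93,3211.65
chemotherapy,DHC,73429456,15.66,1399.93,28018052,24.02,3517.86,223313473,17.57,6274.45,725107595,58.21,23527.41
hospitalizations,DHC,104089546,22.20,1915.55,15453906,13.25,1879.60,377473449,29.69,10199.17,315441267,25.32,10197.08
emergency,DHC,6240086,1.33,114.84,926449,0.79,112.68,4249286,0.33,114.81,3550979,0.29,114.79
palliative,DHC,4793722,1.02,76.47,1912383,1.64,203.48,21116270,1.66,515.37,10077388,0.81,527.30
total_dhc,DHC,245900380,52.45,4844.35,59818164,51.29,7878.49,749971992,59.00,21077.26,1152616149,92.54,38617.41
public_formal,DNHC,126432,0.03,1.99,50370,0.04,5.30,553693,0.04,13.39,259010,0.02,13.33
private_formal,DNHC,1235043,0.26,19.45,492033,0.42,51.74,5408711,0.43,130.82,2530115,0.20,130.23
informal,DNHC,112708919,24.04,1784.14,47855777,41.03,5049.87,505313452,39.75,12293.17,90186328,7.24,3785.87
total_dnhc,DNHC,114070394,24.33,1805.58,48398180,41.50,5106.91,511275856,40.22,12437.38,92975453,7.46,3929.43
temp_disability,IC,37936056,8.09,973.23,4136727,3.55,668.13,9975732,0.78,342.54,0,0.00,0
perm_disability,IC,6129363,1.31,102.23,773669,0.66,94.37,0,0.00,0.00,0,0.00,0
premature_mortality,IC,64769698,13.82,915.14,3496382,3.00,435.63,10774,0.00,0.38,0,0.00,0
total_ic,IC,108835116,23.22,1990.61,8406778,7.21,1198.13,9986506,0.79,342.92,0,0.00,0
total,TOTAL,468805889,100,8640.53,116623122,100,14183.54,1271234354,100,33857.56,1245591602,100,42546.84
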