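compound_id,lambda_abs_nm,lambda_emi_nm,epsilon_1e4,stokes_1e4,phi
10a,339.63,427.63,1.7500,0.6059,0.015
10b,340.00,428.90,1.7540,0.6096,0.018
10c,341.21,428.02,1.9500,0.5944,0.0184
10d,340.04,429.9,1.8500,0.6147,0.0182
10e,338.41,428.26,2.1500,0.6199,0.0159
10f,341.55,429.9,2.1000,0.5962,0.0171
10g,340.39,429.69,1.6000,0.6105,0.0171
10h,337.83,428.02,2.0500,0.6237,0.0143
10i,340.22,411.70,1.8000,0.5103,0.3197
10j,341.73,413.06,1.9500,0.5053,0.558
10k,338.99,412.50,2.1500,0.5256,0.2104
10l,340.80,413.3,1.5500,0.5147,0.0232
10m,340.22,413.26,1.9000,0.5194,0.2283
10n,340.22,412.26,2.1000,0.5136,0.2228
10o,340.33,413.53,1.7500,0.5201,0.24
10p,338.41,412.50,2.4000,0.5307,0.1267
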