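compound_id,lambda_exp_nm,lambda_theor_nm,osc_strength,energy_ev,contribution_label,contribution_percent
10a,339.63,388.53,0.0090,3.1911,H+2 -> L,52.99
10a,339.63,381.27,0.0628,3.2518,H -> L,78.96
10a,339.63,358.96,0.0004,3.4540,H+1 -> L,88.86
10b,340.00,390.09,0.0285,3.1784,H -> L,46.68
10b,340.00,385.61,0.0151,3.2153,H -> L,35.09
10b,340.00,373.69,0.0301,3.3179,H -> L+1,77.96
10c,341.21,413.58,0.0750,2.9979,H -> L-1,52.53
10c,341.21,405.69,0.0362,3.0561,H -> L,53.56
10c,341.21,388.21,0.0133,3.1937,H+2 -> L,48.39
10d,340.04,406.83,0.0042,3.0475,H -> L,99.12
10d,340.04,397.25,0.1508,3.1211,H -> L-1,97.56
10d,340.04,388.97,0.0074,3.1875,H+2 -> L,56.73
10e,338.41,478.79,0.0734,2.5895,H -> L,97.77
10e,338.41,401.98,0.0004,3.0843,H -> L-1,98.42
10e,338.41,393.12,0.0231,3.1538,H+1 -> L,83.83
10i,340.22,368.13,0.0763,3.3680,H -> L,94.54
10i,340.22,347.69,0.0005,3.5659,H+1 -> L,94.28
10i,340.22,343.63,0.0017,3.6080,H+2 -> L,95.69
10j,341.73,374.42,0.0459,3.3113,H -> L,81.21
10j,341.73,360.43,0.0337,3.4399,H+1 -> L,79.91
10j,341.73,344.17,0.0019,3.6025,H+2 -> L,98.15
10k,338.99,375.26,0.0417,3.3040,H -> L,80.29
10k,338.99,362.28,0.0393,3.4223,H+1 -> L,78.84
10k,338.99,344.43,0.0018,3.5997,H+2 -> L,98.31
10l,340.80,375.90,0.0436,3.2983,H -> L,80.29
10l,340.80,360.69,0.0358,3.4374,H+1 -> L,78.84
10l,340.80,344.19,0.0020,3.6022,H+2 -> L,98.31
10m,340.22,374.17,0.0517,3.3136,H -> L,79.25
10m,340.22,359.44,0.0291,3.4494,H+1 -> L,78.40
10m,340.22,344.65,0.0017,3.5974,H+2 -> L,98.27
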