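variable,category,elasticity,cix,abs_contribution,pct_contribution
education,no education,,,,
education,incomplete primary,0.003,0.014,0.000,0.013
education,complete primary,0.009,0.270,0.002,0.736
education,incomplete secondary,0.035,0.558,0.019,5.926
education,complete secondary,0.031,0.835,0.026,8.017
education,higher,0.023,0.953,0.022,6.741
age_band,15-19,,,,
age_band,20-24,0.001,0.084,0.000,0.026
age_band,25-29,0.012,0.056,0.001,0.207
age_band,30-34,0.022,-0.005,0.000,-0.032
age_band,35-39,0.025,-0.089,-0.002,-0.680
age_band,40-44,0.014,-0.156,-0.002,-0.676
age_band,45-49,0.003,-0.277,-0.001,-0.266
employed,no,,,,
employed,yes,0.098,-0.003,0.000,-0.091
marital,never in union,,,,
marital,married,-0.001,-0.061,0.000,0.015
marital,cohabiting,0.004,0.060,0.000,0.077
marital,widowed,0.001,-0.085,0.000,-0.021
marital,divorced,-0.005,0.066,0.000,-0.093
marital,separated,-0.002,0.171,0.000,-0.114
parity,one,,,,
parity,two-four,-0.005,0.050,0.000,-0.085
parity,five or more,-0.030,-0.243,0.007,2.222
insurance,no,,,,
insurance,yes,-0.024,0.366,-0.009,-2.697
media_newspaper,no,,,,
media_newspaper,yes,-0.005,0.584,-0.003,-0.920
media_radio,no,,,,
media_radio,yes,-0.001,0.095,0.000,-0.015
internet,no,,,,
internet,yes,-0.002,0.474,-0.001,-0.287
barrier_permission,not a big problem,,,,
barrier_permission,big problem,-0.004,-0.115,0.001,0.150
barrier_distance,not a big problem,,,,
barrier_distance,big problem,0.007,-0.119,-0.001,-0.238
wealth_quintile,poorest,,,,
wealth_quintile,poorer,0.013,-0.171,-0.002,-0.662
wealth_quintile,middle,0.021,-0.021,0.000,-0.133
wealth_quintile,richer,0.030,0.158,0.005,1.441
wealth_quintile,richest,0.032,0.433,0.014,4.284
head_sex,male,,,,
head_sex,female,0.004,0.128,0.000,0.143
residence,urban,,,,
residence,rural,-0.090,-0.157,0.014,4.350
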