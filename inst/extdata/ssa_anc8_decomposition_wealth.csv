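variable,category,elasticity,cix,abs_contribution,pct_contribution
wealth_quintile,poorest,,,,
wealth_quintile,poorer,0.013,-0.357,-0.004,-1.478
wealth_quintile,middle,0.021,0.057,0.001,0.392
wealth_quintile,richer,0.030,0.456,0.014,4.466
wealth_quintile,richest,0.032,0.826,0.027,8.756
age_band,15-19,,,,
age_band,20-24,0.001,-0.016,0.000,-0.005
age_band,25-29,0.012,0.029,0.000,0.112
age_band,30-34,0.022,0.048,0.001,0.345
age_band,35-39,0.025,0.018,0.000,0.146
age_band,40-44,0.014,-0.047,-0.001,-0.219
age_band,45-49,0.003,-0.164,-0.001,-0.168
education,no education,,,,
education,incomplete primary,0.003,-0.113,0.000,-0.117
education,complete primary,0.009,0.044,0.000,0.129
education,incomplete secondary,0.035,0.229,0.008,2.607
education,complete secondary,0.031,0.468,0.015,4.810
education,higher,0.023,0.673,0.016,5.100
employed,no,,,,
employed,yes,0.098,-0.005,-0.001,-0.166
marital,never in union,,,,
marital,married,-0.001,-0.005,0.000,0.001
marital,cohabiting,0.004,-0.028,0.000,-0.039
marital,widowed,0.001,-0.075,0.000,-0.020
marital,divorced,-0.005,-0.008,0.000,0.013
marital,separated,-0.002,-0.032,0.000,0.023
parity,one,,,,
parity,two-four,-0.005,0.050,0.000,-0.089
parity,five or more,-0.030,-0.159,0.005,1.555
insurance,no,,,,
insurance,yes,-0.024,0.168,-0.004,-1.327
media_newspaper,no,,,,
media_newspaper,yes,-0.005,0.402,-0.002,-0.680
media_radio,no,,,,
media_radio,yes,-0.001,0.136,0.000,-0.023
internet,no,,,,
internet,yes,-0.002,0.455,0.000,-0.295
barrier_permission,not a big problem,,,,
barrier_permission,big problem,-0.004,-0.116,0.000,0.163
barrier_distance,not a big problem,,,,
barrier_distance,big problem,0.007,-0.206,-0.001,-0.442
head_sex,male,,,,
head_sex,female,0.004,0.033,0.000,0.039
residence,urban,,,,
residence,rural,-0.090,-0.257,0.023,7.636
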