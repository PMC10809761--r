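analyte,n_labels,condition,replicate,abundance_percent
Ser,0,natural,,96.74
Ser,0,13CO2,1,84.99
Ser,0,13CO2,2,92.89
Ser,0,13CO2_acetate,1,80.51
Ser,0,13CO2_acetate,2,86.59
Ser,0,acetate_1,1,95.73
Ser,0,acetate_1,2,96.23
Ser,0,acetate_2,1,95.19
Ser,0,acetate_2,2,94.04
Ser,0,control,1,96.89
Ser,0,control,2,96.86
Ser,1,natural,,3.23
Ser,1,13CO2,1,13.45
Ser,1,13CO2,2,6.38
Ser,1,13CO2_acetate,1,17.62
Ser,1,13CO2_acetate,2,11.3
Ser,1,acetate_1,1,4.27
Ser,1,acetate_1,2,3.77
Ser,1,acetate_2,1,4.81
Ser,1,acetate_2,2,5.96
Ser,1,control,1,3.11
Ser,1,control,2,3.14
Ser,2,natural,,0.04
Ser,2,13CO2,1,1.57
Ser,2,13CO2,2,0.74
Ser,2,13CO2_acetate,1,1.87
Ser,2,13CO2_acetate,2,2.11
Ser,2,acetate_1,1,
Ser,2,acetate_1,2,
Ser,2,acetate_2,1,
Ser,2,acetate_2,2,
Ser,2,control,1,
Ser,2,control,2,
Ser,3,natural,,0
Ser,3,13CO2,1,
Ser,3,13CO2,2,
Ser,3,13CO2_acetate,1,0.12
Ser,3,13CO2_acetate,2,0.04
Ser,3,acetate_1,1,
Ser,3,acetate_1,2,
Ser,3,acetate_2,1,
Ser,3,acetate_2,2,
Ser,3,control,1,
Ser,3,control,2,
Asp,0,natural,,95.67
Asp,0,13CO2,1,78.93
Asp,0,13CO2,2,89.01
Asp,0,13CO2_acetate,1,71.48
Asp,0,13CO2_acetate,2,80.21
Asp,0,acetate_1,1,95.26
Asp,0,acetate_1,2,94.66
Asp,0,acetate_2,1,93.77
Asp,0,acetate_2,2,92.55
Asp,0,control,1,95.88
Asp,0,control,2,96.28
Asp,1,natural,,4.26
Asp,1,13CO2,1,16.36
Asp,1,13CO2,2,8.3
Asp,1,13CO2_acetate,1,21.42
Asp,1,13CO2_acetate,2,15.16
Asp,1,acetate_1,1,4.74
Asp,1,acetate_1,2,5.34
Asp,1,acetate_2,1,6.23
Asp,1,acetate_2,2,7.45
Asp,1,control,1,4.12
Asp,1,control,2,3.72
Asp,2,natural,,0.07
Asp,2,13CO2,1,4.31
Asp,2,13CO2,2,2.42
Asp,2,13CO2_acetate,1,6.34
Asp,2,13CO2_acetate,2,4.26
Asp,2,acetate_1,1,
Asp,2,acetate_1,2,
Asp,2,acetate_2,1,
Asp,2,acetate_2,2,
Asp,2,control,1,
Asp,2,control,2,
Asp,3,natural,,0
Asp,3,13CO2,1,0.4
Asp,3,13CO2,2,0.27
Asp,3,13CO2_acetate,1,0.76
Asp,3,13CO2_acetate,2,0.37
Asp,3,acetate_1,1,
Asp,3,acetate_1,2,
Asp,3,acetate_2,1,
Asp,3,acetate_2,2,
Asp,3,control,1,
Asp,3,control,2,
Asp,4,natural,,0
Asp,4,13CO2,1,
Asp,4,13CO2,2,
Asp,4,13CO2_acetate,1,
Asp,4,13CO2_acetate,2,
Asp,4,acetate_1,1,
Asp,4,acetate_1,2,
Asp,4,acetate_2,1,
Asp,4,acetate_2,2,
Asp,4,control,1,
Asp,4,control,2,
Glu,0,natural,,94.62
Glu,0,13CO2,1,71.81
Glu,0,13CO2,2,84.11
Glu,0,13CO2_acetate,1,65.74
Glu,0,13CO2_acetate,2,73.99
Glu,0,acetate_1,1,93.05
Glu,0,acetate_1,2,93.52
Glu,0,acetate_2,1,92.35
Glu,0,acetate_2,2,91.52
Glu,0,control,1,94.67
Glu,0,control,2,94.54
Glu,1,natural,,5.26
Glu,1,13CO2,1,20.49
Glu,1,13CO2,2,11.88
Glu,1,13CO2_acetate,1,23.97
Glu,1,13CO2_acetate,2,18.83
Glu,1,acetate_1,1,6.95
Glu,1,acetate_1,2,6.48
Glu,1,acetate_2,1,7.65
Glu,1,acetate_2,2,8.48
Glu,1,control,1,5.33
Glu,1,control,2,5.46
Glu,2,natural,,0.12
Glu,2,13CO2,1,6.51
Glu,2,13CO2,2,3.14
Glu,2,13CO2_acetate,1,8.54
Glu,2,13CO2_acetate,2,6.07
Glu,2,acetate_1,1,
Glu,2,acetate_1,2,
Glu,2,acetate_2,1,
Glu,2,acetate_2,2,
Glu,2,control,1,
Glu,2,control,2,
Glu,3,natural,,0
Glu,3,13CO2,1,1.19
Glu,3,13CO2,2,0.88
Glu,3,13CO2_acetate,1,1.75
Glu,3,13CO2_acetate,2,1.11
Glu,3,acetate_1,1,
Glu,3,acetate_1,2,
Glu,3,acetate_2,1,
Glu,3,acetate_2,2,
Glu,3,control,1,
Glu,3,control,2,
Glu,4,natural,,0
Glu,4,13CO2,1,
Glu,4,13CO2,2,
Glu,4,13CO2_acetate,1,
Glu,4,13CO2_acetate,2,
Glu,4,acetate_1,1,
Glu,4,acetate_1,2,
Glu,4,acetate_2,1,
Glu,4,acetate_2,2,
Glu,4,control,1,
Glu,4,control,2,
Glu,5,natural,,0
Glu,5,13CO2,1,
Glu,5,13CO2,2,
Glu,5,13CO2_acetate,1,
Glu,5,13CO2_acetate,2,
Glu,5,acetate_1,1,
Glu,5,acetate_1,2,
Glu,5,acetate_2,1,
Glu,5,acetate_2,2,
Glu,5,control,1,
Glu,5,control,2,
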