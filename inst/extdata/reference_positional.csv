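analyte,main,side,condition,replicate,abundance_percent
Ser,0,0,natural,,96.74
Ser,0,0,13CO2,1,84.99
Ser,0,0,13CO2,2,92.89
Ser,0,0,13CO2_acetate,1,80.51
Ser,0,0,13CO2_acetate,2,86.59
Ser,0,0,acetate_1,1,95.73
Ser,0,0,acetate_1,2,96.23
Ser,0,0,acetate_2,1,95.19
Ser,0,0,acetate_2,2,94.04
Ser,0,0,control,1,96.89
Ser,0,0,control,2,96.86
Ser,1,0,natural,,1.08
Ser,1,0,13CO2,1,4.06
Ser,1,0,13CO2,2,2.69
Ser,1,0,13CO2_acetate,1,6.29
Ser,1,0,13CO2_acetate,2,3.54
Ser,1,0,acetate_1,1,0.96
Ser,1,0,acetate_1,2,1.24
Ser,1,0,acetate_2,1,1.24
Ser,1,0,acetate_2,2,1.14
Ser,1,0,control,1,1.07
Ser,1,0,control,2,0.97
Ser,0,1,natural,,2.15
Ser,0,1,13CO2,1,9.39
Ser,0,1,13CO2,2,3.68
Ser,0,1,13CO2_acetate,1,11.33
Ser,0,1,13CO2_acetate,2,7.76
Ser,0,1,acetate_1,1,3.32
Ser,0,1,acetate_1,2,3.58
Ser,0,1,acetate_2,1,3.58
Ser,0,1,acetate_2,2,4.82
Ser,0,1,control,1,2.04
Ser,0,1,control,2,2.16
Ser,1,1,natural,,0.02
Ser,1,1,13CO2,1,1.04
Ser,1,1,13CO2,2,0.58
Ser,1,1,13CO2_acetate,1,1.17
Ser,1,1,13CO2_acetate,2,1.43
Ser,1,1,acetate_1,1,
Ser,1,1,acetate_1,2,
Ser,1,1,acetate_2,1,
Ser,1,1,acetate_2,2,
Ser,1,1,control,1,
Ser,1,1,control,2,
Ser,0,2,natural,,0.01
Ser,0,2,13CO2,1,0.52
Ser,0,2,13CO2,2,0.16
Ser,0,2,13CO2_acetate,1,0.7
Ser,0,2,13CO2_acetate,2,0.68
Ser,0,2,acetate_1,1,
Ser,0,2,acetate_1,2,
Ser,0,2,acetate_2,1,
Ser,0,2,acetate_2,2,
Ser,0,2,control,1,
Ser,0,2,control,2,
Ser,1,2,natural,,0
Ser,1,2,13CO2,1,
Ser,1,2,13CO2,2,
Ser,1,2,13CO2_acetate,1,0.12
Ser,1,2,13CO2_acetate,2,0.04
Ser,1,2,acetate_1,1,
Ser,1,2,acetate_1,2,
Ser,1,2,acetate_2,1,
Ser,1,2,acetate_2,2,
Ser,1,2,control,1,
Ser,1,2,control,2,
Asp,0,0,natural,,95.67
Asp,0,0,13CO2,1,78.93
Asp,0,0,13CO2,2,89.01
Asp,0,0,13CO2_acetate,1,71.48
Asp,0,0,13CO2_acetate,2,80.21
Asp,0,0,acetate_1,1,95.26
Asp,0,0,acetate_1,2,94.66
Asp,0,0,acetate_2,1,93.77
Asp,0,0,acetate_2,2,92.55
Asp,0,0,control,1,95.88
Asp,0,0,control,2,96.28
Asp,1,0,natural,,1.06
Asp,1,0,13CO2,1,4.51
Asp,1,0,13CO2,2,2.43
Asp,1,0,13CO2_acetate,1,5.66
Asp,1,0,13CO2_acetate,2,3.91
Asp,1,0,acetate_1,1,0.88
Asp,1,0,acetate_1,2,1.3
Asp,1,0,acetate_2,1,1.08
Asp,1,0,acetate_2,2,1.34
Asp,1,0,control,1,1.31
Asp,1,0,control,2,0.96
Asp,0,1,natural,,3.19
Asp,0,1,13CO2,1,11.85
Asp,0,1,13CO2,2,5.87
Asp,0,1,13CO2_acetate,1,15.76
Asp,0,1,13CO2_acetate,2,11.25
Asp,0,1,acetate_1,1,3.86
Asp,0,1,acetate_1,2,4.04
Asp,0,1,acetate_2,1,5.15
Asp,0,1,acetate_2,2,6.11
Asp,0,1,control,1,2.81
Asp,0,1,control,2,2.76
Asp,1,1,natural,,0.04
Asp,1,1,13CO2,1,2.41
Asp,1,1,13CO2,2,1.19
Asp,1,1,13CO2_acetate,1,3.49
Asp,1,1,13CO2_acetate,2,2.05
Asp,1,1,acetate_1,1,
Asp,1,1,acetate_1,2,
Asp,1,1,acetate_2,1,
Asp,1,1,acetate_2,2,
Asp,1,1,control,1,
Asp,1,1,control,2,
Asp,0,2,natural,,0.04
Asp,0,2,13CO2,1,1.9
Asp,0,2,13CO2,2,1.23
Asp,0,2,13CO2_acetate,1,2.85
Asp,0,2,13CO2_acetate,2,2.21
Asp,0,2,acetate_1,1,
Asp,0,2,acetate_1,2,
Asp,0,2,acetate_2,1,
Asp,0,2,acetate_2,2,
Asp,0,2,control,1,
Asp,0,2,control,2,
Asp,1,2,natural,,0
Asp,1,2,13CO2,1,0.4
Asp,1,2,13CO2,2,
Asp,1,2,13CO2_acetate,1,0.76
Asp,1,2,13CO2_acetate,2,0.37
Asp,1,2,acetate_1,1,
Asp,1,2,acetate_1,2,
Asp,1,2,acetate_2,1,
Asp,1,2,acetate_2,2,
Asp,1,2,control,1,
Asp,1,2,control,2,
Asp,0,3,natural,,0
Asp,0,3,13CO2,1,
Asp,0,3,13CO2,2,
Asp,0,3,13CO2_acetate,1,
Asp,0,3,13CO2_acetate,2,
Asp,0,3,acetate_1,1,
Asp,0,3,acetate_1,2,
Asp,0,3,acetate_2,1,
Asp,0,3,acetate_2,2,
Asp,0,3,control,1,
Asp,0,3,control,2,
Asp,1,3,natural,,0
Asp,1,3,13CO2,1,
Asp,1,3,13CO2,2,
Asp,1,3,13CO2_acetate,1,
Asp,1,3,13CO2_acetate,2,
Asp,1,3,acetate_1,1,
Asp,1,3,acetate_1,2,
Asp,1,3,acetate_2,1,
Asp,1,3,acetate_2,2,
Asp,1,3,control,1,
Asp,1,3,control,2,
Glu,0,0,natural,,94.62
Glu,0,0,13CO2,1,71.81
Glu,0,0,13CO2,2,84.11
Glu,0,0,13CO2_acetate,1,65.74
Glu,0,0,13CO2_acetate,2,73.99
Glu,0,0,acetate_1,1,93.05
Glu,0,0,acetate_1,2,93.52
Glu,0,0,acetate_2,1,92.35
Glu,0,0,acetate_2,2,91.52
Glu,0,0,control,1,94.67
Glu,0,0,control,2,94.54
Glu,1,0,natural,,1.05
Glu,1,0,13CO2,1,4.14
Glu,1,0,13CO2,2,4.19
Glu,1,0,13CO2_acetate,1,6.11
Glu,1,0,13CO2_acetate,2,5.27
Glu,1,0,acetate_1,1,1.83
Glu,1,0,acetate_1,2,1.09
Glu,1,0,acetate_2,1,1.5
Glu,1,0,acetate_2,2,1.37
Glu,1,0,control,1,1.26
Glu,1,0,control,2,1.2
Glu,0,1,natural,,4.21
Glu,0,1,13CO2,1,16.36
Glu,0,1,13CO2,2,7.69
Glu,0,1,13CO2_acetate,1,17.85
Glu,0,1,13CO2_acetate,2,13.57
Glu,0,1,acetate_1,1,5.12
Glu,0,1,acetate_1,2,5.39
Glu,0,1,acetate_2,1,6.14
Glu,0,1,acetate_2,2,7.11
Glu,0,1,control,1,4.08
Glu,0,1,control,2,4.26
Glu,1,1,natural,,0.05
Glu,1,1,13CO2,1,2.56
Glu,1,1,13CO2,2,1.31
Glu,1,1,13CO2_acetate,1,3.28
Glu,1,1,13CO2_acetate,2,2.36
Glu,1,1,acetate_1,1,
Glu,1,1,acetate_1,2,
Glu,1,1,acetate_2,1,
Glu,1,1,acetate_2,2,
Glu,1,1,control,1,
Glu,1,1,control,2,
Glu,0,2,natural,,0.07
Glu,0,2,13CO2,1,3.95
Glu,0,2,13CO2,2,1.83
Glu,0,2,13CO2_acetate,1,5.26
Glu,0,2,13CO2_acetate,2,3.71
Glu,0,2,acetate_1,1,
Glu,0,2,acetate_1,2,
Glu,0,2,acetate_2,1,
Glu,0,2,acetate_2,2,
Glu,0,2,control,1,
Glu,0,2,control,2,
Glu,1,2,natural,,0
Glu,1,2,13CO2,1,0.77
Glu,1,2,13CO2,2,0.56
Glu,1,2,13CO2_acetate,1,1.18
Glu,1,2,13CO2_acetate,2,0.75
Glu,1,2,acetate_1,1,
Glu,1,2,acetate_1,2,
Glu,1,2,acetate_2,1,
Glu,1,2,acetate_2,2,
Glu,1,2,control,1,
Glu,1,2,control,2,
Glu,0,3,natural,,0
Glu,0,3,13CO2,1,0.42
Glu,0,3,13CO2,2,0.32
Glu,0,3,13CO2_acetate,1,0.57
Glu,0,3,13CO2_acetate,2,0.36
Glu,0,3,acetate_1,1,
Glu,0,3,acetate_1,2,
Glu,0,3,acetate_2,1,
Glu,0,3,acetate_2,2,
Glu,0,3,control,1,
Glu,0,3,control,2,
Glu,1,3,natural,,0
Glu,1,3,13CO2,1,
Glu,1,3,13CO2,2,
Glu,1,3,13CO2_acetate,1,
Glu,1,3,13CO2_acetate,2,
Glu,1,3,acetate_1,1,
Glu,1,3,acetate_1,2,
Glu,1,3,acetate_2,1,
Glu,1,3,acetate_2,2,
Glu,1,3,control,1,
Glu,1,3,control,2,
Glu,0,4,natural,,0
Glu,0,4,13CO2,1,
Glu,0,4,13CO2,2,
Glu,0,4,13CO2_acetate,1,
Glu,0,4,13CO2_acetate,2,
Glu,0,4,acetate_1,1,
Glu,0,4,acetate_1,2,
Glu,0,4,acetate_2,1,
Glu,0,4,acetate_2,2,
Glu,0,4,control,1,
Glu,0,4,control,2,
Glu,1,4,natural,,0
Glu,1,4,13CO2,1,
Glu,1,4,13CO2,2,
Glu,1,4,13CO2_acetate,1,
Glu,1,4,13CO2_acetate,2,
Glu,1,4,acetate_1,1,
Glu,1,4,acetate_1,2,
Glu,1,4,acetate_2,1,
Glu,1,4,acetate_2,2,
Glu,1,4,control,1,
Glu,1,4,control,2,
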