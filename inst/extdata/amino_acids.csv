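name,code,formula,n_carbons,main_indices,side_indices,detectable,hydrolysis_fate,migration_time_s
Lysine,Lys,C6H14N2O2,6,1,2;3;4;5;6,TRUE,,45
Arginine,Arg,C6H14N4O2,6,1,2;3;4;5;6,TRUE,,50
Histidine,His,C6H9N3O2,6,1,2;3;4;5;6,TRUE,,56
Glycine,Gly,C2H5NO2,2,1,2,TRUE,,70
Alanine,Ala,C3H7NO2,3,1,2;3,TRUE,,75
Serine,Ser,C3H7NO3,3,1,2;3,TRUE,,80
Proline,Pro,C5H9NO2,5,1,2;3;4;5,TRUE,,85
Valine,Val,C5H11NO2,5,1,2;3;4;5,TRUE,,90
Threonine,Thr,C4H9NO3,4,1,2;3;4,TRUE,,95
Cysteine,Cys,C3H7NO2S,3,1,2;3,FALSE,degraded,100
Leucine,Leu,C6H13NO2,6,1,2;3;4;5;6,TRUE,,105
Isoleucine,Ile,C6H13NO2,6,1,2;3;4;5;6,TRUE,,118
Asparagine,Asn,C4H8N2O3,4,1,2;3;4,FALSE,deamidated,123
Glutamine,Gln,C5H10N2O3,5,1,2;3;4;5,FALSE,deamidated,127
Methionine,Met,C5H11NO2S,5,1,2;3;4;5,TRUE,,131
Tryptophan,Trp,C11H12N2O2,11,1,2;3;4;5;6;7;8;9;10;11,FALSE,degraded,135
Phenylalanine,Phe,C9H11NO2,9,1,2;3;4;5;6;7;8;9,TRUE,,139
Tyrosine,Tyr,C9H11NO3,9,1,2;3;4;5;6;7;8;9,TRUE,,144
Aspartate,Asp,C4H7NO4,4,1,2;3;4,TRUE,,155
Glutamate,Glu,C5H9NO4,5,1,2;3;4;5,TRUE,,162
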