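# Wood-Ljungdahl pathway alone: CO2 fixation to acetyl-CoA, pyruvate and
# oxaloacetate, without any reductive TCA operation. 2-oxoglutarate (and
# hence Glu/Pro) is not producible under this hypothesis.
#
# Free parameters: f (CO2 excess enrichment), d_ac (acetyl-CoA dilution),
# a_ac (acetate contribution to acetyl-CoA).

metabolite: CO2, 1
metabolite: acetate, 2
metabolite: acCoAwl, 2
metabolite: acetylCoA, 2
metabolite: pyruvate, 3
metabolite: OAA, 4
metabolite: Ser, 3
metabolite: Asp, 4
metabolite: Ala, 3
metabolite: Thr, 4

source: CO2 enrichment=f
source: acetate enrichment=0
dilute: acCoAwl fraction=d_ac

acCoAwl[ab] <- CO2[a] + CO2[b]
acetylCoA[ab] <- acCoAwl[ab] @ 1-a_ac
acetylCoA[ab] <- acetate[ab] @ a_ac
pyruvate[abc] <- CO2[a] + acetylCoA[bc]
OAA[abcd] <- pyruvate[abc] + CO2[d]

Ser[abc] <- pyruvate[abc]
Ala[abc] <- pyruvate[abc]
Asp[abcd] <- OAA[abcd]
Thr[abcd] <- OAA[abcd]
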