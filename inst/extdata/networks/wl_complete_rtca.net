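# Wood-Ljungdahl pathway plus a hypothetical COMPLETE reductive TCA cycle:
# the incomplete branch extended by reductive carboxylation of
# 2-oxoglutarate and citrate cleavage, recycling label into acetyl-CoA and
# oxaloacetate. The recycling flux fraction r closes the ring; at r=0 the
# network reduces to the incomplete variant.
#
# Citrate-lysis carbon bookkeeping (lumped through isocitrate/citrate):
# the cleaved acetyl moiety carries 2OG C5 (carboxyl) and C4 (methyl);
# the regenerated OAA carries the added CO2 as C1 and 2OG C3/C2/C1 as
# C2/C3/C4.
#
# Free parameters: f, d_ac, a_ac as in the incomplete network, plus
#   r - fraction of the acetyl-CoA / OAA fixation flux routed through
#       citrate cleavage (ring closure).

metabolite: CO2, 1
metabolite: acetate, 2
metabolite: acCoAwl, 2
metabolite: acCoAfix, 2
metabolite: acetylCoA, 2
metabolite: pyruvate, 3
metabolite: OAA, 4
metabolite: malate, 4
metabolite: fumarate, 4
metabolite: succinate, 4
metabolite: succinylCoA, 4
metabolite: 2OG, 5
metabolite: Ser, 3
metabolite: Asp, 4
metabolite: Glu, 5
metabolite: Ala, 3
metabolite: Thr, 4
metabolite: Pro, 5

source: CO2 enrichment=f
source: acetate enrichment=0
dilute: acCoAwl fraction=d_ac
symmetric: fumarate
symmetric: succinate

# carbon-fixation-derived acetyl-CoA: WL route or citrate cleavage
acCoAwl[ab] <- CO2[a] + CO2[b]
acCoAfix[ab] <- acCoAwl[ab] @ 1-r
acCoAfix[ab] <- 2OG[cdeba] @ r
acetylCoA[ab] <- acCoAfix[ab] @ 1-a_ac
acetylCoA[ab] <- acetate[ab] @ a_ac

pyruvate[abc] <- CO2[a] + acetylCoA[bc]

# oxaloacetate: anaplerotic carboxylation or regeneration by citrate cleavage
OAA[abcd] <- pyruvate[abc] + CO2[d] @ 1-r
OAA[abcd] <- 2OG[dcbef] + CO2[a] @ r

malate[abcd] <- OAA[abcd]
fumarate[abcd] <- malate[abcd]
succinate[abcd] <- fumarate[abcd]
succinylCoA[abcd] <- succinate[abcd]
2OG[abcde] <- CO2[a] + succinylCoA[bcde]

Ser[abc] <- pyruvate[abc]
Ala[abc] <- pyruvate[abc]
Asp[abcd] <- OAA[abcd]
Thr[abcd] <- OAA[abcd]
Glu[abcde] <- 2OG[abcde]
Pro[abcde] <- Glu[abcde]
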