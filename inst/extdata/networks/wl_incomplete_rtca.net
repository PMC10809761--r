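# Wood-Ljungdahl pathway plus the incomplete reductive TCA branch
# (oxaloacetate -> 2-oxoglutarate; no aconitase, no isocitrate dehydrogenase,
# hence no ring closure). Carbon slots are letters; carbon 1 of every amino
# acid is the carboxyl carbon lost in the immonium fragment.
#
# Free parameters:
#   f    - excess 13C enrichment of the CO2 pool
#   d_ac - fraction of the acetyl-CoA pool drawn from an unlabeled reservoir
#   a_ac - fraction of the acetyl-CoA pool derived from exogenous acetate

metabolite: CO2, 1
metabolite: acetate, 2
metabolite: acCoAwl, 2
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

# acetyl-CoA: carbonyl (a) and methyl (b) both CO2-derived in the WL pathway;
# a fraction a_ac of the pool comes from exogenous acetate instead
acCoAwl[ab] <- CO2[a] + CO2[b]
acetylCoA[ab] <- acCoAwl[ab] @ 1-a_ac
acetylCoA[ab] <- acetate[ab] @ a_ac

# pyruvate synthase: new carboxyl C1 from CO2, C2/C3 from acetyl-CoA
pyruvate[abc] <- CO2[a] + acetylCoA[bc]

# anaplerotic carboxylation of pyruvate: new carboxyl becomes OAA C4
OAA[abcd] <- pyruvate[abc] + CO2[d]

# reductive TCA branch down to succinyl-CoA (symmetric intermediates scramble)
malate[abcd] <- OAA[abcd]
fumarate[abcd] <- malate[abcd]
succinate[abcd] <- fumarate[abcd]
succinylCoA[abcd] <- succinate[abcd]

# 2-oxoglutarate synthase: carboxylation of succinyl-CoA, new carbon is C1
2OG[abcde] <- CO2[a] + succinylCoA[bcde]

# precursor -> amino acid carbon maps
Ser[abc] <- pyruvate[abc]
Ala[abc] <- pyruvate[abc]
Asp[abcd] <- OAA[abcd]
Thr[abcd] <- OAA[abcd]
Glu[abcde] <- 2OG[abcde]
Pro[abcde] <- Glu[abcde]
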