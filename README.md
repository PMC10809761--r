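# tracemid

¹³C tracer-based metabolomics of underivatized proteinogenic amino acids
measured by CE-MS: from raw peak lists to natural-abundance-corrected mass
isotopomer distributions (MIDs), main-chain/side-chain positional
isotopomer tables resolved from MS/MS fragments, and atom-transition-
network-based discrimination of carbon-fixation pathway hypotheses.

The package is built around the central-carbon metabolism of
hydrogenotrophic methanogens such as *Methanothermobacter
thermautotrophicus*, which fix CO₂ through the Wood–Ljungdahl (WL)
pathway and are thought to run only an *incomplete* reductive TCA cycle
(oxaloacetate → 2-oxoglutarate, with no aconitase or isocitrate
dehydrogenase to close the ring). It is aimed at microbiologists and
metabolomics analysts who want to turn isotopologue peak areas into
pathway-level conclusions without hand-built spreadsheets.

## What it computes

For an *n*-carbon analyte, the measured MID is the tracer-only MID
convolved with the natural ¹³C background (each carbon independently ¹³C
with *p* = 0.011):

```
m_k = Σ_{j≤k} x_j · C(n−j, k−j) · p^(k−j) · (1−p)^(n−k)
```

`correct_mid()` inverts this by non-negative least squares. MS/MS of
protonated amino acids loses the carboxyl carbon (H₂O + CO), so the
fragment MID measures carbons C2..Cn; `split_positional()` deconvolves the
precursor and fragment MIDs into the joint (main-chain, side-chain)
label-count table, which is uniquely determined when the main chain is the
single carboxyl carbon. `simulate_isotopomers()` propagates a tracer
through a carbon atom-transition network (plain-text reaction maps with
per-carbon letters) to steady state, and `fit_hypothesis()` /
`compare_hypotheses()` fit tracer and dilution parameters per pathway
hypothesis and rank the hypotheses — the computational form of the
argument that labeled-carbon enrichment ordering Glu > Asp > Ser implies
an incomplete reductive cycle.

## Worked example

Correct the bundled ¹³CO₂-labeled measurements (replicate 1) and rank the
pathway hypotheses:

```r
library(tracemid)

res <- run_reference_analysis("13CO2", replicate = 1)
round(100 * res$ordering$enrichments, 2)
#>  Glu  Asp  Ser
#> 6.40 5.51 4.49
res$ordering$holds
#> [1] TRUE
res$ranking$id
#> [1] "WL_incomplete_rTCA" "WL_complete_rTCA"
```

The enrichments are the mean fraction of labeled carbons per analyte after
removing the natural ¹³C background: glutamate (6.4%) exceeds aspartate
(5.5%) exceeds serine (4.5%), and the incomplete-rTCA hypothesis ranks
above the complete ring — the extra recycling parameter buys no real
improvement in fit.

A fully synthetic round trip, from pathway simulation to recovered
parameters:

```r
hyp <- hypothesis_wl_incomplete_rtca("CO2")
ds  <- generate_dataset(hyp, params = list(f = 0.2, d_ac = 0.75),
                        noise = noise_model(seed = 42),
                        out_dir = "demo-data")
cfg <- run_config(precursor = "demo-data/precursor.csv",
                  fragments = "demo-data/fragments.csv")
out <- run_study(cfg)
round(unlist(out$fits$WL_incomplete_rTCA$parameters), 4)
#>      f   d_ac
#> 0.1946 0.7304
```

The generating CO₂ enrichment (0.20) and acetyl-CoA dilution (0.75) are
recovered from the noisy peak lists. A thin command-line front end with
the same functionality is installed as `exec/tracemid`
(`tracemid generate|correct|run`).

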