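---
title: "Methods: 13C tracer MIDs, positional isotopomers, and pathway inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 13C tracer MIDs, positional isotopomers, and pathway inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracemid)
```

## The problem

A hydrogenotrophic methanogen grows on H2/CO2 and fixes carbon through the
Wood-Ljungdahl (WL) pathway; genomic evidence suggests its TCA cycle is
incomplete (no aconitase, no isocitrate dehydrogenase), operating only
reductively from oxaloacetate to 2-oxoglutarate. Feeding ¹³CO₂ or
position-labeled acetate and measuring the mass isotopomer distributions
(MIDs) of protein-derived amino acids by CE-MS lets one discriminate these
topologies: serine carbons come from pyruvate, aspartate's from
oxaloacetate, glutamate's from 2-oxoglutarate, and every step down that
chain adds one more CO₂-derived carboxyl carbon. Under an *incomplete*
reductive cycle the labeled-carbon enrichment must order
Glu > Asp > Ser; ring closure (a complete reductive cycle) would recycle
label from 2-oxoglutarate back into acetyl-CoA and oxaloacetate and erode
the ordering. This package implements the full computational chain from
peak lists to that inference.

## From peak lists to corrected MIDs

**Annotation.** Analytes are assigned by accurate mass (`[M+H]+` at
charge +1; default tolerance 5 ppm, which brackets the few-ppm errors of a
well-calibrated Orbitrap) and, where masses coincide (Leu/Ile), by a
migration-time window (default ±6 s around reference times from a standard
mixture). Isotopologue peaks are collected at multiples of 1.003355 Th
(the ¹³C-¹²C mass difference) from the matched peak — unit spacing would
be ~32 ppm off at m/z 106 and collect nothing at a 5 ppm tolerance.

**Natural-abundance model.** Each of the n carbons of an analyte carries
natural ¹³C independently with probability $p = 0.011$. The measured MID
is a lower-triangular binomial convolution of the tracer-only MID,

$$m_k = \sum_{j \le k} x_j \binom{n-j}{k-j} p^{k-j} (1-p)^{n-k-j+j},$$

and correction solves $m = A x$ by non-negative least squares followed by
renormalization. The plain triangular inversion is retained as an internal
cross-check (`method = "inverse"`); the two agree to the displayed digits
on clean spectra and differ only in how small negative components from
truncated ("not detected") isotopologues are removed. Only carbon is
corrected: at the resolutions considered, the printed natural-abundance
columns of the study's tables match the carbon-only binomial to every
digit, so H/N/O/S corrections would be over-modeling. Tracer purity is
taken as 100%.

**Positional split.** MS/MS of protonated amino acids proceeds by loss of
H₂O + CO from the carboxyl group, so the immonium-type fragment retains
carbons C2..Cn. The package therefore partitions every amino acid into a
one-carbon "main chain" (the carboxyl C1) and an (n−1)-carbon "side
chain"; with a single main-chain carbon the joint (main, side) label-count
table is uniquely determined by the precursor MID and the side-chain
fragment MID, and `split_positional()` recovers it exactly on noiseless
input (non-negative least squares on the stacked marginal equations). For
hypothetical multi-carbon main chains the least-squares optimum is a set —
all joints sharing the fitted marginals — and the maximum-entropy member
is selected by iterative proportional fitting from a uniform start, which
is deterministic and reduces to the unique solution when it exists.
Fragment MIDs are corrected with the fragment's own carbon count before
splitting.

## The atom-transition network simulator

Networks are plain text: metabolites with carbon counts, reactions with
per-carbon letter maps, tracer source pools, an optional unlabeled-
reservoir dilution per pool, optional relative flux weights when several
reactions feed one pool, and a `symmetric:` directive that averages the
two orientations of succinate and fumarate 50/50. States are probability
vectors over the $2^n$ binary labeling patterns (n ≤ 8 enforced — amino
acid precursors need at most 6). The steady state is the fixed point of
"product state = atom-mapped tensor product of substrate states, mixed
over producing reactions, then diluted"; acyclic networks are solved in
one topological pass, and cyclic ones (label recycling through citrate
cleavage) iterate the cyclic core to a $10^{-12}$ fixed point before a
final downstream pass.

Three networks ship. All share the WL core (both acetyl-CoA carbons from
CO₂), pyruvate synthesis (new carboxyl from CO₂), anaplerotic
carboxylation to oxaloacetate, and the reductive branch to 2-oxoglutarate
(new C1 from CO₂ via succinyl-CoA carboxylation). The complete-rTCA
variant adds reductive carboxylation of 2-oxoglutarate and citrate
cleavage with a recycling flux fraction `r`; at `r = 0` it reduces exactly
to the incomplete variant.

Two modeling choices deserve comment:

* **Excess-label frame.** Simulation and fitting work in the tracer-only
  frame: an unenriched CO₂ pool has excess enrichment 0, and natural ¹³C
  enters exactly once — via the forward convolution in the generator, or
  its removal in `correct_mid()`. Mixing natural abundance into the
  source pools *and* convolving would double-count it.
* **Where the unlabeled reservoir enters.** The dilution parameter `d_ac`
  exists because acetyl-CoA-derived carbons (Ser C2/C3) are observed less
  enriched than directly CO₂-derived carboxyls. The entry point of that
  unlabeled carbon is not identifiable from the data; the networks place
  it on the WL-derived acetyl units, upstream of acetate mixing and of
  recycling. Placing it on the pooled acetyl-CoA instead would re-dilute
  recycled label on every turn of the complete cycle and reverse the
  qualitative recycling signature (complete ≥ incomplete Ser/Asp
  enrichment) that makes the hypotheses distinguishable.

With CO₂ excess enrichment $f$ and acetyl-CoA per-carbon enrichment
$a = f(1 - d_{ac})$, the simulator reproduces the closed-form mean labels
$(2a+f)/3$, $(2a+2f)/4$ and $(2a+3f)/5$ for Ser, Asp and Glu, so the
ordering Glu > Asp > Ser holds exactly when $f > a$ — the quantitative
form of the qualitative argument above.

## Hypothesis fitting and ranking

`fit_hypothesis()` minimizes the weighted residual sum of squares between
predicted and corrected observed MID fractions over the bounded parameter
box $[0,1]^k$ ($k \le 3$ for the shipped hypotheses): an exhaustive coarse
grid (step 0.05 up to two parameters, 0.2 beyond, where each evaluation is
a full network simulation) followed by deterministic box-constrained
L-BFGS-B refinement from the three best grid points. Multi-start
refinement matters: the complete-rTCA RSS surface has a curved valley in
which single-start axis-aligned search can stall.

The default objective uses *relative* residuals,
$\sum ((\hat m_k - m_k)/(m_k + 0.01))^2$. CE-MS areas span four orders of
magnitude and their noise is multiplicative, so after normalization the
absolute error of a fraction scales with its size; relative residuals are
approximately homoscedastic, whereas unweighted least squares is dominated
by the (noisy) M+0 entry and leaves the small informative isotopologues
with almost no influence. `weighting = "none"` restores plain least
squares for users who prefer it.

Ranking (`compare_hypotheses()`) orders fits by RSS with a deterministic
parsimony guard: the complete-rTCA hypothesis *nests* the incomplete one
(`r = 0`), so on noisy data its extra bounded parameter always absorbs
some residual. A richer model therefore only outranks a smaller one when
its RSS improvement per extra parameter exceeds `parsimony` (default 15)
(default) times its own per-degree-of-freedom residual — an F-ratio-shaped heuristic
rather than a significance test (replicate counts here are far too small
for a calibrated error model, which is also why no information criterion
is used). The default was chosen by simulating the null (data generated
from the smaller model at the study's noise level) on a dedicated
calibration seed set and picking the smallest factor that does not reward
one parameter of pure noise absorption, while leaving genuinely
recycling-labeled data (which misfit the incomplete model by an order of
magnitude or more in weighted RSS) ranked under the complete variant.
Exact ties break toward fewer parameters. The RSS machinery formalizes
what the original study argued qualitatively; reports should treat the
ranking, not any RSS value, as the result.

For acetate tracer experiments the CO₂ pool is pinned at natural abundance
(zero excess) and only the acetate contribution to acetyl-CoA is fitted;
the trace co-feed (0.01% w/v) is expected to leave fixation fluxes
untouched.

## The synthetic-data generator

`generate_dataset()` emulates the measurement chain so every stage is
testable without instrument data: simulate tracer-only states → convolve
natural abundance (jointly over the main/side bipartition, so fragment
data stay consistent) → scale fractions to areas → apply noise → write
peak lists. Defaults were chosen once to bracket the printed diagnostics
of the real acquisitions: multiplicative log-normal area noise with 5% CV
(areas in the study span 4119 to ~2×10⁷, so additive noise would be
wrong); uniform ±2 ppm mass jitter (observed errors 0.04-4.61 ppm);
Gaussian ±2 s migration-time jitter against reference times (with the
default ±6 s matching window this loses an analyte in well under 1% of
runs — such runs count as failures in the recovery harness); 20 baseline
peaks per spectrum with areas log-uniform below the smallest analyte peak,
so a baseline peak can never out-compete a real analyte within a matching
window; per-analyte abundance scales log-uniform over three orders of
magnitude. Migration times follow the fixed plausible order charged <
neutral < acidic rather than an electrophoretic model. The generator does
not emulate profile-mode peak shapes, ion statistics at very low signal,
detector saturation, or correlated drift across a batch — so passing
recovery tests demonstrate correctness of the computational chain under
the stated noise model, not robustness to every instrument pathology.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 1000 random simplex points
per carbon count for the correction round-trip (tolerance 1e-8);
exhaustive tree-recursion enumeration against the simulator on the
acyclic networks (tolerance 1e-10; the cyclic variant is checked against
a depth-80 truncated recursion at 1e-4, the truncation residual being
~r¹⁰); and a recovery harness of 4 parameter combinations × 20 seeds with
full pipeline refits. Solver tolerances: NNLS as implemented by
`pracma::lsqnonneg`; simulator fixed point 1e-12 with a 10,000-sweep
guard; IPF 1e-12 with 1000 iterations. Percent values reproduce printed
tables with half-up rounding to two decimals. Degenerate inputs are
rejected early: all-zero area vectors (undetected analyte), all-zero
solutions of the positional split, empty observed/predictable overlap in
fitting.

## Known limitations

* The main/side bipartition is the finest positional resolution the
  fragment data support; per-carbon isotopomers are not resolved.
* Steady-state labeling only; no kinetics, no time courses (the study
  design has a single harvest at 48 h).
* The effective intracellular CO₂ enrichment under a 5% headspace spike is
  unknown (dissolution and exchange); it is always a free parameter and is
  never asserted to equal the headspace value.
* Model discrimination is a deterministic heuristic ranking, not a
  statistical test; with duplicate cultures there is no basis for error
  bars on RSS differences.
* Isotope fine structure, adducts, multimers and electron-mass refinements
  are out of scope; charge is fixed at +1.
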