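# pioneerCoop

Tools for studying how pioneer transcription factors (TFs) open chromatin
cooperatively. Low-affinity TF motifs often contribute to chromatin
accessibility only through distance-dependent ("soft syntax",
intra-nucleosomal, < ~200 bp) cooperation with stronger pioneer motifs
nearby. `pioneerCoop` implements the computational stack needed to study
this quantitatively on data with known ground truth:

1. **A kinetic model of TF–nucleosome competition out of equilibrium.**
   Chromatin at a locus is closed (nucleosome present) or open; a TF binds
   and unbinds in either conformation. The chain over
   (conformation × occupancy) — 4 states for one TF, 8 for two — evolves by
   Markovian dynamics with rates:
   binding `k_on` (concentration-absorbed, diffusion-limited); unbinding
   `g·k_off` (open + motif, `1/g` is the motif affinity), `k_off` (open),
   `β_n·k_off` / `β_m·g·k_off` (closed); opening `k_open·∏o` and closing
   `(k_open/d)/∏c` over bound TFs (Arrhenius multiplicativity — additive
   effects on the activation energy). Steady states come from the
   nullspace of the column-Laplacian rate matrix; accessibility is the
   total open-state probability. The no-TF baseline is `d/(1+d)` and the
   saturating-concentration plateau is `(o·c·d)/(1+o·c·d)` — independent
   of motif affinity `g`, which only shifts the dose–response curve.
   Detailed balance holds exactly when `o·c = β_m`; otherwise the system
   is driven, as expected for ATP-dependent nucleosome remodeling.

2. **In silico motif scoring against any sequence → log-counts predictor.**
   *Isolation scores* (motif injected into 256 dinucleotide-shuffled,
   GC/CpG-matched backgrounds; a proxy for intrinsic motif strength),
   *context scores* (motif ablated in situ by random replacement, 16
   trials), and *pairwise cooperativity*: joint effect `(AB − null)`
   versus marginal `((A − null) + (B − null))` in exponentiated-counts
   space, score `log(joint/marginal)`. Distance-binned significance uses
   a one-tailed Wilcoxon rank-sum test of each 10-bp bin against far
   pairs (> 400 bp), Bonferroni-corrected at p < 1e-7, bins with < 20
   pairs excluded.

3. **CWM scanning.** Motif instances are mapped onto per-base contribution
   tracks with the two seqlet-derived criteria — continuous Jaccard
   similarity above the 20th seqlet percentile and L1 contribution
   magnitude above the minimum seqlet contribution, with no PWM log-odds
   requirement — followed by redundancy/palindrome resolution and
   information-content PWM percentiles.

4. **A synthetic-data generator** planting motifs of graded affinity
   (0/1/2 consensus mismatches) with distance-dependent superadditive
   interactions `κ(d) = κ₀·e^(−d/τ)` below a 200 bp cutoff, matching
   contribution tracks and fabricated seqlet statistics — so every score
   and scanner can be validated against known ground truth.

## Worked example

A Sox2-like TF (`k_on = 0.1 s⁻¹`, `k_off = 1 s⁻¹`, motif affinity
`1/g = 100`, nucleosome dissociation constant `d = 0.01`, opening boost
`o = 10`, closing attenuation `c = 2`):

```r
library(pioneerCoop)
sox2 <- kineticParams(kOn = 0.1, kOff = 1, g = 0.01, betaN = 5, betaM = 5,
                      kOpen = 0.05, d = 0.01, o = 10, c = 2)
p <- steadyState(buildRateMatrix(sox2))
round(p, 4)
#> closed|- closed|A   open|-   open|A
#>   0.2992   0.5816   0.0032   0.1160
accessibility(p)
#> [1] 0.1191459
isolationLfcKinetic(sox2)
#> [1] 2.209712
```

The region is open 11.9% of the time (versus the 1.0% no-motif baseline:
the motif's isolation-equivalent log-fold-change is 2.21). Adding a fixed
cooperating partner TF raises both the response and the plateau:

```r
partner <- kineticParams(kOn = 0.05, g = 0.01, o = 10, c = 2, d = 0.01)
doseResponse(sox2, konGrid = 10^seq(-3, 3, by = 1.5), partner = partner)
#>            kOn accessibility
#> 1 1.000000e-03     0.1147375
#> 2 3.162278e-02     0.3964741
#> 3 1.000000e+00     0.6203184
#> 4 3.162278e+01     0.6324111
#> 5 1.000000e+03     0.6327520
cooperativityKinetic(sox2, partner)
#>   p_null    p_A    p_B   p_AB  joint marginal  score valid
#> 1  0.015 0.1318 0.1141 0.5263 0.5113   0.2159 0.8623  TRUE
```

The two-TF plateau (0.633) far exceeds the single-TF plateau (0.167
for these parameters): the joint accessibility gain (0.51) is 2.4-fold
the sum of the marginal gains (0.22), a cooperativity score of 0.86 —
cooperation raises the motif's regulatory potential in a way that
increasing affinity alone cannot.

The same analyses run against any predictor satisfying the
sequence → log-counts contract: see `isolationScore()`, `contextScore()`,
`pairwiseCooperativity()`, `binnedCooperativityTest()`, `cwmScan()` and
the synthetic ground-truth generator `simulateRegions()` /
`syntheticPredictor()` / `syntheticContributions()`. The methods
vignette (`vignettes/pioneer-cooperativity.Rmd`) documents the model,
the scores and every numerical design choice.

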