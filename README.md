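# vdomics

Analysis pipeline for tracking **virus-derived dissolved organic matter
(vDOM)** in ultrahigh-resolution mass spectrometry data.

When prophages in sediment bacteria are induced into the lytic cycle,
the lysed cells release their molecular inventory into the pore water.
FT-ICR-MS resolves thousands of exact masses per DOM extract, each
assignable to a unique CHNOSP elemental composition, so the imprint of
viral lysis can be read directly from molecular-formula inventories of
treated versus control incubations. `vdomics` is for researchers running
such incubation experiments (or re-analysing deposited peak lists) who
need the full chain from raw peak lists to a defensible differential
formula set.

## What it computes

Given per-spectrum peak lists (m/z, intensity, S/N) and a sample table
(depth × treatment/control × day × replicate, plus blanks):

1. **Formula assignment** — candidate CHNOSP compositions for each
   [M−H]⁻ ion within a ppm tolerance (default 0.5 ppm), under
   plausibility rules (element ranges, H/C ∈ [0.3, 2.5], O/C ≤ 1.2,
   integer DBE ≥ 0, N+S+P ≤ 5); multiply assigned peaks resolved by the
   heteroatom priority ladder NSP, N2S, N3S, N4S, N2P, N3P, N4P, NS2,
   S2P (exact patterns, applied in order; unresolved peaks keep no
   formula).
2. **Quality control** — S/N ≥ 4; cross-spectrum alignment; per-spectrum
   detection limit raised by 5%; features required in ≥ 3 non-blank
   spectra; blank removal (blank S/N > 20× sample S/N, or present in
   ≥ 7 of 10 blanks); replicate-outlier handling; normalization to the
   spectrum's total remaining intensity.
3. **Classification** — DBE, modified aromaticity index
   AImod = (1 + C − 0.5·O − S − 0.5·H)/(C − 0.5·O − N − S − P), H/C and
   O/C (van Krevelen coordinates), and exclusive compound classes
   (saturated / aromatic / highly unsaturated / potential protein /
   unsaturated / other).
4. **vDOM detection and fate** — with presence defined as detection in
   *all* replicates, `vDOM = T6 \ (C6 ∪ T0 ∪ C0)`; persistence at the
   final day, removed fraction, and N/S/P content of the pulse.
5. **Statistics** — Hellinger transform, Bray–Curtis PCoA, permutation
   fitting of environmental vectors, permutation Spearman screening of
   single formulas; rarefaction Shannon/Pielou diversity for OTU tables
   and the virus-to-cell ratio.

A first-class **synthetic-data generator** (`sim_config()`,
`generate_formula_library()`, `simulate_experiment()`) emulates the
whole experiment — formula library, lysis pulse with configured
heteroatom content and decay, analytical triplicates with ppm-scale mass
jitter, noise peaks, planted blank contaminants — with a ground-truth
ledger, so recovery of the planted answer can be measured exactly.

## Worked example

```r
library(vdomics)

cfg   <- sim_config(seed = 1)              # study-scale defaults
truth <- generate_formula_library(cfg)     # 5000 background + 1230 pulse
sim   <- simulate_experiment(truth)        # 48 sample spectra + 10 blanks

out <- run_vdom_pipeline(sim$spectra, sim$meta)
out$report
#>             stage n_features n_spectra
#> 1         aligned      16658        58
#> 2 detection_limit      16583        58
#> 3  min_occurrence       6491        58
#> 4    blank_filter       6460        48
#> 5      normalized       6228        48

report <- vdom_analysis(out$table, depth = "subsurface")
report
#> vdom_report: 1218 formulas, removed fraction 0.593
#>   heteroatom content: N 63.0%, S 28.2%, P 20.1%

evaluate_vdom_recovery(report, truth)[c("precision", "recall")]
#> $precision
#> [1] 0.9909688
#> $recall
#> [1] 0.9813008

pcoa(bray_curtis_matrix(hellinger(out$table)), k = 2)
#> PCoA: 48 samples, axis variance 53.4%, 3.8%
```

Reading the numbers: of the 1,230 planted lysis-pulse formulas the
pipeline recovers 1,218, with 99.1% of the detected set truly planted;
the estimated removed fraction (0.593) sits within sampling error of
the configured 58% removal; the realized heteroatom content matches
the configured 63/28/20% N/S/P targets; and the first ordination axis
separates the time course, carrying 53% of the variance.

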