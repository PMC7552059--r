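---
title: "Tracking virus-derived DOM in FT-ICR-MS data: methods and design"
author: "vdomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking virus-derived DOM in FT-ICR-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When temperate viruses integrated in sediment bacteria are induced into
the lytic cycle (for example with mitomycin C), the burst cells release
their molecular inventory into the pore water. Ultrahigh-resolution mass
spectrometry (FT-ICR-MS) can resolve thousands of exact masses in the
dissolved organic matter (DOM) pool, each assignable to a unique CHNOSP
elemental composition. Comparing induced incubations against untreated
controls over time then identifies the *virus-derived* DOM (vDOM): the
molecular formulas that appear after the induction event, were absent
from the controls, and were absent from both arms at the start.

`vdomics` implements this analysis as a tested pipeline: peak lists in,
a quality-controlled formula table out, plus the differential set logic,
compound classification, ordination statistics and community-diversity
summaries that surround it. A synthetic-data generator with a ground
truth ledger makes every stage verifiable.

## Formula assignment

Peaks are singly deprotonated ions, so the neutral mass is
`m/z + 1.00727646688`. Candidate CHNOSP compositions within a ppm
tolerance of the neutral mass are enumerated exhaustively under
plausibility rules (`assignment_rules()`):

* tolerance 0.5 ppm — conservative relative to a calibration error
  below 0.07 ppm, configurable;
* element ranges C 1–100, H 1–200, N 0–4, O 0–60, S 0–2, P 0–1;
* H/C in [0.3, 2.5], O/C ≤ 1.2;
* double-bond equivalents `DBE = 1 + (2C − H + N + P)/2` must be a
  non-negative integer;
* combined heteroatoms N + S + P ≤ 5. Without this cap the element grid
  admits a 0.16 mDa mass-degenerate substitution
  (−5C +5H +4N −6O +2S +1P) that pairs ordinary CHO compositions with
  N4S2P-type candidates — heteroatom-richer than any combined class the
  double-assignment ladder below enumerates, and chemically implausible
  for natural DOM. The cap equals the richest ladder class (N4S, N4P).

The search loops over the heteroatom grid (N, S, P, O) and solves for
the carbon/hydrogen pair in the residual mass band; at sub-mDa
tolerances each carbon count admits at most one hydrogen count, so the
inner step is O(1). The enumerator is implemented in C++ for throughput
and proven exhaustive in the test suite against an independent R
brute-force oracle that sweeps the full carbon range with no pruning.

Peaks below a signal-to-noise ratio of 4 are never assigned. When more
than one candidate fits, candidates whose (N, S, P) composition exactly
matches the patterns NSP, N2S, N3S, N4S, N2P, N3P, N4P, NS2, S2P are
deleted in that order, stopping when one candidate remains; if several
still remain the peak keeps no formula. Patterns are matched exactly
(not "at least"), since the ladder's explicit N2S/N3S/N4S rungs would be
redundant under superset semantics.

## Quality control

The dataset-level filters run in a fixed order that mirrors the
workflow narrative: S/N ≥ 4 → alignment → raised detection limit →
minimum occurrence → blank removal → replicate outliers →
normalization.

* **Alignment** keys features by assigned formula; unassigned peaks are
  clustered across spectra by single-linkage on m/z (sorted masses are
  split at gaps larger than the tolerance, which is exactly single
  linkage in one dimension). Each spectrum's minimum detected intensity
  is recorded here, once, as its detection limit.
* **Raised detection limit**: entries below 1.05× the recorded limit
  are set to not-detected, absorbing slight between-spectrum
  sensitivity differences. Because the limit is stored rather than
  recomputed, the filter is idempotent; recomputing it would remove the
  new minimum on every pass.
* **Minimum occurrence**: features detected in fewer than 3 non-blank
  spectra of the whole dataset are removed. The count is taken across
  the entire experiment, not per replicate group, and blanks never
  count.
* **Blank rules**: a feature is removed everywhere if its maximum blank
  S/N exceeds 20× its maximum sample S/N, or if it is detected in at
  least 7 of the 10 blanks. The 20× comparison aggregates by maximum on
  both sides; per-sample variants would also be defensible, and the
  thresholds are configuration keys.
* **Replicate outliers**: a manual id list (mirroring manual curation)
  or a Bray–Curtis distance rule against the replicate-group mean
  profile. Removing every replicate of a condition is an error.
* **Normalization** divides each spectrum by its total remaining
  assigned intensity; unassigned features are reported separately and
  never silently dropped.

## Indices and compound classes

`DBE` and the modified aromaticity index
`AImod = (1 + C − 0.5·O − S − 0.5·H) / (C − 0.5·O − N − S − P)` (zero
when numerator or denominator is non-positive, capped at 1) drive the
classification: aromatic (AImod > 0.5), highly unsaturated
(AImod ≤ 0.5 and H/C < 1.5), unsaturated (H/C ≥ 1.5 and DBE ≠ 0),
saturated (DBE = 0), potential protein (H/C ≥ 1.5, DBE ≠ 0, N > 0).
The raw rules overlap — every potential protein is also unsaturated —
so a fixed precedence makes labels exclusive: saturated first (DBE = 0
is unambiguous), then aromatic, highly unsaturated, potential protein,
unsaturated, other. Class "relative abundance" trajectories default to
intensity weighting; a count weighting is provided because formula-count
percentages are also in common use, and the two differ whenever
intensities are uneven.

## vDOM set logic

Presence of a formula in a condition requires detection in **every**
non-outlier analytical replicate (`presence_set()`, rule
`all_replicates`; `any_replicate` is retained for sensitivity
analyses). With `T6`, `C6` the treatment/control presence sets at the
induction time point and `T0`, `C0` at day 0:

```
vDOM = T6 \ (C6 ∪ T0 ∪ C0)
```

"Corresponding control" is read as the control at the same time point;
`exclude_control_all_days = TRUE` gives the stricter union over all
control days. Persistence compares vDOM against the treatment presence
set at the final day; `removed_fraction = 1 − |persistent|/|vDOM|`.
Heteroatom content is the share of vDOM formulas containing at least
one N, S or P (overlapping shares; they need not sum to 1).

## Ordination and permutation statistics

Normalized tables are Hellinger-transformed (square root of relative
abundances) before Bray–Curtis dissimilarity and principal coordinate
analysis. PCoA is classical scaling (Gower centring of −D²/2); negative
eigenvalues are reported without Cailliez/Lingoes correction and the
explained fractions are computed over positive eigenvalues only.
Environmental vectors are fitted to the first two axes by least squares;
significance uses label permutations with the convention
`p = (1 + #{permuted r² ≥ observed}) / (n_perm + 1)`, which can never
return zero. The Spearman screen correlates each formula with each
environmental parameter (average ranks for ties, two-sided permutation
p), reporting raw p-values against a 0.001 cutoff with **no**
multiple-testing correction — deliberately, as a screening step.
Both tests are checked for type-I calibration in the test suite
(rejection rate at α = 0.05 inside the exact binomial 95% interval
over 200 simulated nulls with 500 permutations each) and the vector
fit is cross-checked against `vegan::envfit`.

## Community diversity

OTU tables are rarefied by subsampling without replacement (11,000
reads, 30 repeats by default — "bootstraps" in the loose sense of
repeated rarefactions). Shannon diversity uses the natural logarithm
and Pielou's evenness is `J = H / ln(richness)` of the rarefied sample,
zero for single-OTU samples. Published tables of H and J from such
workflows are often mutually inconsistent under any single logarithm
base, so the base here is declared rather than inferred, and no
literature values are treated as reproduction targets. Taxa whose
relative abundance stays below 1% in every sample are merged into an
"Others" group only then — a taxon that exceeds the threshold in a
single sample stays separate.

## The synthetic experiment

`sim_config()` encodes the emulated study conditions: 2 depths ×
{treatment, control} × days {0, 6, 14, 55} × 3 analytical replicates
plus 10 blanks; a background library of 5,000 formulas; a lysis pulse
of 1,230 biomolecule-like formulas injected into the subsurface
treatment at day 6 (the surface arms simulate the no-induction null);
63/28/20% of the pulse containing N/S/P; 58% of the pulse undetectable
by day 55; mass jitter of 0.05 ppm, within the instrument's calibration
error. Design choices worth spelling out:

* **Exact-count allocation.** Heteroatom membership and the removed
  subset are allocated by exact counts (`round(p·n)`), not i.i.d.
  coin flips, so the configured rates *are* the ground truth and any
  discrepancy measured downstream is attributable to the pipeline.
* **Identifiable composition space.** Library and pulse formulas are
  sampled so that each exact mass resolves back to its own formula
  under the assignment rules. The generator emulates the molecular
  formulas a workflow can identify — counts in this field are always
  post-identification counts — and a planted truth that no method
  could recover would conflate instrument physics with pipeline
  defects. Mass-degenerate compositions still appear in the enumeration
  tests; they are simply never planted as truth.
* **Intensities** are log-normal (meanlog log(5e5), sdlog 0.9) with
  20% replicate scatter; the true intensity distribution of DOM peaks
  is unknown, so this assumption is exposed in the configuration.
  Detection is Bernoulli with a logistic curve in log10 intensity
  (midpoint 10^3.5, scale 0.3 decades), giving near-certain detection
  for mid-library intensities and a soft floor consistent with the
  raised-detection-limit filter having something to do.
* **Decay** uses the simplest two-point model: full pulse at day 6,
  intensity attenuation (0.6) at day 14, removed subset absent at
  day 55. The true kinetics are unobserved.
* **Blanks** carry three planted populations: library-derived
  contaminants in exactly 5 of 10 blanks at S/N far above their sample
  level (exercising the 20× rule alone), blank-specific small molecules
  (< 600 Da) in exactly 9 of 10 blanks (exercising the majority rule),
  and trace random carryover that must *survive* the rules.
* **Noise peaks** (400 per spectrum) are uniform in m/z with half drawn
  below S/N 4; they exercise the S/N threshold, the alignment of
  unassigned features and the occurrence filter.
* The OTU generator is Dirichlet-multinomial: a "stabilized" scenario
  with constant expected composition, and a "bloom" scenario
  concentrating reads onto a few copiotrophic OTUs so evenness falls
  over time. The environmental table follows linear-in-day trends with
  the virus-to-cell ratio of the induced arm rising from ~34 to ~77
  through day 14.

What the generator does **not** emulate: isotopologue patterns, adducts
other than [M−H]⁻, multiply charged ions, ionization efficiency or
matrix effects, scan averaging, or between-day drift. Passing tests
therefore demonstrate correctness of the *data analysis* under the
stated error model, not robustness to every instrumental artefact.

## Problem sizes and numerical choices

The test suite runs the full study-scale experiment (58 spectra,
~270,000 peaks) once, end to end; unit tests use scaled-down libraries
(tens to hundreds of formulas) chosen to keep the suite comfortably
inside a coffee break while still exercising every rule at its
boundary. Worked-example values (glucose 180.0633881 Da, DBE and AImod
of benzene/benzoic acid, Bray–Curtis of small vectors, Shannon limits)
were computed independently of the code paths they check. Permutation
seeds are explicit everywhere; the generator refuses to run without
one.

## Limitations

* Structural isomers are invisible to formula-level analysis; compound
  classes are composition-based heuristics, not identifications.
* The double-assignment ladder discards genuinely ambiguous peaks;
  at 0.5 ppm this loses a few percent of heavy (> 500 Da) compositions,
  which is the physically honest behaviour.
* The all-replicates presence rule is conservative: one dropped
  replicate hides a formula from a condition. The `any_replicate`
  switch quantifies the sensitivity of conclusions to this rule.
* No attribution of individual formulas to lysed taxa, and no global
  flux extrapolation, is attempted.

## A complete run

```{r workflow}
library(vdomics)

cfg <- sim_config(seed = 1)
truth <- generate_formula_library(cfg)
sim <- simulate_experiment(truth)

out <- run_vdom_pipeline(sim$spectra, sim$meta)
report <- vdom_analysis(out$table, depth = "subsurface")
report
evaluate_vdom_recovery(report, truth)

ord <- pcoa(bray_curtis_matrix(hellinger(out$table)), k = 2)
env <- generate_env_table(sim$meta, seed = 2)
fit_env_vectors(ord, env[rownames(ord$scores), ], n_perm = 999, seed = 3)
```
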