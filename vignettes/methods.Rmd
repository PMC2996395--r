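---
title: "Merging tissue MR spectroscopy and microarrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging tissue MR spectroscopy and microarrays: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrsomics)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where a published description leaves the design open. It
states no empirical result that the test suite does not itself compute.

## The measurement design

HR MAS ¹H MR spectroscopy records a metabolite spectrum from an intact
tissue biopsy (~10–30 mg) and leaves the tissue usable for RNA extraction,
so a two-color expression microarray can be run on the *same* sample. Two
spectrum types play different roles: spin-echo (CPMG) spectra suppress
broad macromolecule signals and serve as high-dimensional metabolic
profiles for clustering; single-pulse spectra retain absolute intensity
information and are used for quantification against the TSP reference
(trimethylsilyl tetradeuteropropionic acid, 9 equivalent protons, a known
amount in the rotor buffer).

## Array preprocessing

The raw input is a probe-level table of red/green foreground signals and
background surface values. The pipeline is:

1. **Background subtraction** per channel; corrected values ≤ 0 are
   replaced by half the smallest positive corrected value on that array and
   channel. *Why:* published descriptions are silent on negatives; this
   floor keeps `log2` defined without discarding probes, a common two-color
   convention.
2. **Within-array loess** of M = log2(R/G) on A = ½log2(RG), degree 1,
   robust (`family = "symmetric"`), span 0.3 (configurable). The fitted
   trend is interpolated onto all probes and held constant beyond the
   fitted A range.
3. **Green-channel quantile normalization between arrays**: each array's
   green log-intensities are mapped onto the mean of the sorted green
   vectors; the red channel receives the identical additive log-scale
   correction, so within-array M is preserved exactly (an invariant the
   tests assert to machine precision). This is the natural reading of
   "adjusts the red channel accordingly" when the green channel is a common
   reference RNA.
4. **Local least squares imputation**: each missing entry is predicted by
   regressing its row on the k = 15 most correlated complete rows
   (absolute Pearson over the row's observed columns); pivoted QR tolerates
   collinear neighbors. k is clamped with a warning when fewer complete
   rows exist.
5. **Filtering/collapsing**: control probes out; probes flagged as outliers
   on *more than* 20% of arrays out (strict inequality — a probe flagged on
   exactly 20% stays); duplicate probes averaged; among probes sharing a
   gene symbol the one with the highest IQR across samples represents the
   symbol; unannotated probes are kept under their probe id.
6. **Blacklist removal** (optional): rows whose representative probe id is
   on the HR-MAS-effect blacklist are dropped, with the count reported.

## Intrinsic subtyping

Gene-median-centered expression over the intrinsic genes shared with a
centroid table is Spearman-correlated to each of the five subtype
centroids; a sample takes the argmax label only if the maximum correlation
strictly exceeds 0.1 and is unique, otherwise it is `unclassified`. The
centroids shipped by the generator are synthetic stand-ins; real centroid
tables are user input. Note the documented fragility: median centering on a
cohort dominated by one subtype subtracts that subtype's own profile, so
classification accuracy claims are only meaningful on reasonably balanced
cohorts — the recovery test uses a balanced mixture for exactly this
reason.

## Spectral subgrouping

Profile spectra are restricted to 1.45–4.80 ppm with two lipid windows
deleted ([1.95, 2.15] and [2.73, 2.87] ppm — the published description
names only the centers 2.05 and 2.8; the widths cover typical –CH₂–
multiplets and are configurable), then mean-normalized per spectrum
(each row divided by its own mean; the per-spectrum reading of "mean
normalization" is adopted — it is the variant that removes sample-amount
differences). Dissimilarity is 1 − Spearman ρ between spectra (average
ranks on ties), clustered with complete linkage. The cut height is a
required argument; `hcluster_cut()` also returns the cluster count over a
full height sweep so the choice is inspectable rather than hidden.
Point-wise Welch t-tests (pooled-variance optional) compare each subgroup
pair at every ppm point, flagged at p < 0.001 **without** multiplicity
correction — deliberately exploratory, matching field practice for these
spectral difference displays; the direction of each flagged point is the
sign of the mean difference.

## Moderated tests and gene-set analysis

The differential-expression layer is written from first principles. For a
two-group or paired (one-sample-on-differences) design, gene-wise residual
variances are shrunk through a scaled inverse-chi-square prior:
s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ), with (d₀, s₀²) estimated by matching the
digamma/trigamma moments of log s²ᵍ (with a Newton inverse-trigamma). The
moderated t has d₀ + dᵍ degrees of freedom; d₀ = 0 recovers the ordinary
t-test and d₀ = ∞ a pooled-variance z — both exposed via `prior_df` and
asserted in tests, alongside agreement with an independent implementation
to ~1e-10.

Gene sets are scored with the signed maxmean statistic (the larger of the
mean positive part and mean negative part of the member scores), and the
null is built from sample-label permutations with *restandardization*: per
permutation, set statistics are centered and scaled by the mean and sd of
maxmean over random gene sets of the same size, which protects against
genome-wide shifts. p = (1 + #{|perm| ≥ |obs|})/(n_perm + 1) — the floor
avoids zero p-values. Defaults: 10 000 permutations (tests scale down to
1000 where the criterion allows), 50 random sets per size. One pragmatic
choice: the moderation prior (d₀, s₀²) is estimated once from the observed
labels and reused across permutations; re-estimating per permutation
changes the statistic negligibly and triples the cost. Calibration note:
marginal GSA p-values are uniform under the null (verified over independent
replicate datasets), but p-values of many sets tested on one matrix are
mutually dependent (shared samples and permutations), so omnibus
independence-based tests such as KS must be applied across replicates, not
across sets.

## Quantification

`fit_peaks()` fits a sum of area-parameterized Voigt lineshapes (Lorentzian
HWHM γ convolved with Gaussian sd σ, evaluated via Humlíček's w4 rational
approximation to the Faddeeva function, ~1e-4 relative accuracy — ample
against spectral noise) plus a first-degree polynomial baseline inside each
window. The fit is *separable*: areas and baseline are solved linearly for
any candidate shape parameters, and only centers (± 0.005–0.01 ppm) and log
widths are optimized (L-BFGS-B with a bounded Nelder–Mead fallback for
line-search failures). Windows group the catalogued resonances that
overlap: the crowded 3.2–3.3 ppm stretch (choline 3.21, PCho 3.22, GPC
3.23, taurine 3.25, glucose and myo-inositol satellites) is fitted jointly.
Lactate is catalogued as a nuisance resonance only — in tissue spectra
lipid signals overlap it, so it is never quantified. Concentrations follow
c = (A_m/A_TSP)·(9/n_m)·tsp_nmol/mass_mg in µmol/g wet weight.

## Ranked-list enrichment

After an IQR ≥ 0.8 probe filter, each transcript is Spearman-correlated to
a metabolite's concentrations and the list sorted by decreasing ρ (stable
gene-id tie-break). For a term with B members in the list, the mHG score is
the minimum over prefixes n = 1..N−1 of the hypergeometric upper tail
P[X ≥ b(n)]; the optimal prefix takes the smallest n on ties (the tightest
enriched prefix). Because this score is a minimum over dependent tails, it
is not a p-value; the exact p-value P[mHG ≤ s] is computed by a dynamic
program over the (n, b) lattice in its sequential-sampling form (bounded
probability mass, O(N·B), with rejected mass accumulated directly to avoid
catastrophic cancellation at very small p). The enrichment fold is
e = (b/n)/(B/N). FDR is adjusted within each GO category (BP/MF/CC),
mirroring how such results are conventionally grouped; N is the full ranked
list length by default (unannotated genes retained). The tests verify the
DP against exhaustive enumeration of all arrangements at small N and the
property p ≥ mHG.

## The synthetic world

`generate_dataset()` emulates a 46-sample ER-enriched ductal-carcinoma
cohort. Defaults, chosen once and then frozen:

- **Subtype mixture** 36 : 1 : 1 : 1 : 7 (lumA : lumB : basal : ERBB2 :
  normal-like), the composition of the cohort the framework targets.
- **Concentrations**: typical breast-tumor values (glucose 2, lactate 6,
  creatine 2, myo-inositol 3, taurine 5, glycine 2, choline 0.4, PCho 1,
  GPC 1, alanine 1 µmol/g), per-sample log2 sd 0.25.
- **Spectra**: Voigt peaks at literature shifts on a 8000-point 0.5–5.0 ppm
  grid (quantification spectra extend to −0.2 ppm for TSP and scale with
  sample mass), plus 11 broad Gaussian lipid/macromolecule envelope
  components, plus white noise (sd 5 intensity units; large peaks are
  O(10³)).
- **Metabolic subgroups**: three, planted within luminal A. The named
  metabolite offsets follow the expected group phenotypes — subgroup 1
  lipid-rich and myo-inositol-low, subgroup 2 Warburg-like (glucose −1.5,
  alanine +1.5, lactate +1 in log2), subgroup 3 amino-acid-α-H-rich — and
  each subgroup additionally carries a fixed signature on three broad
  envelope bands (1.5–2.4, 2.45–3.3, 3.4–4.4 ppm). The broad-band
  signatures are essential, not cosmetic: the named peaks occupy a tiny
  fraction of the ~5300 retained points, so even doubling them moves a
  spectrum-wide rank correlation by only ~0.02, far too little for a fixed
  dendrogram cut to see; real tissue spectra separate on broad lipid and
  macromolecule structure, and so does the generator.
- **Expression**: intrinsic genes follow per-subtype centroids (noise sd
  0.5 against centroid sd 1); a 50-gene cell-cycle-like set is shifted
  +1 log2 in subgroup 2; a 30-gene block tracks log2 myo-inositol through a
  Gaussian copula with ρ = 0.7; 20 random decoy sets.
- **Raw arrays**: signals rebuilt on the intensity scale with a smooth
  quadratic intensity-dependent dye bias, additive sinusoidal background
  surfaces, 5% duplicate probes, 5% unannotated probes, 50 control probes,
  1% outlier flags, 2% missingness completely at random.
- **Paired study**: 18 pairs, patient effect sd 1 versus within-pair sd
  0.3 (so arrays cluster by patient), 3% affected probes at ±0.5 log2
  (70% down), mirroring the expected direction balance of a
  procedure-induced effect.

What the generator does **not** emulate: chemical-shift drift and
misalignment between samples, baseline roll and phase errors, the many
minor tissue metabolites, probe-sequence-specific effects, spatial array
artifacts beyond a smooth surface, or RNA-quality gradients. A green test
therefore establishes that the algorithms recover what they are designed to
recover under realistic-but-clean conditions; it does not establish
robustness to acquisition artifacts, and cohort-level biological findings
(specific GO terms, specific group counts) are expressly out of reach
without the clinical data.

## Numerical choices and degenerate inputs

- Negative corrected intensities: floored at half the per-array/channel
  minimum positive value (keeps logs finite).
- Spearman ties: average ranks throughout.
- Exact correlation ties in subtyping and exact HGT ties in mHG break
  toward `unclassified` and the smallest prefix respectively.
- `mhg_pvalue` guards float noise by comparing tails at s·(1 + 1e-9) and
  floors the result at the smallest positive double.
- Constant spectra (undefined ranks), all-missing rows, non-positive row
  means, unpaired samples and empty filter results raise errors naming the
  offending sample/row rather than propagating NaN.
- Cluster ids are renumbered by decreasing size (ties by first member) so
  labels are stable under sample permutation.
- All simulation entry points take an integer seed and restore the caller's
  RNG state; identical configuration + seed reproduces datasets, reports
  and permutation p-values byte-identically.

## Known limitations

- The Humlíček approximation limits lineshape accuracy to ~1e-4; fits of
  peaks narrower than ~3 grid points are unreliable (the fitter requires a
  minimum of points per peak).
- The GSA layer supports two-group and paired designs only — no covariates.
- The mHG dynamic program is O(N·B); for very large gene universes with
  thousands of members per term a permutation fallback would be preferable;
  at the package's intended scale (N ≈ 10⁴, B ≤ 10³) it runs in well under
  a second per term.
- Quantification assumes the catalogued resonances are the dominant signals
  in each fit window; heavily lipid-contaminated windows (the reason
  lactate is excluded) would need user-supplied windows.
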