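# mrsomics

Joint analysis of HR MAS ¹H MR spectra and two-color gene-expression
microarrays measured on the *same* tumor tissue samples.

High-resolution magic angle spinning (HR MAS) MR spectroscopy profiles the
metabolome of an intact tissue biopsy and leaves it usable for RNA
extraction, so the transcriptional and metabolic state of one sample can be
read together. This package implements a complete desk-scale framework for
that design, built around two complementary strategies:

1. **Metabolic subtyping within a transcriptional subtype.** Arrays are
   preprocessed (background subtraction, within-array loess, green-channel
   quantile normalization between arrays, LLS imputation, probe filtering
   and collapsing), samples are assigned an intrinsic molecular subtype by
   Spearman correlation to published centroids (label = argmax ρ if
   ρ > 0.1, else unclassified), and the CPMG spectra of the dominant
   subtype (region 1.45–4.80 ppm, lipid windows near 2.05/2.8 ppm deleted,
   mean-normalized) are clustered with complete linkage on the Spearman
   dissimilarity d(i,j) = 1 − ρ(xᵢ, xⱼ), cut at a fixed dendrogram height.
   Subgroups are compared point-by-point in the spectra (Welch t, flagged at
   p < 0.001) and gene-set-wise with a permutation GSA using the maxmean
   statistic with restandardization, on empirical-Bayes moderated t-scores
   t̃ᵍ = β̂ᵍ / (s̃ᵍ √vᵍ), where s̃ᵍ² = (d₀s₀² + dᵍsᵍ²)/(d₀ + dᵍ) and
   (d₀, s₀²) are moment-matched from the distribution of log sᵍ².
2. **Metabolite-transcript correlation with ranked-list enrichment.** Eight
   metabolites (myo-inositol, taurine, choline, GPC, PCho, glucose,
   creatine, glycine) are quantified absolutely from single-pulse spectra by
   Voigt-lineshape peak fitting and TSP referencing,
   c = (A_m/A_TSP)·(9/n_m)·tsp_nmol/mass_mg (µmol/g). Every transcript with
   IQR ≥ 0.8 is ranked by Spearman correlation to each metabolite, and GO
   terms enriched toward the top of each list are found with the minimal
   hypergeometric (mHG) statistic — the minimum over all prefixes n of the
   hypergeometric tail P[X ≥ b(n)] — with an exact lattice dynamic program
   for its p-value and the enrichment fold e = (b/n)/(B/N).

A third, supporting analysis quantifies the effect of the HR MAS procedure
itself on the transcriptome from paired (spun vs. control) samples: paired
moderated t-tests at FDR < 0.01 produce a probe blacklist that the
preprocessing of the main study removes.

A seeded synthetic-data generator (`generate_dataset()`,
`generate_paired_hrmas_study()`) builds complete cohorts — spectra with
planted metabolic subgroups, raw probe-level two-color arrays with dye bias
and background, centroids, gene sets, truth labels — so every stage is
testable without patient data.

## Worked example

```r
library(mrsomics)

ds    <- generate_dataset(synth_config(seed = 42))
expr  <- prep_arrays(ds$raw_arrays)
calls <- classify_subtypes(median_center_genes(expr), ds$centroids)
table(calls$label)
#>  basal  erbb2   lumA   lumB normal
#>      3      3     30      1      9

luma <- calls$sample_id[calls$label == "lumA"]
keep <- intersect(luma, ds$metadata$sample_id[ds$metadata$tumor_pct > 5])
spec <- mean_normalize(extract_region(
          new_spectral_matrix(ds$spectra$ppm, ds$spectra$intensity[keep, ])))
hcluster_cut(spearman_dissimilarity(spec), cut_height = 0.39)
#> <cluster_result> 21 samples in 3 subgroup(s) at height 0.390
#> subgroup
#> 1 2 3
#> 7 7 7

quantify_spectrum(ds$quant_spectra[[keep[1]]])[, c("metabolite", "concentration")]
#>   metabolite  concentration
#> 1 choline             0.483
#> 2 pcho                0.894
#> 3 gpc                 1.12
#> ...                     (µmol/g wet tissue)

conc <- setNames(ds$metabolite_truth$myoinositol, ds$metabolite_truth$sample_id)
rl   <- rank_by_metabolite(iqr_filter(expr[, keep], 0.5), conc,
                           metabolite = "myoinositol")
enrichment_table(enrich_ranked_list(rl, ds$gene_sets, fdr = 0.003))
#>   category term                p_value enrichment tuple
#> 1 BP       linked_myoinositol 1.3e-52      59.7   (1923,27,31,26)
#> 2 BP       cell_cycle_like    9.2e- 9       2.07  (1923,49,776,41)
```

The cohort is mostly luminal A; its spectra split into three metabolic
subgroups at the 0.39 cut (here matching the planted groups exactly). The
quantified concentrations recover the generator's truth within a few
percent. In the ranked-list enrichment the transcript block planted to track
myo-inositol tops the list with a huge fold (26 of its 27 measurable genes
in the top-31 prefix); the cell-cycle-like set also appears because the
subgroup that carries it differs metabolically — the same kind of indirect
coupling that makes this analysis interesting on real tumors.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the worked-example enrichment folds: it loads the bundled table
of published (N, B, n, b) tuples (`gorilla_worked_examples()`), recomputes
e = (b/n)/(B/N) for eight reference GO terms with `enrichment_fold()`, and
writes them as JSON at each row's printed precision.
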