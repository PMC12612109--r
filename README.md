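# cfchrom

Open-chromatin-guided analysis of cell-free DNA (cfDNA) fragmentomes.

Plasma cfDNA consists largely of nucleosome-protected fragments released
by dying cells, and its genomic placement preserves the chromatin
accessibility of the cells of origin: nucleosome-sized fragments
accumulate at open chromatin (ATAC-seq peaks), with phased nucleosomes
around peak centers, a sharp chromatosome length mode near 167 bp, a
10–11 bp periodicity in sub-nucleosomal (80–140 bp) fragments, and a CCNN
bias at 5′ fragment ends. In cancer patients a small tumor-derived
fraction (typically 1–3%) shifts cfDNA occupancy at tumor- and
immune-cell-specific open chromatin. `cfchrom` is for computational
biologists who want to exploit that structure: it implements fragment
I/O, fragmentomic statistics, differential nucleosome occupancy at
extended ATAC-seq peaks, genomic annotation, and an interpretable
gradient-boosted classification protocol, together with a cohort
simulator that provides ground truth for validating every stage.

## Core statistics

* **Counting**: fragments are assigned to regions by midpoint
  (`floor((start+end)/2)`), so counts over non-overlapping regions
  partition each library.
* **Normalization**: trimmed mean of M-values (TMM). For sample *s*
  against reference *r*, over regions with positive counts in both,
  `M = log2((y_s/N_s)/(y_r/N_r))`, `A = ½·log2((y_s/N_s)(y_r/N_r))`;
  after 30%/5% two-sided trims on M/A the factor is
  `2^(Σ w M / Σ w)` with delta-method binomial weights, rescaled to
  geometric mean 1.
* **Testing**: conditional negative-binomial exact test. With counts
  scaled to a common effective library, the group-A sum given the total
  follows the convolution of NB laws with shared mean and dispersion φ;
  the two-sided p doubles the smaller tail (ties included). φ = 0
  reduces to an exact binomial split test. Direction calls use p < α (or
  BH-adjusted FDR < α) with strict sign inequalities.
* **Ordination**: leading-logFC MDS — per sample pair, the RMS of the
  top-k largest |Δ logCPM|, then classical (Torgerson) scaling.
* **Classification**: XGBoost (binary:logistic, depth 6, 100 rounds,
  `tree_method = "hist"`, AUC-PR early stopping with patience 15) on
  mean depth-normalized coverage over 10 kb regions, with a stratified
  70/30 split, a grid over learning rate 0.05–0.65 / λ 1–10 /
  positive-class weight 0.8–1, selection by balanced accuracy, matched
  non-overlapping random background controls, and gain-based feature
  importances mapped back to genomic loci.

## Worked example

Simulate the default validation cohort (6 healthy vs 6 breast-cancer-like
samples, 2×10⁵ fragments each, tumor fraction 1–3%) and run the
fragmentomics and differential stages:

```r
library(cfchrom)

cohort <- simulate_cohort(sim_config(seed = 1))
pooled <- data.table::rbindlist(cohort$samples)

length_distribution(pooled)
#> length_distribution: 2400000 fragments, lengths 80 - 527 bp, mode 167 bp

per <- subnucleosomal_period(length_distribution(pooled))
sprintf("periodicity: %.1f bp (confidence %.2f)", per$period, per$confidence)
#> "periodicity: 10.4 bp (confidence 0.98)"

end_motif_frequencies(pooled[1:200000], cohort$sequence)
#> motif_profile: 200000 fragment 5' ends, 4 bp k-mers; CCNN=0.1508
```

The pooled length histogram peaks at the 167 bp chromatosome mode; the
sub-nucleosomal periodicity estimate (10.4 bp) recovers the configured
comb; and the CCNN 5′-end frequency (0.151) sits far above the 1/16
expected on unbiased uniform sequence, reflecting the simulated
nuclease-cleavage bias.

Differential occupancy at 1 kb-extended immune-catalog peaks:

```r
labels  <- setNames(cohort$truth$samples$label, cohort$truth$samples$sample)
regions <- extend_intervals(cohort$truth$catalogs$immune, 1000)
cm   <- count_fragments_in_regions(cohort$samples, regions)
f    <- tmm_factors(cm)
phi  <- estimate_common_dispersion(cm, labels, f)
res  <- nb_exact_test(cm, labels, "cancer", f, phi)
calls <- call_differential(res, alpha = 0.05)
#> 65 increased, 65 decreased of 1000 regions (p < 0.05)
```

All 100 planted differential regions (50 increased, 50 decreased at
2-fold) are recovered with the correct direction; the remaining calls
fall at the nominal false-positive rate among the 900 unplanted regions.

For classification, `sim_config_classification()` generates a 30 vs 30
cohort on a sparse toy genome; `model_comparison()` then trains the
whole-genome, tumor-catalog, immune-catalog and combined feature spaces
plus a matched random-background control, and `feature_importance()`
maps the top gain features back to the planted loci.

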