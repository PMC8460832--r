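# swathpipe

Post-quantification analysis of SWATH/DIA proteomic abundance matrices from
tumor-tissue cohorts, built for the question of separating aggressive (AG,
Gleason ≥ 7) from non-aggressive (NAG, Gleason 6) primary prostate cancer
alongside benign controls (C) and castration-naive/resistant metastases
(Nmet/M). The package takes a proteins × runs intensity matrix — the output
of any DIA quantification tool — and runs the downstream statistics;
everything upstream (acquisition, library search, protein inference) is out
of scope.

It is aimed at proteomics analysts who want these steps as tested,
composable functions rather than a notebook: reference normalization,
replicate-based reliability filtering, clustering/PCA, differential
expression, permutation rank-stability selection, and protease-activity
inference from substrate peptide ratios. A synthetic-cohort generator with
a ground-truth record makes every stage testable as a parameter-recovery
problem.

## The statistics at the core

* **Reference normalization.** Each run *s* is scaled by *c_s* so that the
  median over shared proteins of *c_s·x_ps / x_p,ref* equals 1 (every
  sample is assumed to have median relative expression 1 against the
  reference run, default `AG1`); working values are
  log2(*c_s·x_ps / x_p,ref*).
* **CV reliability filter.** A protein is kept iff its biological CV
  (SD/|mean| of linear-scale abundances across biological samples) is at
  least the maximum over tissue groups of the technical CV (RMS over a
  group's duplicate-run pairs of the pair CV). Variation across patients
  must not be smaller than measurement noise.
* **Differential expression.** Per-protein two-sided pooled-variance
  Student's *t* on log2 values, in two regimes: pooled tumors vs control
  (BH-adjusted p < 0.01 and fold change ≥ 2 or ≤ 1/2) and AG vs NAG
  (raw p < 0.05 and fold change ≥ 1.5 or ≤ 1/1.5).
* **Permutation rank-stability.** Proteins are ranked by AG-vs-NAG p-value
  (rank 1 = smallest); group labels are shuffled B = 500 times with sizes
  preserved and ranks recomputed. A protein is *stable* when its observed
  rank beats the 5th percentile of its own permuted rank distribution.
* **Structure.** Top-500-variance proteins, per-protein Z-scores, Ward
  linkage on Euclidean distances (`ward.D2`) on both axes with a 4-cluster
  cut, and sample PCA via the SVD of the centered matrix.
* **Protease activity.** Per sample, the DPP4 activity readout is the
  cleaved/intact neuropeptide-Y peptide ratio
  (`SKPDNPGEDAPAEDMAR` / `YPSKPDNPGEDAPAEDMAR`), correlated with enzyme
  abundance (Pearson, on log scale) and contrasted between groups, with
  the shared C-terminal peptide `HYINLITRQR` as a total-substrate readout.

The methods vignette (`vignettes/swathpipe-methods.Rmd`) documents the
models, every tunable parameter with units and defaults, the numerical
conventions, and what the synthetic generator does and does not emulate.

## Worked example

```r
library(swathpipe)

cfg <- sim_config(n_proteins = 1000, seed = 42)   # discovery design
cohort <- simulate_cohort(cfg)
dim(cohort$abundance)
#> [1] 1000   97          # 49 biological samples + 48 duplicate runs

norm <- normalize_to_reference(cohort$abundance, reference = "AG1")
replicate_correlation(norm, cohort$metadata)$mean_correlation
#> [1] 0.9444433          # mean Pearson r across the 48 replicate pairs

rec <- cv_filter(norm, cohort$metadata)
table(rec$retained)
#> FALSE  TRUE
#>    67   933             # biological CV >= max technical CV keeps 933/1000

samples <- average_replicates(norm, cohort$metadata)
filt <- apply_cv_filter(samples, rec)
de <- differential_expression(filt, cohort$metadata, "ag_vs_nag")
subset(de, call == "down" & protein_id %in% cohort$truth$protease_panel,
       c(protein_id, fold_change, p_value, call))
#>       protein_id fold_change      p_value call
#> DPP4        DPP4   0.3450733 4.134062e-04 down
#> KLK3        KLK3   0.3894349 1.629427e-04 down
#> CMA1        CMA1   0.4021701 4.044106e-04 down
#> ITGB1      ITGB1   0.3131262 1.098127e-05 down
#> ANPEP      ANPEP   0.2481553 2.869994e-06 down
```

The planted protease panel (shifted −1.5 log2 in AG) is recovered as
down-regulated with ~0.25–0.4-fold changes. The permutation test confirms
the calls are rank-stable:

```r
st <- permutation_stability(filt, cohort$metadata, n_permutations = 500,
                            seed = 7)
subset(st$results, protein_id == "DPP4")
#>   protein_id   observed_p observed_rank mean_permuted_rank rank_threshold stable
#> 1       DPP4 0.0004134062             6            472.336             44   TRUE
```

DPP4 ranks 6th of 933 observed, against a mean permuted rank of 472 — far
below its 5th-percentile threshold of 44, hence stable. On the combined
106-sample design, the activity module recovers the planted
enzyme–substrate linkage:

```r
cfg106 <- sim_config(group_sizes = cohort_design("combined"),
                     cohort = "combined", n_proteins = 1000, seed = 42)
cohort <- simulate_cohort(cfg106)
samples <- average_replicates(normalize_to_reference(cohort$abundance, "AG1"),
                              cohort$metadata)
pep <- simulate_peptides(cfg106, cohort$metadata, cohort$truth)
act <- compute_ratios(pep, npy_dpp4_assay(), cohort$metadata)
correlate_with_enzyme(act, samples, "DPP4")
#> $pearson_r: 0.503  $p_value: 4.42e-08  $n_samples: 105

cmp <- compare_ratio_groups(act, "AG", "NAG")
round(unlist(cmp$ratio), 4)
#> mean_log2_a mean_log2_b  difference t_statistic     p_value   n_a   n_b
#>     -1.1306      0.8124     -1.9430     -2.9849      0.0045    19    29
```

DPP4 abundance correlates positively with the cleaved/intact ratio
(r = 0.50 here, planted population value 0.45), and AG tumors show the
lower ratio (difference −1.9 log2 units, p = 0.0045) — reduced protease
activity in the aggressive subtype, exactly as planted.

`run_pipeline(pipeline_config(...), out_dir)` chains all stages and writes
per-stage TSV/JSON plus a provenance manifest;
`inst/scripts/swathpipe-run.R` exposes the same from the shell.

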