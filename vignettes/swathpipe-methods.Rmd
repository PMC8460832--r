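---
title: "Methods behind swathpipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind swathpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathpipe)
```

# Scope

`swathpipe` implements the post-quantification half of a SWATH/DIA tissue
proteomics study of prostate-cancer subtypes: everything that happens after
a proteins x runs intensity matrix exists. Spectral acquisition, library
search and protein inference are upstream of the package and out of scope.
The pipeline stages are reference normalization, CV-based reliability
filtering, structure analysis (clustering and PCA), two-regime differential
expression, permutation rank-stability selection, and protease-activity
inference from substrate peptide ratios. Because the underlying raw maps of
such studies are rarely public, the package also contains a first-class
synthetic-cohort generator whose ground-truth record turns every stage test
into a parameter-recovery problem.

# The abundance model and the synthetic generator

The generator assumes protein intensities are log-normal. For protein $p$
in biological sample $s$ of tissue group $g(s)$:

$$\log_2 X_{ps} = \mu_p + \delta_{p,g(s)} + b_{ps}, \qquad
  \mu_p \sim N(m_0, s_0^2), \quad b_{ps} \sim N(0, \sigma_b^2)$$

and a technical replicate run $r$ of sample $s$ observes
$\log_2 X_{psr} = \log_2 X_{ps} + e_{psr}$ with
$e_{psr} \sim N(0, \sigma_t^2)$ — duplicate runs resample *only* technical
noise, which is what makes the biological-vs-technical CV comparison
meaningful. Group effects $\delta$ are the planted truth: a configurable
protease panel (by default DPP4, KLK3, CMA1, CPE, ITGB1, ANPEP) shifted by
$-1.5$ log2 units in the aggressive (AG) and metastatic (Nmet, M) groups,
plus arbitrary user-planted effects.

Default parameters, chosen once as field-realistic values:

| parameter | default | unit | rationale |
|---|---|---|---|
| `group_sizes` | 10 C / 10 NAG / 9 AG / 10 Nmet / 10 M | samples | the discovery cohort design; `cohort_design("combined")` gives the full 106-sample study |
| `n_proteins` | 4415 | proteins | the scale of a SWATH tissue map |
| `n_replicated_samples` | 48 | samples | duplicate-run count of the study |
| `baseline_log2_mean`, `baseline_log2_sd` | 20, 2 | log2 intensity | typical dynamic range of protein-level SWATH intensities |
| `biological_log2_sd` | 0.6 | log2 | between-patient variation of a typical protein (~50% linear CV) |
| `technical_cv` | 0.15 | linear CV | replicate-run reproducibility of a well-behaved DIA workflow |
| `protease_log2_shift` | -1.5 | log2 | a strong (~3x) loss, the magnitude the panel displays |
| `miss_intercept`, `miss_slope` | 7, -0.5 | logit | ~5% missing at mean abundance, rising steeply for faint proteins |

Missingness is abundance-dependent:
$P(\text{missing}) = \mathrm{logit}^{-1}(a + c \cdot \log_2 x)$ with
$c \le 0$ enforced, so missingness is monotone non-increasing in abundance.
This emulates the *pattern* of partial quantification in DIA tissue data
(most proteins quantified in most but not all runs) without claiming its
mechanism. Missing entries are `NA`, never 0; zeros are treated as measured
values throughout the package, because CV and ratio computations must
distinguish "absent" from "zero".

## The substrate-peptide linkage

For each sample the generator emits three neuropeptide-Y surrogate
peptides: intact NPY(1-36) (`YPSKPDNPGEDAPAEDMAR`), DPP4-cleaved NPY(3-36)
(`SKPDNPGEDAPAEDMAR`) and the shared C-terminal peptide (`HYINLITRQR`)
tracking total substrate. The cleaved/intact log-ratio is linked linearly
to the sample's true DPP4 level:

$$\log_2 \frac{\text{cleaved}_s}{\text{intact}_s}
   = \beta\,(D_s - \bar D) + \varepsilon_s,
  \qquad \varepsilon_s \sim N(0, \sigma_r^2)$$

With $\beta = 1$, the population correlation between $D$ and the log-ratio
is $\rho = \sigma_D / \sqrt{\sigma_D^2 + \sigma_r^2}$. Under the combined
106-sample design, $D$ has variance
$\sigma_b^2 + \Delta^2 q(1-q) = 0.6^2 + 1.5^2 \cdot \tfrac{67}{106}\cdot\tfrac{39}{106}
\approx 0.883$ (the 67 AG/Nmet/M samples carry the $-1.5$ shift), i.e.
$\sigma_D \approx 0.94$. Solving $\rho = 0.45$ gives
$\sigma_r = \sigma_D\sqrt{1/\rho^2 - 1} \approx 1.87$, the default
`dpp4_ratio_noise`. This places the planted enzyme-substrate association at
the strength the assay is expected to show, and it is the one generator
parameter calibrated to an association strength rather than to a noise
magnitude. Total NPY is shifted $+1$ log2 in AG (`npy_ag_log2_shift`),
emulating substrate accumulation where the protease is lost.

# Normalization

Every run $s$ is rescaled by a factor $c_s$ such that the median, over
proteins quantified in both $s$ and the reference run, of
$c_s x_{ps} / x_{p,\mathrm{ref}}$ is exactly 1 — each run is assumed to
have a median relative expression of 1 against the reference. The working
values are $\log_2(c_s x_{ps}/x_{p,\mathrm{ref}})$. Consequences worth
knowing:

* the reference run's own column is identically 0 (its median is 0
  *exactly*, not within tolerance);
* rescaling any raw column by a positive constant does not change the
  output (scale invariance), and renormalizing an already-normalized matrix
  yields factors of 1 (idempotence);
* proteins not quantified in the reference run have no ratio and stay
  missing everywhere. Downstream stages treat them as non-computable. The
  pipeline's activity stage therefore falls back to raw log2 abundance for
  the enzyme if the enzyme itself is unquantified in the reference run —
  rare, but possible under abundance-dependent missingness;
* a zero intensity has no finite log-ratio and becomes missing in the
  output (it still participates in nothing else; it is not imputed).

The reference defaults to run `AG1`, and is configurable.

# The CV reliability filter

Per protein, the biological CV is $\mathrm{SD}/|\mathrm{mean}|$ of the
replicate-averaged, linear-scale normalized abundances across biological
samples. The technical CV is computed per tissue group as the
root-mean-square over the group's replicate pairs of the pair-level CV
(for a pair, $\mathrm{SD}/\mathrm{mean} = |a-b|/(\sqrt 2 \cdot (a+b)/2)$),
and the maximum over groups is used. A protein is retained iff
biological CV $\ge$ max technical CV — the `>=` is deliberate, so a protein
that is exactly constant everywhere (both CVs 0) is retained.

Two conventions here are genuinely open and are exposed as switches:

* **`cv_scale`** — the CV could be computed on log2 ratios directly, but
  log2 ratios are centered near 0, making $\mathrm{SD}/|\mathrm{mean}|$
  numerically unstable; the linear scale is the standard definition of a
  CV and is the default. Both are implemented (`"linear"`, `"log2"`).
* **`tech_aggregate`** — pooling a group's pair CVs by RMS pools their
  variances; a plain mean is offered (`"mean"`).

Proteins quantified in fewer than 3 biological samples cannot yield a
meaningful biological CV and are dropped as non-computable (conservative).
Proteins never observed in a complete replicate pair have no technical CV
and are retained — there is no evidence against them.

# Differential expression

Per protein, a two-sided two-sample Student's t-test with pooled variance
on log2 values (Welch available via `var_equal = FALSE`). Proteins with
fewer than two present values in either group are flagged untested and
excluded from the multiple-testing correction, so $m$ is the tested count.
Two threshold regimes mirror the two contrasts:

* **tumor_vs_control** (pooled NAG+AG+Nmet+M versus C): significant iff
  BH-adjusted p < 0.01 and fold change $\ge 2$ (up) or $\le 1/2$ (down);
* **subtype** (AG versus NAG, small groups): significant iff raw p < 0.05
  and fold change $\ge 1.5$ or $\le 1/1.5$.

Fold change is derived from the difference of group mean log2 values
(a geometric-mean ratio), the natural convention when the analysis matrix
is log2; "absolute fold change $\ge$ 2" is read symmetrically as
$|\log_2 \mathrm{FC}| \ge 1$. Fold-change cuts are inclusive, p-value cuts
strict. Degenerate zero-variance proteins give t = 0, p = 1 when the means
agree, and are infinitely significant otherwise. BH adjustment wraps the
standard step-up procedure; the test suite cross-checks it against an
independent brute-force implementation.

# Permutation rank-stability

The stability test asks whether a protein's differential rank survives
destroying the group structure. Observed AG-vs-NAG p-values are ranked
(rank 1 = smallest, average ranks on ties). For each of B = 500 iterations
the group labels are shuffled uniformly over the combined samples with
group sizes preserved — the standard construction of the permutation null,
which is how "random sampling" of group assignments is implemented here —
and ranks are recomputed. A protein is **stable** when its observed rank
lies strictly below the 5th percentile (configurable) of its own permuted
rank distribution. The percentile is a decision the underlying plot leaves
open; 5 is the package default.

Within each iteration, proteins that become untestable under the shuffle
are assigned the average of the remaining worst ranks, so every iteration's
ranks sum to $m(m+1)/2$ exactly — an invariant the tests assert. A
leave-one-sample-out jackknife of the observed ranking is available
(`jackknife = TRUE`) as the resampling diagnostic for the unpermuted
average-rank curve; the default curve uses the single observed ranking,
and both are labeled in the output.

A statistical note: under the null, each protein's mean permuted rank has
expectation $(m+1)/2$ with iid-theory standard error
$\sqrt{(m^2-1)/(12B)}$, but *conditionally on a fixed dataset* the mean
permuted rank also carries a data-driven component (a protein with an
outlying sample is systematically harder or easier to separate under any
labeling), inflating the spread beyond the iid value by roughly 8% in our
simulations. Simultaneous per-protein bounds at 3 SE over hundreds of
proteins should therefore be expected to show occasional exceedances even
for a correct implementation; the across-protein *mean* of mean permuted
ranks equals $(m+1)/2$ exactly by rank-sum conservation.

# Structure analysis

The top 500 proteins by sample variance (n - 1 denominator, ties broken by
protein id) are Z-scored per protein (missing values excluded from the
statistics and left missing), then clustered with Ward linkage on Euclidean
distances — `hclust(method = "ward.D2")`, the Ward criterion on a Euclidean
distance matrix, matching the seaborn/scipy `ward`/`euclidean` combination —
on both axes, and cut into 4 flat protein clusters by default. Ward
requires complete vectors, so missing Z-values are imputed as 0 (the row
mean) *for the distance computation only*; the imputation never leaks back
into the data. PCA treats samples as observations via the SVD of the
column-centered sample-by-protein matrix; explained variances are
non-increasing and sum to the total variance, and reconstruction from all
components returns the centered matrix — both asserted in the tests.

# Protease activity

Per biological sample, replicate runs are averaged on the linear scale
*before* the ratio (ratio of means — more stable at low intensities than
the mean of ratios, which is offered as `average = "after"`), and the
activity readout is cleaved/intact. The ratio is undefined — not zero —
when the intact peptide is missing or zero; `log2_ratio` additionally
requires both intensities positive. Undefined ratios are excluded, never
imputed, and exclusion counts are reported. The enzyme association is the
Pearson correlation between enzyme log2 abundance and the log2 ratio
(linear-scale option available), with a t-transform p-value; group
contrasts of the log-ratio and of total substrate (the C-terminal reference
peptide — reported as such; whether "total" means this peptide alone or a
sum over peptides is ambiguous upstream, and the reference peptide is the
cleaner readout) use Student's t. Ratios are scale-invariant to per-sample
rescaling, and the correlation is invariant under positive affine
transforms — both are tested properties.

# Pipeline, configs and the command line

`run_pipeline()` executes normalize → CV filter → structure → differential
→ stability → activity, writing each stage as plain TSV/JSON plus a
manifest (package version, seed, parameters, MD5 of every file). All
randomness derives from the config seed, so reruns are byte-identical —
asserted in the tests. Percentages in `cohort_bookkeeping()` round half
away from zero to one decimal, the usual clinical reporting convention
(base R's `round()` is half-even). Simulation configs serialize to YAML,
assays to JSON; `inst/scripts/swathpipe-run.R` is a thin command-line
wrapper, and the package functions remain the primary interface.

# Problem sizes used by the test suite

The suite exercises the statistical guarantees at sizes chosen to make the
Monte-Carlo bounds meaningful while keeping the default run light: null
calibration on a 5,000-protein zero-effect cohort; permutation uniformity
at m = 500 proteins and B = 500 shuffles; planted-shift recovery over 100
generator seeds at B = 500; the activity closed loop over 200 seeds of the
106-sample design; oracle equivalence on 1,000 random BH vectors and 100
random CV fixtures. These are the package's own verification sizes, not
properties of the method.

# What passing tests do and do not show

The generator draws Gaussian log2 abundances with homoscedastic group
variances, independent proteins, and logistic missingness. Real SWATH
tissue data have heavy-tailed intensity errors, correlated protein modules,
batch structure, and identification-driven (not purely abundance-driven)
missingness. Passing parameter-recovery tests therefore shows the
*algorithms* are correct and calibrated under their stated assumptions —
not that those assumptions hold in any particular tissue cohort. Two
consequences are visible in the synthetic defaults: replicate correlations
come out near 0.94 (in normalized ratio space, where the shared per-protein
baseline is divided out, the pair correlation is governed by biological
ratio variance against technical noise), somewhat above the ~0.89 typical
of real replicate SWATH runs, and the CV filter retains ~93% of synthetic
proteins versus ~88% in the motivating study.
Neither number is a target; both are reported by the acceptance script as
descriptive outputs.

# Known limitations

* No imputation and no batch correction (the upstream analysis performs
  none); proteins unquantified in the reference run are lost to ratio
  space.
* Plain t-tests without variance moderation, by design — the point is to
  reproduce the analysis, not to improve it.
* The permutation test controls no across-protein FDR; stability is a
  per-protein call against its own permutation distribution.
* Enrichment analysis, external mRNA comparison and staining validation of
  the motivating study are out of computational scope.
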