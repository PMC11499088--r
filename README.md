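# morphodetail

Does smoothing away fine anatomical surface detail help or hurt when you
cluster anatomies by shape? `morphodetail` implements a complete,
reproducible pipeline for answering that question on left-atrial-appendage
(LAA)-like surfaces, where the detail in question is trabeculation: the
pectinate-muscle ridge structure that conventional statistical shape
analysis (SSA) pipelines smooth away during reconstruction.

The package is aimed at researchers in morphometrics / biological image
analysis who want to quantify the effect of surface simplification on
point-distribution shape models and on downstream unsupervised shape
categorisation.

## What it computes

Starting from a cohort of watertight triangle meshes with class labels
(a built-in synthetic generator of two-class LAA-like anatomies stands in
for private patient data), the pipeline:

1. **normalises** every mesh to a common volume (6,000 mm³) and rigidly
   **registers** the cohort (moment-based coarse alignment, ICP with 2,000
   samples per iteration and a 10 mm → 0.5 mm rejection schedule, multiview
   refinement until 80% of samples of every pair lie within 0.5 mm);
2. builds **reduced-detail variants**: oriented surface samples thinned by
   a factor R ∈ {2, 4, 8, 16} and re-reconstructed watertight at implicit
   grid depths d = 8, 7, 6, 5 (an algebraic-sphere IMLS field + marching
   tetrahedra);
3. establishes **particle correspondence** (multiscale, K particles from
   K/2^s by splitting) and fits the **PCA point-distribution model**
   x ≈ x̄ + Σᵢ bᵢ √λᵢ vᵢ per variant;
4. evaluates each model by **compactness** C(n) = Σᵢ≤n λᵢ,
   **generalisation** Ĝ(n) (mean leave-one-out reconstruction error, mm)
   and **specificity** Ŝ(n) (mean distance of sampled shapes to their
   nearest training shape, mm);
5. **clusters** the retained PC scores (complete linkage, correlation
   distance, silhouette-selected k) and scores the partition against the
   ground-truth labels with **adjusted mutual information**
   AMI = (MI − E[MI]) / (mean(H(U), H(V)) − E[MI]), with the exact
   hypergeometric E[MI].

The headline comparison is the AMI of the full-detail ("trabeculated")
dataset versus the 4×-reduced ("simplified") one.

## Worked example

```r
library(morphodetail)

cfg <- experiment_config(
  cohort = cohort_spec(n_shapes = 40, master_seed = 1),
  levels = c(1, 2, 4, 8, 16), K = 256, K_init = 128,
  n_m_max = 12, M = 250, register = TRUE, max_rounds = 1, master_seed = 1)
report <- run_experiment(cfg, quiet = TRUE)
print(report)
```

```
experiment: 5 levels, 40 shapes, seed 1 (324.3 s)
 level n_m compactness generalisation_mm specificity_mm detail_energy_mm k silhouette     ami
    R1  12      0.6727            0.5379         0.5848           0.5618 2     0.2346 0.17209
    R2  12      0.7784            0.4070         0.4729           0.3846 2     0.3222 0.11348
    R4  12      0.8089            0.3813         0.4636           0.3251 2     0.3230 0.05322
    R8  12      0.8174            0.3736         0.4582           0.3080 2     0.2912 0.02805
   R16  12      0.8232            0.3697         0.4573           0.3029 2     0.3048 0.11826
headline: AMI R1 = 0.1721 vs R4 = 0.0532
```

Reading the row for each reduction level: `compactness` is the variance
fraction captured by the first `n_m` PCs (rising with reduction - simpler
shapes compress better); `generalisation_mm` and `specificity_mm` are the
two error metrics in mm (both improve, i.e. decrease, with reduction);
`detail_energy_mm` is the RMS fine-detail displacement remaining relative
to each shape's smooth counterpart (the 4× reduction has stripped about
half the detail); `k`, `silhouette` and `ami` describe the clustering of
that level's PC scores. The headline line is the study's comparison: with
class-informative detail present (R1) the clustering agrees better with
the ground-truth labels than after simplification (R4), even though every
classical model-evaluation score prefers the simplified data. Single-seed
AMI values are noisy at 40 shapes; the test suite asserts the effect as a
median over ten cohorts.

Lower-level entry points: `generate_cohort()`, `normalize_volume()`,
`multiview_register()`, `simplify_dataset()`, `establish_correspondence()`,
`fit_pca()`, `evaluation_curves()`, `cluster_and_score()`. A thin CLI
wrapper lives at `inst/cli/morphodetail.R` (`meshinfo`, `experiment`).
The methods vignette (`vignettes/detail-preservation-methods.Rmd`)
documents the model, every tunable parameter and the numerical choices.

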