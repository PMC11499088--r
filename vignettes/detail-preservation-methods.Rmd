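---
title: "Anatomical detail preservation in statistical shape models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical detail preservation in statistical shape models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Statistical shape analysis (SSA) of the left atrial appendage (LAA) usually
starts from smoothed surface reconstructions, discarding the fine
trabecular structure (pectinate-muscle ridges and invaginations) that makes
each appendage individual. `morphodetail` implements a controlled
experiment asking what that smoothing costs: starting from surfaces with
fine detail, it builds progressively simplified dataset variants by
thinning oriented surface samples and re-reconstructing the surface, fits a
point-distribution shape model to each variant, and compares (a) the three
standard model-evaluation metrics and (b) unsupervised shape
categorisation against ground-truth class labels.

Because clinical CT cohorts of trabeculated LAAs are not shareable, the
package ships a synthetic anatomy generator whose cohorts play the role of
the patient data. The generator is first-class, tested code: its study
conditions define the experiment.

## The synthetic anatomy model

A shape is a swept tube. A circular-arc centerline of arc length $L$ (mm)
turns by the bend angle $\phi$ (degrees); the cross-section radius follows
a natural-spline profile $r(u)$, $u \in [0,1]$, multiplied by a spherical
end-taper over the outer 12% of the length at each end, so the surface
closes with two poles: watertight and genus 0 by construction. Gaussian
bumps (secondary lobes) of 1.5-3 mm height and 4.5-7 mm axial width are
added at random positions. On top of this macro shape, a radial
displacement field emulates trabecular detail:

* a *shape-specific noise field*: a band-limited sum of 14 plane waves
  around the dominant frequency `detail_frequency` (default 0.5 cycles/mm,
  i.e. 2 mm ridge spacing, the pectinate-muscle scale), random phase per
  shape;
* a *class template*: a deterministic circumferential ridge pattern
  (integer harmonics $m \in [9, 14]$, wavelength about 3-4.5 mm around the
  tube, slowly varying along the axis) shared by all shapes of a class.

The displacement RMS is `detail_amplitude` (default 0.6 mm), split 70/30
between template and noise. Two design points deserve explanation:

1. **Why a class template at all?** The study needs detail statistics that
   carry class signal. Phase-random roughness differing only in amplitude
   or frequency between classes is almost invisible to linear PCA followed
   by correlation-distance clustering: random-phase components decorrelate
   score profiles rather than separating them. Anatomically, trabecular
   patterns are stereotyped (pectinate muscles run in preferred
   directions), so a shared within-class ridge pattern is a reasonable
   idealisation.
2. **Why circumferential ridges?** Particle correspondence across subjects
   is uncertain by a few millimetres *along* the axis (shapes differ in
   bend and length) but much more stable *around* it. A template that is
   fine circumferentially and smooth axially survives correspondence
   jitter, while reconstruction smoothing at reduced sampling density
   still removes it. A generic fine 2D template is scrambled by
   correspondence jitter and carries no class signal into the model - we
   measured this directly during development.

Real trabeculae are through-holes (genus > 0); the generator models them as
surface displacement to keep every mesh a topological sphere, which keeps
the registration and reconstruction contracts simple. Consequences: the
simplification step removes *geometric texture* rather than topology, and
nothing in the pipeline exercises hole-filling.

Class-conditional distributions (the frozen study conditions): chicken-wing
(CW) shapes have bend $\mathcal{N}(81^\circ, 8^\circ)$ and length
$\mathcal{N}(48, 3)$ mm; non-chicken-wing (NCW) bend
$\mathcal{N}(63^\circ, 8^\circ)$, length $\mathcal{N}(43, 3)$ mm (the
separation is controlled by `macro_overlap`, default 0.75 of the way from
fully separated to identical). CW prevalence is 21/85. With
`detail_class_coupling = 1` (default) CW detail is 25% stronger and 20%
finer than NCW and the two classes have distinct templates; with coupling 0
the classes share one template and identical detail distributions, which is
the control arm of the headline test. The macro overlap is deliberately
large: macro shape alone should separate the classes only partially, as
the fine detail is the signal whose preservation is under study.

## Pipeline stages and their numerical choices

**Volume normalisation.** Every mesh is scaled about its surface centroid
to 6,000 mm^3 before any comparison; scale is thereby removed from the
shape definition.

**Registration.** Coarse alignment uses area-weighted surface moments
(centroid + principal axes, trying the four proper-rotation sign
combinations, keeping the lowest sampled closest-point RMS; near-isotropic
shapes fall back to the identity with a warning). ICP then refines: 2,000
fresh area-uniform samples per iteration, correspondence rejection distance
starting at 10 mm and shrinking geometrically (factor 0.9) to a floor of
0.5 mm, convergence declared when 80% of samples lie within 0.5 mm of the
partner surface; iteration cap 200 with stall detection. Multiview rounds
re-register each shape against the pooled samples of all others until every
unordered pair meets the 80%-within-0.5 mm criterion or the round cap (10)
is reached; unmet pairs are listed in the report and the pipeline proceeds
with a warning. On heterogeneous cohorts the all-pairs criterion is
geometrically unattainable (two shapes bent 60 and 90 degrees simply do not
overlap that tightly), so the warning path is the normal one there; the
criterion is attainable, and tested, on low-dispersion cohorts.

**Simplification.** For reduction factor $R \in \{2, 4, 8, 16\}$: sample
the mesh's own vertex-density point set with outward normals, thin it to
$\lfloor N/R \rfloor$ points by farthest-point (blue-noise) subsampling,
and reconstruct at depth $d = 8, 7, 6, 5$ respectively. The base density
has a floor such that the thinned cloud keeps at least 500 points: the
minimum sampling density grows with the reduction factor, which keeps the
implicit fit well-posed at 16x while leaving the 4x level sparse enough to
remove the trabecular band. $R = 1$ is the untouched original. All outputs
are re-normalised to 6,000 mm^3 (reconstruction shifts enclosed volume
slightly; re-normalising isolates shape from scale).

**Surface reconstruction.** The reconstruction is an implicit
moving-least-squares signed field over the oriented points - an algebraic
sphere fit (APSS) per evaluation point with Gaussian weights - extracted by
narrow-band marching tetrahedra and polished by Newton projection of the
extracted vertices onto the zero set. Numerical constants: grid voxel
$= \max(\text{bbox}/2^d,\ 0.7 g)$ where $g$ is the 98th-percentile
nearest-neighbour gap of the cloud (octree-style density-limited
refinement: the grid is never finer than the samples warrant); Gaussian
support $h = \max(0.85 g,\ 0.8\,\text{voxel})$, widened by up to 1.6x only
if the extracted surface fails the watertightness check. The sphere term
removes the curvature bias a plane fit suffers at the tip and the bend;
averaging positions and normals before taking the plane offset suppresses
the tilt noise that detailed surfaces carry in their normals. The smoothing
scale therefore tracks the sampling gap: halving the density multiplies the
removed-wavelength band by $\sqrt 2$, which is the mechanism that makes
detail loss monotone in $R$.

**Correspondence.** Multiscale particle correspondence: the template shape
(the one whose farthest-point particles propagate to the others with the
smallest mean residual) seeds $K_\text{init}$ particles; every shape
receives them by closest-point projection; then each scale runs 14
relaxation iterations alternating ensemble-mean attraction (weight ramping
0.15 to 0.8, coverage-dominated early, correspondence-dominated late) with
Gaussian inter-particle repulsion (step ramping down), re-projecting to the
surface each iteration; particles split (duplicate + small tangential
offset) and the loop reruns until $K$ is reached. Every particle must lie
within 0.25 mm of its surface (half the paper-scale mesh edge length);
violation is an error, not a warning. This scheme replaces entropy-based
particle optimisation; the package's claims are invariant-based (surface
fidelity, coverage, identical-shape fixed point, rigid equivariance), not
bit-equality with any external tool.

**Shape model.** PCA of the flattened $3K$-vectors: sample covariance
(divisor $n_s - 1$), modes sorted by descending eigenvalue, at most
$n_s - 1$ of them. Mode signs are canonicalised (the largest-magnitude
score on each mode is positive) so results are reproducible across LAPACK
builds and exactly equivariant under rigid motion of the inputs.

**Evaluation metrics.** Compactness: cumulative eigenvalue sum, absolute
(mm^2) or normalised. Generalisation: leave-one-out, refitting the PCA per
fold on the frozen correspondence (particles are not re-optimised per fold;
this matches common practice and keeps LOO tractable, but is an
approximation). Specificity: $M$ seeded draws from the model at $n_m$
modes, each scored by its distance to the nearest training shape.
"Euclidean distance" between shape vectors is reported as the *mean
per-particle* distance in mm (comparable across particle counts); the
total-norm variant is available behind `per_particle = FALSE`. $M$
defaults to 1,000 for standalone calls and 250 in the desk-scale curves.

**Clustering.** The retained mode count is the smallest $n_m$ reaching 85%
cumulative variance on the reference (trabeculated) dataset; comparison
datasets reuse the reference count. Agglomerative clustering uses complete
linkage on correlation distance (1 minus Pearson correlation of score
vectors); the silhouette (same correlation distance; singleton clusters
contribute 0) selects $k$ over 2..10, ties toward smaller $k$. We use the
clustering metric for the silhouette as the internally consistent choice;
the alternative (squared Euclidean, the default of some toolboxes) is a
known source of divergence between implementations. AMI uses natural-log
entropies, the exact hypergeometric permutation-model expected MI (term
sums are sorted so AMI is bit-exactly symmetric), and the arithmetic-mean
normaliser; two single-class partitions score 1 by convention.

## Problem sizes

Desk scale - the default and the scale at which the test suite and the
acceptance script run - is 40 shapes, 0.8 mm mesh resolution, 256
particles from 128, 250 specificity draws; a full five-level experiment
runs in minutes on one CPU. `paper_scale = TRUE` switches to 85 shapes,
0.5 mm meshes and 1,024 particles from 128. Cohort prevalence (21/85), the
6,000 mm^3 normalisation volume, the 2,000-sample/10 mm/0.5 mm/80%
alignment protocol, the reduction-depth pairing and the 85% variance
threshold are identical at both scales.

## What passing tests do and do not show

The synthetic cohorts reproduce the *structure* of the study - two
partially overlapping macro classes whose fine surface detail carries
additional class signal that simplification removes - not the anatomy of
any patient cohort. Passing the directional tests shows the pipeline's
machinery (reconstruction kernel scaling, correspondence coherence, metric
formulas, clustering and its chance-corrected scoring) behaves as the
method claims; it does not show that real trabeculated LAAs carry class
signal of this form or magnitude. Known limitations: genus-0 detail (no
true through-holes), rigid-only registration, frozen-correspondence
leave-one-out, a correspondence scheme that is feature-blind (it matches
space, not anatomy, which is why correspondence jitter sets a floor on the
usable template wavelength), and the headline clustering comparison is
seed-noisy at 40 shapes - the tests therefore assert medians over ten
seeds, not per-seed wins.
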