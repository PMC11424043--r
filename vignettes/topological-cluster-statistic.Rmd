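---
title: "Topological cluster-extent inference: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological cluster-extent inference: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcstat)
```

## The inferential model

Cluster-extent inference tests brain maps at the level of clusters rather
than nodes: a primary cluster-defining threshold (CDT) selects candidate
nodes, connected sets of candidates form clusters, and a cluster's size is
referred to a null distribution of the maximum cluster size, which controls
the family-wise error rate (FWER) over the whole map. Conventionally
"connected" means spatially adjacent. This package generalizes the adjacency
relation: two nodes are *topologically* connected if they are spatial
neighbors **or** linked by a group-level anatomical (white matter)
connection. Activations that are spatially disjoint but anatomically wired
can then pool their extents, which is exactly the regime where spatial
cluster-extent tests are weakest — small foci that co-activate with a larger,
connected system.

The test itself is a one-sample, two-sided sign-flip permutation test.
Its only distributional assumption is symmetry of the per-subject contrast
maps about zero under the null; under that assumption multiplying each
subject's map by an independent ±1 regenerates the null, and the maximum
cluster extent over both signs across permutations yields exact,
distribution-free FWER control at the attainable levels. The identity
permutation is always included, so corrected p-values are bounded below by
`1/n_perm` and the test can never be anti-conservative by construction.

Positive and negative suprathreshold nodes are clustered separately
(clusters never mix signs), and one pooled max-extent null across both signs
corrects the two-sided family. Pooling is slightly stricter than correcting
each sign separately; we chose it because it controls the FWER of the full
two-sided family without any further correction step.

## Topology construction

The anatomical structure is estimated from individual connectomes in five
steps, each with a tunable parameter:

* **Consistency index** `C(i,j)`: the fraction of subjects with a nonzero
  connection. No parameters; invariant to subject order.
* **Distance normalization**: consistency is strongly biased toward short
  connections, so `C` is standardized against its distance trend,
  `C_n = (C − f_μ(ED)) / f_σ(ED)`, fitted separately for intrahemispheric,
  interhemispheric and subcortical connections (an edge touching a
  subcortical node counts as subcortical; the class rule needs a precedence
  order and this one keeps the two cortical classes pure). `f_μ` and `f_σ`
  are natural cubic splines through per-bin means and standard deviations of
  equal-count distance bins (default 100 bins per class). Equal-count bins
  keep per-bin sd estimates equally stable across the distance range, where
  equal-width bins would starve the long-distance tail. Inside the observed
  distance range the spline interpolates; between the outermost bin center
  and the range edge the natural spline continues linearly (a flat clamp
  there leaves a visible bias at short distances, where the trend is
  steepest); outside the observed range evaluation is clamped. `f_σ` is
  floored at `1e-6` so standardization never divides by zero in
  zero-variance bins.
* **Connectome spatial smoothing** `F_s C_n F_sᵀ`: `F_s` is a row-stochastic
  Gaussian kernel over node coordinates (default FWHM 6 mm, truncated where
  the unnormalized weight drops below `1e-6`, i.e. at ≈ 5.3 σ). Smoothing
  raises intersubject reliability of the consensus pattern. The product is
  re-symmetrized, `(M + Mᵀ)/2`, before any thresholding, so downstream steps
  see an exactly symmetric matrix; its diagonal is discarded (self-edges
  carry no clustering information).
* **Density-matched binarization**: the smoothed matrix is thresholded to
  keep the `k` largest weights, where `k` reproduces the *average individual
  connectome density* (nonzero fraction of the off-diagonal upper triangle),
  then binarized into `C_Dist`. Ties at the cut are broken by weight, then
  lexicographic node pair, making the output reproducible run to run. The
  density is the method's main tuning knob: too high and the topology
  degenerates to the spatial rules, too low and everything merges into one
  cluster; matching the individual density is the established middle ground.
* **Union**: `T = C_Dist ∨ S`. The spatial structure `S` is the triangle
  mesh adjacency on surfaces and the 26-neighborhood on voxel grids.

The pipeline order is fixed as smoothing → density thresholding →
binarization, and the smoothed matrix is re-symmetrized before thresholding;
thresholding the asymmetric product first would make the kept edge set
depend on floating-point evaluation order.

## The ribbon phantom

All validation runs on a synthetic phantom, so no imaging data are needed:
an 80×80 grid masked to an annulus (radii 0.55–0.95 of half the grid),
divided into 11 angular sectors — five per hemisphere of 33° each and a 30°
brain-stem sector at the bottom. Three active regions of graded extent carry
a ground-truth signal with peak 1 on a background of 0: a disc of ~97 pixels,
a disc of ~29 pixels at its mirror position in the opposite hemisphere, and a
2×2 block. Hypothetical fibers connect region anchor pixels: association
fibers between angular neighbors, projection fibers from the brain stem, and
homotopic commissural fibers between mirrored regions; one long association
fiber links the small active region to the large one, and the commissural
fiber between the large region and its mirror links it to the medium one.
The active-region sizes were chosen so the contrast of interest is expressed
at the phantom's nominal noise level: the 2×2 block sits below the extent
that pure-noise clusters reach at CDT 2, while the two discs sit above it,
so the small region is only detectable through its anatomical linkage.

Per-subject maps are `effect_scale · truth + noise`, with Gaussian white
noise (sd 2) added to the signal and both smoothed together (σ = 0.5 pixels;
truncated discrete kernel of radius 4σ, renormalized over in-ribbon
neighbors so the annulus border does not leak mass). At these defaults a
single subject's map has a per-pixel effect of d ≈ 0.9 after smoothing, so a
40-subject group t at the active pixels is ≈ 5–6 — comfortably above a CDT
of 2 — while ~4.6% of background pixels exceed the CDT by chance, which is
what makes the extent-based correction non-trivial.

What the phantom does *not* emulate: realistic spatial autocorrelation
structure (real fMRI noise is longer-range and non-stationary), subject-level
variation in effect topography, hemodynamic confounds, and a realistic
connectome (its fibers are a handful of hand-placed edges, not a
tractography-derived matrix). Passing the phantom checks therefore
demonstrates the *inferential machinery* — error control, the
anatomical-merging behavior, exactness of the reductions — not performance
on any particular real dataset.

## Evaluation utilities

* **Sensitivity**: per node, the fraction of repetitions in which it lay in
  a significant cluster of the correct sign; wrong-sign detections count as
  misses. For truth-null nodes the same proportion is a per-node
  false-positive rate and is flagged as such rather than mixed in.
* **Power curves**: nodes sorted by effect size, moving-average windows of
  width 0.05 in d units with 50% overlap, natural cubic spline through the
  windowed means. The curves are descriptive; the smoothing is a fixed
  default, not cross-validated.
* **Bookmaker informedness** `BM = TPR + TNR − 1`: chance-corrected,
  prevalence-free classification score in [−1, 1]. Truth maps (Cohen's d)
  are discretized at a binarization threshold; the default threshold grid
  0.06–0.16 spans the effect detectable at uncorrected α = 0.05 to the
  effect surviving Bonferroni correction over a dense (91,282-node) map at
  N = 1000 — both endpoints recomputed from the noncentral-t machinery in
  `analytic_power_bounds()` rather than hard-coded. The normalized partial
  AUC over that grid (trapezoidal integral divided by the span) summarizes a
  curve into one threshold-independent number; a constant curve at level b
  integrates to exactly b. One degenerate case needs a convention: if the
  discretized truth has no null nodes, TNR is 0/0; we define it as one minus
  the fraction of detections that are sign errors (one when nothing is
  detected), which is the only choice that scores a perfect prediction 1 and
  a total sign inversion −1 under a single rule.
* **Analytic power bounds**: two-sided one-sample t power from the
  noncentral t distribution (df = n − 1, noncentrality d√n), at level α
  (upper bound) and α/n_tests (Bonferroni lower bound). At d = 0 the central
  distribution is used directly so that power equals the test size exactly.
  The minimal detectable effect is the smallest d on a 10⁻⁴ grid whose
  statistic d√n reaches the two-sided critical value.

## Numerical and degenerate-input choices

* Zero-variance nodes have no t statistic; they are marked missing and are
  never suprathreshold.
* Thresholding is inclusive (`≥ CDT`), and the CDT is specified on the z
  scale by default: t statistics are mapped to two-sided z equivalents
  through log-space tail probabilities, which is stable far into the tails;
  the permutation engine equivalently thresholds t at the t-image of the
  CDT (the map is strictly monotone, so the suprathreshold sets are
  identical) and recomputes each permutation's t map in closed form from a
  single matrix product, since squared data are invariant under sign flips.
* Cluster ids are dense and ordered by decreasing extent, then smallest
  member node; permutation sign draws are one row per permutation from a
  single seeded stream, and exhaustive mode (n ≤ 20 subjects) enumerates all
  2ⁿ patterns exactly once with the identity first.
* Kruskal's algorithm for the maximum spanning tree sorts by descending
  weight with ties broken by node pair; on a disconnected cluster graph it
  returns a maximum spanning forest, one tree per component.
* Matrix Market files are written with a symmetric header and 1-based
  indices; general-header files are accepted when (i,j)/(j,i) duplicates
  agree. Node indices are 1-based everywhere.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` validate at sizes a laptop handles
in minutes: FWER control on 200 pure-noise 40-subject samples of the full
80×80 phantom with 500 permutations each (run for both the topological and
the spatial structure); the anatomical-linkage detection contrast on 100
signal-bearing samples; the exact spatial-reduction check on 50 samples of a
40×40 phantom against an independently coded reference; and oracle
equivalences (component labeling, exhaustive sign-flip enumeration,
exhaustive spanning-tree search, dense smoothing algebra) on graphs of up to
50 nodes. Binomial error at these repetition counts is the limiting
precision: the FWER check accepts up to two binomial standard errors above
the nominal 0.05, i.e. ≈ 0.081 at 200 repetitions.

## Known limitations

* The anatomical structure is only as good as the supplied connectomes;
  densities far from ~1% of possible edges degrade either sensitivity (too
  sparse to merge anything) or specificity (everything merges).
* Sign-flip permutation assumes symmetric errors; heavy skew in per-subject
  contrasts would bias the null.
* The distance model fits each connection class marginally; residual
  distance-by-curvature interactions (e.g. gyral bias in tractography) are
  not modeled.
* Smoothing kernels are built from dense pairwise distances, which is
  appropriate up to a few thousand nodes per build; dense whole-brain
  (91k-node) kernels need a blocked or neighborhood-limited construction
  that this package does not implement.
* TFCE-style integration over thresholds, exchangeability-block permutation
  schemes and multivariate statistics are out of scope.
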