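# tcstat

Cluster-extent inference for multi-subject brain statistical maps that
clusters suprathreshold nodes on a **topology** — the union of spatial
adjacency and a group-consensus anatomical connectivity structure — instead
of on spatial adjacency alone. Spatially disjoint activations that are wired
together by white matter can then form a single cluster, which raises the
power of cluster-extent tests for small, anatomically connected effects while
a sign-flip permutation test keeps family-wise error (FWER) at its nominal
level.

The package is aimed at neuroimaging methodologists: it provides the full
topology-construction pipeline from individual connectomes, the permutation
inference, a self-contained 2D phantom for validation, evaluation utilities,
and anatomical network summaries of significant clusters.

## The method

Given per-subject contrast maps over `N` nodes (surface vertices and/or
voxels, "brainordinates"):

1. **Anatomical structure.** From individual connectomes `A_s`, the group
   consistency index is `C(i,j) = (1/S) Σ_s [A_s(i,j) > 0]`. Because short
   connections are seen more often, `C` is standardized against its
   distance trend: per connection class (intrahemispheric, interhemispheric,
   subcortical), consistencies are grouped into equal-count distance bins,
   cubic splines `f_μ`, `f_σ` are fitted through the per-bin mean and sd, and
   `C_n(i,j) = (C(i,j) − f_μ(ED(i,j))) / f_σ(ED(i,j))`. `C_n` is smoothed as
   `F_s C_n F_sᵀ` with a row-stochastic Gaussian kernel (6 mm FWHM default),
   thresholded to the average individual connectome density, and binarized
   into `C_Dist`.
2. **Topology.** `T(i,j) = 1` if `C_Dist(i,j) = 1` **or** `S(i,j) = 1`, where
   `S` is the spatial structure (triangle-mesh edges on surfaces,
   26-neighborhood in volumes).
3. **Inference.** A one-sample two-sided t map is thresholded at a
   cluster-defining threshold (CDT, default z = 3.3, i.e. two-sided
   p = 0.001); same-sign suprathreshold nodes connected in `T` form clusters
   whose extent (node count) is the test statistic. A sign-flip permutation
   null (default 1,000 permutations, identity included) of the maximum
   extent across both signs yields FWER-corrected cluster p-values;
   clusters with p < 0.05 are significant. With `T = S` the procedure is
   exactly conventional spatial cluster-extent inference.

## Worked example

The ribbon phantom is an 80×80 grid masked to an annulus of ~3,000 "gray
matter" pixels in 11 atlas regions, with three active regions (97, 29 and 4
pixels, peak 1) and hypothetical fibers (association, projection,
commissural) linking them:

```r
library(tcstat)

phantom <- make_ribbon_phantom()
topo    <- make_phantom_topology(phantom)   # S: 4-lattice, T: S + fibers
sample  <- simulate_subject_sample(phantom, n_subjects = 40, seed = 5)

res_T <- run_inference(sample, topo$T, cdt = 2, n_perm = 500, seed = 11)
res_S <- run_inference(sample, topo$S, cdt = 2, n_perm = 500, seed = 11)
res_T
#> <inference_result> 3020 nodes, 108 cluster(s), 1 significant at alpha = 0.05
#>    cluster sign extent p_fwer
#> 1        1    1    131  0.002
#> 2        2   -1      3  0.956
#> ...
res_S
#> <inference_result> 3020 nodes, 110 cluster(s), 2 significant at alpha = 0.05
#>    cluster sign extent p_fwer
#> 1        1    1     97  0.002
#> 2        2    1     30  0.002
#> 3        3    1      4  0.522
#> ...
```

Under the topology `T`, the three active regions merge through their fiber
links into one 131-pixel cluster (p = 0.002), so the 4-pixel region is
detected. Under the spatial structure `S` the same 4 pixels form their own
cluster (extent 4, p = 0.52) and are missed — the anatomical linkage is what
rescues the small effect.

Downstream:

```r
truth <- discretize_truth(group_t_statistic(sample)$d, 0.1)
informedness(predicted_sign(res_T), truth)   # TPR, TNR, BM = TPR + TNR - 1
analytic_power_bounds(n = 1000)$min_detectable_uncorrected  # 0.0621
```

A command-line wrapper covers the same pipeline
(`Rscript inst/cli/tcs.R phantom|topology|infer|evaluate|network ...`).

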