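---
title: "Methods: enamel-outline shape analysis and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enamel-outline shape analysis and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equimorph)
```

This vignette documents the statistical machinery of `equimorph`: the models
and their assumptions, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data tests do and do not
establish.

## 1. Shape capture

A specimen is one digitized occlusal enamel outline: 8 fixed landmarks at
homologous anatomical points (fold extrema of the enamel band) joined by 8
curves digitized as dense polylines. Landmarks are homologous point-to-point;
curve points are not — only the curve itself is homologous — so each curve is
resampled into a fixed number of *semi-landmarks*, equally spaced in arc
length, which are later allowed to slide along the outline.

**Scheme.** `slider_scheme()` fixes the per-curve semi-landmark counts. The
protocol the package mirrors specifies only the total of 178 semi-landmarks
(186 points); the per-curve breakdown is not recoverable from the source
material, so the default spreads them nearly evenly — `(22, 22, 22, 22, 22,
22, 23, 23)` — and the counts are a parameter for datasets digitized
differently. Point order (landmarks first, then curves in anatomical order)
is enforced by the scheme so datasets are interoperable.

**Resampling.** `k` semi-landmarks on a curve of arc length `L` sit at
`L·i/(k+1)`, `i = 1..k`, excluding the flanking landmarks. Resampling is
linear interpolation along the digitized polyline; the digitization density
(≥ 40–60 points per curve) makes the discretization error negligible relative
to digitization noise.

**Mirroring.** Left and right teeth are mirror images; `mirror_to_left()`
reflects right-sided configurations about a vertical axis through the
outline's midline. Reflection is an isometry, so sizes and inter-point
distances are exactly preserved; doing this *before* superimposition is what
justifies restricting the Procrustes rotations to determinant +1.

## 2. Superimposition

`gpa()` implements generalized Procrustes analysis: center each
configuration, scale to unit centroid size, rotate to the running consensus
by the rotation-only least-squares solution (SVD with a determinant
correction; reflections are never used, see above), update the consensus,
iterate to tolerance `1e-10`. Under the unit-centroid-size convention every
aligned shape satisfies `sum(coords²) = 1`, and the stored consensus is the
exact coordinate-wise mean of the aligned shapes.

**Orientation convention.** GPA determines shapes only up to a global
rotation (the first specimen's arbitrary digitized orientation would
otherwise leak into the output). The final sample is therefore rotated to the
principal axes of the consensus with a deterministic sign rule, making the
Procrustes coordinates invariant — to numerical tolerance — to arbitrary
similarity transforms of any input. The rule is ambiguous only for shapes
with (near-)circular symmetry, which teeth are not.

**Sliding.** Semi-landmarks are slid to minimize thin-plate-spline bending
energy relative to the consensus. With reference `X`, the TPS system
`L = [[K, Q], [Q', 0]]` (kernel `U(r) = r² log r²`, affine design
`Q = (1, x, y)`) yields the bending-energy matrix `L_k` (upper-left `p × p`
block of `L⁻¹`); the bending energy of a displacement field `d` is
`d'L_k d` per coordinate, zero exactly on affine fields. Each semi-landmark
may move only along its local tangent — the chord between its two neighbours
in the slider chain (a standard finite-difference tangent, robust to noise) —
and the vector of slide magnitudes solves the induced linear system exactly.
Sliding therefore never increases bending energy. Design choices, made once:

- the criterion is *minimum bending energy* relative to the Procrustes
  consensus (not minimum Procrustes distance), matching the classical
  sliding algorithm;
- one full slide pass per GPA cycle, 5 GPA+slide cycles by default,
  stopping early when total energy stabilizes (`tol` on the relative
  change); whether the original analyses slid once or iterated is unstated
  in the source protocol, so the package iterates — the consensus used as
  the bending reference is itself an estimate, and iterating removes the
  dependence on its initial value;
- shapes are re-centered and re-scaled after each pass, since sliding
  perturbs the centroid and size; the monotonicity guarantee applies to the
  raw minimizer (exposed via `slide_semilandmarks(renormalize = FALSE)`),
  the re-normalization being a similarity transform of negligible energetic
  effect;
- degenerate tangents (coincident neighbours) freeze that semi-landmark
  with a warning rather than failing the whole fit.

## 3. Shape statistics

**PCA.** `shape_pca()` is an SVD of the centered coordinate matrix.
Downstream discriminant analyses use the smallest number of components whose
cumulative variance reaches `threshold` (default **0.99**, the conventional
choice for this protocol). The threshold trades information for
conditioning: the pooled within-group covariance inverted by the CVA must
have `m < n − g`; with very small samples (as in the package's unit tests)
a lower threshold is needed, and `manova_pillai()`/`cva()` fail with an
explicit "retain fewer PCs" error rather than silently regularizing.

**Permutation shape ANOVA.** High-dimensional Procrustes coordinates (2p ≈
372 variables, n ≈ a few hundred) rule out classical parametric MANOVA on
the full coordinates. `shape_anova()` uses the standard randomization
approach for shape data: sequential (type-I) sums of squares of the
multivariate linear model, traced over all coordinates;
`F = MS_term/MS_resid`; significance by *residual randomization under the
reduced model* — for each term, the reduced-model residuals are permuted
across specimens and the term's F recomputed. Defaults: `n_perm = 999`
(+ observed). The effect size `Z = (F_obs − mean F_perm)/sd F_perm` locates
the observed statistic in its permutation distribution (observed included);
this is the definition reported in the output header, since permutation-Z
conventions differ between software generations. The p-value is the
proportion of the distribution ≥ the observed value, so it can never be 0.
Term order is the user's; the package's factorial pipeline enters anatomical
position before taxon, with the interaction last.

**CVA and classification.** `cva()` solves the generalized eigenproblem
`max a'Ba` subject to `a'Wa = 1` via the Cholesky factor of `W`, so canonical
variates have unit pooled within-group variance and Euclidean distance in
canonical space equals Mahalanobis distance in score space.
`crossval_classify()` estimates practical accuracy by repeated stratified
twofold cross-validation (default **10 000 rounds**): training halves
alternate between ceiling and floor of half the group (a group of 2
contributes 1+1 — the smallest feasible twofold split), the CVA is refitted
on each training set, and test rows are assigned to the nearest centroid
(equal priors; ties break to the lowest group index for determinism under a
fixed seed). Untrainable splits are redrawn, and more than 50% redraws is an
error. Two summaries are reported: the headline **CCV** is the mean
per-round percentage of correct assignments (per-specimen averaging first,
then the mean), with the modal-assignment accuracy alongside. Whether
classification happens in canonical space or directly on PCs by Mahalanobis
distance is immaterial under a full-rank CVA — the rankings coincide — and
the package classifies in canonical space.

**Predictive assignment.** `predict_unknown()` maps an undetermined
configuration into the trained space by a single orthogonal Procrustes fit
onto the consensus, projects onto the retained PCs, and reports squared
Mahalanobis distances to each group centroid and posteriors
`∝ exp(−D²/2)` (equal priors).

## 4. Phylogenetic comparative layer

Species mean shapes for the taxa present on the tree are computed *after
re-superimposing just those specimens* (their own GPA per tooth), then
averaged per taxon — mean shapes live in that subset's shape space.
Whether full Procrustes coordinates or retained PC scores feed the K
statistic is immaterial for the distance-based formulation (it is invariant
to orthonormal changes of basis, which the package verifies by test);
`kmult()` takes whatever matrix it is given and defaults to full
coordinates in the pipeline.

**K statistic.** With tip data `Y` (N × d), BM covariance `C`, GLS mean
`â = (1'C⁻¹1)⁻¹1'C⁻¹Y`:

`K = [ Σᵢ‖yᵢ − â‖² / Σᵢ‖C^{-1/2}(yᵢ − â)‖² ] ÷ [ (tr C − N/(1'C⁻¹1)) / (N − 1) ]`

Under Brownian motion `E[K] ≈ 1`; `K < 1` means relatives resemble each
other less than BM predicts. The permutation test shuffles the rows of `Y`
(species mean shapes) across tips — the statistic's standard null; permuting
specimen-level data instead would conflate within-species sampling error
with phylogenetic structure, and is not offered. Default `n_perm = 1000`,
add-one p-value. Branch lengths are consumed as given (substitutions or
time); K is scale-invariant in the branch-length unit.

**Ancestral shapes.** `squared_change_parsimony()` minimizes
`Σ_edges ‖x_parent − x_child‖²/length` with tips fixed: the stationarity
conditions form a sparse weighted-Laplacian system solved exactly per trait
dimension (no iteration). With branch-length weighting this coincides with
the ML/GLS ancestral estimates under BM — an equivalence the acceptance
suite checks to `1e-8`. Polytomies are handled natively; zero-length
branches are floored with a warning.

**Phylomorphospace.** PCA of the species means, SCP on the retained scores,
branches drawn between tip and node coordinates on (PC1, PC2); the
reconstructed root shape is returned so species outlines can be displayed
against the ancestral outline.

## 5. The synthetic generator: what it emulates, what it does not

`simulate_tooth_study()` states a world once and the tests live in it:

- **Design.** 15 taxa × 4 tooth positions with the unbalanced per-group
  sample sizes of the emulated study (`default_taxon_table()`, groups of
  2–15), so the small-group edge cases (1+1 twofold splits) are exercised
  by default; 10 of the 15 taxa sit on a fixed phylogeny
  (`default_equid_tree()`) with the caballine/(asses+hemiones, zebras)
  clade structure and arbitrary unit-scale branch lengths — the real tree's
  lengths are unpublished alongside this package, so only the topology is
  copied.
- **Template.** A smoothed ellipse (aspect 1.7) with 8 sinusoidal inward
  folds (relative depth 0.25) standing in for the folded enamel band; 8
  landmarks at fold extrema, 8 dense curves.
- **Effects.** Taxon, tooth and interaction effects are coefficients on 5
  low-frequency harmonic displacement fields of the outline angle — smooth,
  anatomically coherent deformations rather than iid per-landmark offsets.
  Taxon effects for tree taxa evolve by Brownian motion (rate defaulting to
  `taxon_effect_scale²/mean(diag(C))` so on- and off-tree taxa diverge
  comparably). Default scales (relative radius units): taxon 0.05, tooth
  0.04, interaction 0.02, within-group noise 0.01, extra curve jitter
  0.002 — chosen once so that effect ordering and magnitudes echo the
  emulated study's results (taxon > tooth > interaction, all ≫ noise;
  near-perfect but not trivial classification).
- **Nuisance structure.** Random per-specimen rotation, translation and
  ~15% log-scale magnification; about half of the specimens stored as
  mirrored right sides.

It does **not** emulate: real flexid anatomy (no claim that the template's
folds match any tooth), wear/age effects (excluded by prior evidence in the
emulated protocol), digitizer autocorrelation along curves, or measurement
error correlated with size. A green pipeline test therefore establishes the
*statistical* machinery — recovery of effects with the right calibration —
not anatomical validity of any biological conclusion.

## 6. Numerical conventions and degenerate inputs

- Convergence: GPA consensus RMS change `< 1e-10`; sliding cycles stop when
  total bending energy stabilizes.
- Collinear TPS references, singular phylogenetic covariances, zero-size
  configurations, single-member groups, zero-variance traits and one-level
  factors all raise explicit errors naming the remedy; zero-variance trait
  columns in `kmult()` are dropped with a warning.
- All stochastic functions take a `seed` and restore the caller's RNG
  state; identical seeds give identical results, including byte-identical
  generated files.
- Assignment ties break to the lowest group index; GPA orientation sign
  ties break by the largest-|x| consensus point.

## 7. Known limitations

- Strictly 2D occlusal outlines; no 3D support.
- The per-curve semi-landmark breakdown and exact landmark definitions of
  the emulated protocol are configurable defaults, not recovered facts.
- `crossval_classify()` refits a full CVA per round; at 10 000 rounds on
  large studies this is minutes, not seconds.
- The K permutation test has little power below ~8 tips (the package still
  reports the observed K).
- Parametric MANOVA (Pillai) is only offered on retained PC scores with
  `m < n − g`; there is no regularized discriminant fallback by design.
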