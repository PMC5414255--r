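# equimorph

Geometric morphometrics of equid cheek-tooth enamel with a phylogenetic
comparative layer.

## The problem

The occlusal surface of an equid mandibular cheek tooth (P3, P4, M1, M2)
exposes a folded enamel band whose outline carries both taxonomic and
evolutionary information. Palaeontologists and zooarchaeologists need to
answer, from an isolated tooth, two questions: *which tooth is it* and *which
equid taxon does it belong to* — and, across taxa, *how much of the shape
variation tracks the phylogeny*. `equimorph` implements the complete
quantitative toolchain for such a study:

1. **Shape capture.** TPS landmark/curve files (the `tpsDig` dialect) are
   read, right-sided teeth mirrored to the left, and each digitized curve
   resampled into equidistant semi-landmarks (default protocol: 8 fixed
   landmarks + 178 semi-landmarks on 8 curves = 186 points).
2. **Superimposition.** Generalized Procrustes analysis (centering, unit
   centroid-size scaling, rotation-only least-squares alignment) with
   sliding semi-landmarks: each semi-landmark moves along its local curve
   tangent to minimize the thin-plate-spline bending energy
   `d' L_k d` relative to the consensus, where `L_k` is the `p × p`
   upper-left block of the inverse TPS system matrix with kernel
   `U(r) = r² log r²`.
3. **Shape statistics.** PCA with variance-threshold retention (default
   99%); factorial permutation shape-ANOVA with sequential sums of squares
   and residual randomization (`F = MS_term / MS_resid`,
   `Z = (F_obs − mean F_perm)/sd F_perm`); MANOVA (Pillai); canonical
   variate analysis normalized to unit pooled within-group variance;
   twofold cross-validated classification (CCV) by Mahalanobis distance;
   predictive assignment of unknowns with posteriors `∝ exp(−D²/2)`.
4. **Phylogenetic signal.** Brownian-motion phylogenetic covariance
   `C` (shared branch lengths); the multivariate K statistic

   `K = [ Σ‖y_i − â‖² / Σ‖C^{-1/2}(y_i − â)‖² ] ÷ [ (tr C − N/(1'C⁻¹1)) / (N − 1) ]`

   with `â` the GLS phylogenetic mean — expectation 1.0 under Brownian
   motion — tested by permuting species across tips; squared-change
   parsimony ancestral shapes (equivalently, ML under Brownian motion);
   and phylomorphospace projection of the tree into PC space.
5. **Synthetic studies.** A fully seeded generator
   (`simulate_tooth_study()`) builds fake studies with the same structure:
   a parametric folded-outline tooth template, Brownian taxon effects on a
   phylogeny, tooth-position and interaction effects as smooth displacement
   fields, digitization noise, mirrored right sides and random image
   transforms — so the entire pipeline is testable without specimen data.

## Worked example

A small synthetic four-taxon study, analyzed end to end:

```r
library(equimorph)
sch <- slider_scheme(c(11,11,11,11,11,11,11,11))   # 88 semi-landmarks
tab <- default_taxon_table()[c(1, 3, 11, 14), ]    # CBL, AFR, GRV, BRC
st  <- simulate_tooth_study(42, taxa_table = tab, scheme = sch, n_dense = 40)
rep <- analyze_tooth_study(st, tree = st$tree, scheme = sch,
                           rounds = 200, n_perm_anova = 199, n_perm_k = 199,
                           threshold = 0.95, seed = 42)
print(rep)
```

```
Dental study analysis (seed 42 , 6 s)

Permutation shape ANOVA (sequential SS, residual randomization, 199 permutations)

             Df       SS         MS      Rsq       F      Z Pr(>F)
tooth         3 0.541745 0.18058172 0.444299 906.465 14.071  0.005
taxon         3 0.589617 0.19653908 0.483560 986.566 14.071  0.005
tooth:taxon   9 0.064854 0.00720604 0.053189  36.172 14.035  0.005
Residuals   116 0.023109 0.00019922 0.018952      NA     NA     NA
Total       131 1.219326         NA 1.000000      NA     NA     NA

Anatomical CCV: 98.1 %
Taxonomic CCV per tooth (%): P3=100.00, P4=100.00, M1=100.00, M2=100.00
Phylogenetic signal per tooth:
  P3   K = 0.8077  p = 0.7
  P4   K = 0.8974  p = 0.3
  M1   K = 0.9721  p = 0.125
  M2   K = 0.9480  p = 0.215
```

Reading the output: both factors and their interaction are significant
(`Pr(>F)` is the permutation p-value; `Rsq` the fraction of total shape
variation). The anatomical model identifies tooth position in 98% of
cross-validated assignments, taxa are perfectly separable here by
construction, and K is near its Brownian expectation of 1 — with only four
species on the tree the permutation test has essentially no power, which is
why the p-values are large. `write_study_report(rep, "out/")` exports every
table as CSV plus a JSON run report with all seeds and parameters.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the calibration of the
multivariate K statistic: 500 trait sets (20 dimensions) are simulated under
Brownian motion along a fixed 10-tip phylogeny and the mean K across
replicates is written as JSON.

## Layout

- `R/` — implementation (TPS I/O, scheme, GPA/sliding, PCA/ANOVA/CVA,
  phylogenetic methods, synthetic generator, pipeline).
- `tests/testthat/` — unit, property and acceptance tests; all fixtures are
  generated in code.
- `vignettes/enamel-shape-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical conventions, limitations.
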