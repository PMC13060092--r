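# dmscan

Deep mutational scanning (DMS) analysis for transporter specificity
screens.

A metal transporter can be screened for thousands of variants at once two
ways: a **sort-seq** assay, where a fluorescent reporter of intracellular
metal drives FACS sorting into four bins and barcode sequencing reads out
each variant's bin occupancy, and a **growth selection**, where a
transporter-knockout strain only grows if a variant imports a second
substrate. dmscan is an R toolkit for designing such screens and
analyzing their output end to end:

* **Library design** — identity-threshold sequence reweighting
  (θ = 0.8, M<sub>eff</sub>), site-independent PSSMs, a PCA latent
  embedding of the one-hot alignment, and Gibbs sampling from restrained
  energy models
  U′(x) = U(x) + w<sub>d</sub>·Hamming(x, WT) − w<sub>pca</sub>·‖u(x) − u₀‖,
  with calibration of T, w<sub>d</sub>, w<sub>pca</sub>; binding-site
  shell enumeration from structures (12 Å any-atom rule, 19 missense +
  synonymous + deletion per position); variational-synthesis
  position/frequency designs.
* **Scores** — Poisson–Gamma read-count posteriors
  (f̂ = (c+1)/(N(1+β))), weighted-mean-bin sort-seq scores anchored to
  WT = 1 / null = 0 with 100-draw resampling errors, growth
  log-enrichment with pre-count thresholds, DerSimonian–Laird
  random-effects replicate merging, errors-in-variables (ODR-style)
  cross-library calibration, and BH-FDR hit calling against a WT-barcode
  null.
* **Phenotypes** — anchored two-component Gaussian mixtures for flow
  cytometry (regularized EM, λ<sub>μ</sub> = λ<sub>Σ</sub> = 0.3,
  λ<sub>π</sub> = 0.1), Michaelis–Menten dose responses, nested
  logistic/Richards/Baranyi–Roberts growth-model selection by BIC.
* **Landscape models** — Bayesian global-epistasis regression
  y ~ N(g(β₀ + Σβ), se² + σ²) with identity or sigmoid link
  g(z) = L + (U−L)·logistic(z); 99.5% posterior-predictive double-mutant
  cycle outliers; reciprocal-sign-epistasis calls; pairwise couplings
  ω<sub>AB</sub> = g⁻¹(y<sub>AB</sub>) − (β₀+β<sub>A</sub>+β<sub>B</sub>)
  and triple-cycle predictions; two-substrate specificity models with
  shared latents β<sub>g</sub> and a sparse (Laplace-prior)
  specificity set β<sub>s</sub>.
* **Kinetics** — a four-state alternating-access model:
  V′<sub>max</sub>/V<sub>max,0</sub> = (1+r)/(e<sup>φx</sup> + r·e<sup>(φ−1)x</sup>)
  with x = ΔΔG<sub>flip</sub>/RT and r = k₊/k₋, validated against an
  exact steady-state oracle, with epistasis and substrate-specificity
  predictions on that bell-shaped manifold.
* **Synthetic data** — generators for clade-structured alignments,
  sort-seq and selection counts, and flow-event mixtures, all carrying
  their ground truth so every stage is testable without external data.

## Worked example

Simulate a small sort-seq screen from a known landscape, score it, and
fit the global-epistasis model:

```r
library(dmscan)

truth <- random_landscape(n_mutations = 30, effect_sd = 2,
                          effect_mean = -0.5, noise_sd = 0.05, seed = 42)
variants <- unique(c("WT", "null", names(truth$beta),
                     with_seed(43, replicate(80, paste(
                       sample(names(truth$beta), 2), collapse = "+")))))
sim <- simulate_sortseq_counts(truth, variants, sortsim_config(),
                               replicates = 3, seed = 44)
scores <- score_sortseq_table(sim$counts, sim$cells, seed = 45)
head(scores, 5)
#>     variant     score          se n_rep
#> 100      WT 1.0000000 0.004648165     3
#> 83     null 0.0000000 0.002109558     3
#> 49     G49F 0.0715283 0.003604214     3
#> 40    G153R 1.9299321 0.028742866     3
#> 8      C74K 1.0484165 0.020774151     3
```

The anchors are exact by construction — WT scores 1 and the inactive
null 0 in every replicate; other variants scale between "no activity"
(~0) and "WT-like" (~1), with scores above 1 indicating better-than-WT
transport (G153R here carries a strongly positive latent effect). The
Spearman correlation between recovered and true scores in this run is
0.999.

```r
gm  <- build_design_matrix(scores[!scores$variant %in% c("WT", "null"), ])
fit <- fit_global_epistasis(gm, link = "sigmoid")
fit
#> <global_epistasis_fit> link = sigmoid, 30 features, sigma_model = 0.00496, R^2 = 1
cor(fit$beta[names(truth$beta)], truth$beta)
#> [1] 0.9999615
```

The sigmoid link adds only two parameters (its asymptotes) over a linear
model, and the fitted background-averaged latent effects β match the
planted ones to r = 0.99996 at this noise level.

On the kinetics side, the conformational-balance curve for a transporter
whose loaded flip is 10× faster than its return flip (r = k₊/k₋ = 10,
φ = 0.5) peaks at a *destabilized* inward state — a mutation can beat the
wild type:

```r
optimal_ddg(phi = 0.5, kratio = 10, RT = 1)
#> $ddg_opt
#> [1] 2.302585
#> $peak
#> [1] 1.739253
vmax_ratio(c(-2, 0, 2.3, 6), phi = 0.5, kratio = 10, RT = 1)
#> [1] 0.3992639 1.0000000 1.7392513 0.5344110
```

A variant at ΔΔG ≈ +2.3 RT transports 1.74× faster than WT, while
perturbations in either direction away from the optimum lose activity —
the bell shape that lets pairs of conformation-shifting mutations show
negative, positive, or reciprocal sign epistasis
(`predict_double_cycle()`), and lets one mutation raise one substrate's
V<sub>max</sub> while lowering another's (`specificity_trajectory()`).

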