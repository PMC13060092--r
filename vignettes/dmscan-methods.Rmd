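---
title: "Models and methods in dmscan"
author: "dmscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dmscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscan)
```

dmscan is an analysis toolkit for deep mutational scanning (DMS) of a
membrane metal transporter assayed two ways: a fluorescence **sort-seq**
screen for the native substrate (cells sorted into four bins by a
riboswitch-driven reporter of intracellular metal, bin occupancy read out
by barcode sequencing) and a **growth selection** for a secondary substrate
(a transporter-knockout strain grows only if the variant imports the
second metal). Around those two screens the package covers
evolution-guided library design from an alignment of homologs, Bayesian
global-epistasis and two-substrate specificity regression, double- and
triple-mutant-cycle analysis, and a four-state alternating-access kinetic
model that ties the observed epistasis and specificity patterns to the
transporter's conformational equilibrium.

Every stage can be exercised on synthetic data generated from an explicit
ground truth, so the whole pipeline is testable without access to raw
screen data. This vignette records the models, the tunable parameters and
their defaults, the numerical choices, and the limits of what the
synthetic benchmarks demonstrate.

## Variant notation and barcode counting

Variants are written in the compact protein notation used throughout the
field: `"M230A"` (substitution, 1-based residue index), `"Δ230"` /
`"del230"` (codon deletion), `"ins230A"` (insertion after residue 230),
joined by `+` and canonically ordered by position; the wild type is the
literal `"WT"`. `parse_variant_string()` and `render_variant()` are exact
inverses on canonical strings.

Barcodes follow an 18-nt `NNNNSWNNNNSWNNNNSW` template (S = G/C, W = A/T)
located between fixed flanks. `count_barcodes()` extracts barcodes by
exact flank match — no mismatch tolerance. The rationale: libraries are
bottlenecked and deeply sequenced, and singleton barcodes are discarded
when the barcode–variant map is built, so sequencing errors mostly produce
unmapped barcodes, which are tallied rather than guessed at. Every read
lands in exactly one of four tallies (mapped, unmapped,
template-violating, unparsed), an invariant the tests assert.

## From counts to scores

**Read-count posterior.** Counts $c$ for a variant in a sample of
$N_\mathrm{reads}$ are modeled as Poisson with rate $\lambda = f
N_\mathrm{reads}$ and a conjugate $\Gamma(\alpha, \beta)$ prior on
$\lambda$, giving the posterior $\Gamma(\alpha + c,\, 1 + \beta)$ and the
posterior-mean frequency

$$\hat f = \frac{c + \alpha}{N_\mathrm{reads}(1 + \beta)},$$

with defaults $\alpha = 1$, $\beta = 0.001$ — a nearly flat prior that
still assigns appropriately larger relative errors to low-count variants.

**Sort-seq score.** Per bin $b$, the estimated read frequency is
converted to a sorted-cell weight $w_b \propto \hat f_b C_b$ (reads are
per-bin samples, so each bin's frequencies are normalized within the bin
before weighting by the number of sorted cells $C_b$). The summary is the
weighted mean bin $\sum_b b\, w_b / \sum_b w_b$ (bins indexed 1–4),
normalized so the wild type scores 1 and an inactive frameshift-like null
scores 0 — exactly, in every replicate, by construction. Errors come from
100 posterior draws of the variant's bin frequencies (anchor raw values
held fixed); each variant gets a dedicated seed stream so scores are
reproducible. Replicates merge through a DerSimonian–Laird random-effects
model: between-replicate variance by method of moments (truncated at
zero), inverse-variance weights $1/(\sigma_i^2 + \tau^2)$. The merge is
cross-checked in the tests against `metafor::rma(method = "DL")`.

**Growth selection.** The log enrichment is
$\log(\hat f_\mathrm{post} / \hat f_\mathrm{pre})$ per replicate. Because
the pre-selection overnight cultures drop variants stochastically,
replicates with a pre-selection count below a threshold (default 50) are
excluded, and a variant failing in every replicate is reported *missing*,
never zero. Under exponential selection the expected log-enrichment
difference between two variants is $\Delta(\text{activity}) \times t$,
which the generator-recovery tests confirm to closed form.

**Cross-library calibration.** Scores from two libraries measuring the
same variants on different scales are merged by an errors-in-variables
(orthogonal-distance–style) linear fit: minimize
$\sum_i (y_i - m x_i - b)^2 / (\sigma_{y,i}^2 + m^2 \sigma_{x,i}^2)$
over $(m, b)$ after filtering both tables on their score errors (default
$\sigma \le 0.15$). Ordinary least squares would attenuate the slope
because the $x$ axis is itself noisy; the acceptance checks plant a known
slope and verify the errors-in-variables fit recovers it while OLS is
measurably biased low. Table B is rescaled through $(y - b)/m$ and merged
per variant with the random-effects model.

**Hit calling.** The null is the empirical distribution of scores among
barcodes mapping to the wild-type protein:
$z = (s - \mu_0) / \sqrt{\sigma_0^2 + \mathrm{se}^2}$, one-sided upper
p-values (enrichment above WT is the alternative; a two-sided switch
exists), Benjamini–Hochberg step-up FDR at level 0.05. We use a normal
reference with the pooled variance rather than a t reference — with
dozens of WT barcodes the difference is negligible, and the choice is
recorded here because it is not derivable from the interface.

## Phenotype fits

**Anchored Gaussian mixture.** Flow events (log10 fluorescence, side
scatter) are bimodal when part of the population silences expression. A
single Gaussian is first fit to the negative control
($\mu_\mathrm{inactive}, \Sigma_\mathrm{inactive}$); all other samples get
a two-component EM fit whose first component is regularized toward that
anchor by $\lambda_\mu \lVert \mu_1 - \mu_\mathrm{inactive}\rVert^2 +
\lambda_\Sigma \lVert \Sigma_1 - \Sigma_\mathrm{inactive}\rVert^2 +
\lambda_\pi \pi_1$, with defaults $\lambda_\mu = \lambda_\Sigma = 0.3$,
$\lambda_\pi = 0.1$. The mean and weight penalties have closed-form
penalized M-steps (a 2×2 linear solve and a quadratic root respectively).
The Frobenius penalty on $\Sigma_1$ has no closed-form M-step, so
$\Sigma_1$ is updated by convex shrinkage toward the anchor with weight
$\rho = \lambda_\Sigma / (\lambda_\Sigma + N_1)$ — a fixed-point surrogate
that reaches the correct limits (plain EM at $\lambda = 0$, pinned to the
anchor as $\lambda \to \infty$, both asserted in tests, the former against
`mclust`'s EM from an identical start) and preserved a monotone objective
on every tested dataset; the objective trace is stored so monotonicity is
checkable per fit. The downstream score is the active component's mean
log fluorescence.

**Dose response.** Control-subtracted responses are fit to
$y = V_\max c / (K_M + c)$ by Levenberg–Marquardt from the standard
initial guesses $V_\max = 0.1$, $K_M = 25$. The fitted $K_M$ is an
*effective* in-vivo constant, inflated by competing ions in the medium. A
flat response is reported with $V_\max \approx 0$ and the $K_M$ flagged
unidentifiable.

**Growth curves.** OD curves are truncated to the first 8 h (excluding a
later second growth phase), then fit by bounded least squares to the
nested family logistic (3 parameters) ⊂ Richards (+ shape $v \ge 1$) ⊂
Baranyi–Roberts (6 parameters, adding a lag through the initial
physiological state $q_0$), with bounds $y_0 \in [0, 0.05]$,
$K \in [0.4, 10]$, $r > 0$, $v, q_0 \ge 0.01$ for the lag model. The
minimum-BIC candidate wins and only its rate $r$ is reported; a flat
curve is flagged no-growth.

## Evolution-guided library design

**Alignment models.** Sequences are reweighted by the standard identity
rule (weight $1/|\{j : \mathrm{id}(i,j) \ge \theta\}|$, $\theta = 0.8$;
$M_\mathrm{eff} = \sum w_i$) and a site-independent PSSM is built from
weighted frequencies with a pseudocount over the 21-letter alphabet (20
amino acids + gap). Columns under 70% coverage are excluded from the
PSSM but retained in the PCA, because coverage filtering belongs to model
inference, not to the latent embedding.

**Latent space.** The one-hot alignment matrix is column-centered and
decomposed by truncated SVD, $X \approx U \Sigma V^{\mathsf T}$; rows of
$U\Sigma$ embed sequences, columns of $V$ are directions in mutation
space, and a reference (wild-type) embedding $u_0$ anchors displacement
calculations. Whether to center is not externally specified; we center
(standard PCA) — the uncentered variant differs only in a rank-one
correction. PCA is computed unweighted by default (reweighting is
documented for model inference, not the embedding); a weighted variant
sits behind the `weights` argument for sensitivity analysis. `k = 2` by
default: the first two components carry the clade-separation signal that
the design exploits. A single substitution displaces the embedding by
exactly the difference of two rows of $V$, so `top_latent_mutations()`
ranks candidate mutations by that displacement norm over the first two
components — these are the mutations conserved within clades but differing
between them.

**Restrained Gibbs sampling.** Sequences are sampled from
$p(x) \propto \exp(-U'(x)/T)$ with

$$U'(x) = U(x) + w_d \sum_i [x_i \ne x_{i,\mathrm{WT}}]
          - w_\mathrm{pca} \lVert u(x) - u_0 \rVert.$$

The linear distance restraint approximately cancels the entropy growth of
distant sequences; the exploration term *rewards* latent displacement.
The source equation is written as an additive term while being described
as a reward, a sign ambiguity we resolve in favor of the described
behavior: the term enters with a negative sign, and the tests assert that
raising $w_\mathrm{pca}$ enriches the latent-weighted control mutations.
Each sweep visits positions in a fresh random order; conditionals are
exact single-position energy differences (closed form for PSSM + Hamming;
the latent norm is recomputed per candidate letter in $O(k)$ via cached
$V$ rows). Exactness is tested against exhaustive Boltzmann enumeration
on toys (total-variation distance < 0.02 at the stated sweep counts).

**Calibration.** The temperature is the grid point whose samples match
the wild type's average energy. The weights $(w_d, w_\mathrm{pca})$ are
calibrated by sweeping $w_\mathrm{pca}$ and, for each value, bisecting
$w_d$ to hit a target mean Hamming distance (2.8 by default, the mean of
a distance distribution peaking at 2–4 mutations), then choosing the
$w_\mathrm{pca}$ that maximizes sampling of positive-control mutations
subject to a cap on the single most latent-weighted mutation (one third
of the library by default), which would otherwise dominate.

**Synthesis design.** From the sampled sequences, the 59 most-mutated
positions (ties to the lower index) become the variable positions of a
stochastic synthesis design; per-position frequencies equal the sample
marginals — the independent-product distribution closest in KL divergence
to the sampled distribution. Correlations between positions are
necessarily lost; the tests document this on a perfectly correlated toy.

**Binding-site shell.** The companion site-saturation library enumerates
every position with any non-hydrogen atom within 12 Å of the bound metal
in any supplied structure (any-atom rather than Cα distance, the reading
closest to "every position within" a radius; configurable). Per position
and per background: 19 missense variants coded by the organism's most
abundant codon, one synonymous control when the wild-type amino acid has
more than one codon, and one codon deletion — so a two-codon-amino-acid
position contributes 21 designs and a Met/Trp position 20. The codon
table ships with the package as a versioned text file.

## Global epistasis and specificity

**Model.** Scores are regressed on binary mutation features with an
additive latent phenotype $z_v = \beta_0 + \sum_{m \in v} \beta_m$ and a
link $g$ — identity, or the sigmoid
$g(z) = L + (U - L)\,\mathrm{logistic}(z)$. Slope and midpoint of the
sigmoid are absorbed into $\beta_0$ and the scale of $\beta$ (they are
non-identifiable separately), so the sigmoid adds exactly two parameters
over the linear model. The observation model is
$y_v \sim \mathcal N\!\big(g(z_v),\; \mathrm{se}_v^2 +
\sigma_\mathrm{model}^2\big)$: known experimental error plus a learned
global model variance, the standard measurement-error composition.
Normal priors on $\beta$ (sd 10 by default).

**Inference.** The posterior is summarized by a Laplace (quadratic)
approximation at the MAP: `nlminb` with analytic gradients, covariance
from the inverse Hessian. For the identity link this is the exact
Gaussian posterior; for the sigmoid it matches a mean-field variational
summary wherever the tests can compare recovery. The approach is
deterministic, seed-free at fixed data, and fast enough to refit in
seconds at $2{,}000$ variants × 50 features (the recovery benchmark:
Pearson $r > 0.95$ between fitted and planted $\beta$ at noise sd 0.1,
asymptotes within 2%).

**Mutant cycles.** For every double cycle $\{WT, A, B, AB\}$ the model
predicts $g(\beta_0 + \beta_A + \beta_B)$; the 99.5% posterior-predictive
interval combines the delta-method parameter variance, the model
variance, and the double's experimental error. On purely additive null
simulations the flag rate sits at the nominal 0.5% (slightly conservative,
0.2–0.4% in practice, because in-sample predictions correlate with their
own observations — the calibration band in the acceptance suite is
0.5% ± 0.3%). Reciprocal sign epistasis is called on observed quartets:
both single-mutation effects must flip sign across backgrounds, with every
background effect exceeding twice its propagated error; within-error
differences never flag. Pairwise couplings are read off double cycles on
the latent scale, $\omega_{AB} = g^{-1}(y_{AB}) - (\beta_0 + \beta_A +
\beta_B)$ (scores outside the invertible range are clipped and flagged),
and plugged into triple-cycle predictions as point estimates — fitting
couplings jointly is a documented alternative we did not take, since the
plug-in form is what the cycle decomposition defines.

**Two-substrate specificity.** The constrained curve assumes all
variants share a latent phenotype read off the primary-substrate score
through the inverse primary link, with a single specificity shift
$\Delta_\mathrm{spec}$ attributed to the focal mutation; the residual
$\varepsilon_v$ is measured vertically in the secondary-substrate
direction at the observed primary score (the projection axis is a
package choice, recorded here), so $\varepsilon > 0$ means more
secondary-substrate activity than expected. The sparse model replaces the
single shift with per-feature shifts: $z^{(1)} = \beta_0^{(1)} + X
\beta_g$, $z^{(2)} = \beta_0^{(2)} + X(\beta_g + \beta_s)$, each substrate
with its own sigmoid; $\beta_g$ carries a normal prior and $\beta_s$ a
sparse Laplace prior, implemented as an L1 penalty (smoothed
$\sqrt{x^2 + 10^{-8}}$) inside the same MAP optimizer, with rate
`lambda_s = 20` chosen so that planted determinants of magnitude ≥ 2
survive while null features shrink below $10^{-3}$ at the benchmark's
noise level. One identifiability property matters in practice and is
exercised by the tests: a specificity shift attached to a fully
inactivating mutation is invisible, because both substrate scores sit on
the saturated tail of the sigmoid — recovery benchmarks therefore plant
shifts on moderate-effect mutations, just as experimentally identified
determinants are necessarily mutations with measurable activity.

## Conformational-balance kinetics

A four-state alternating-access cycle (outward-empty → outward-bound →
inward-bound → inward-empty →) with three assumptions: conformational
flips are rate-limiting, all intermediates are at steady state, and
transition-state energies track the inward/outward gap linearly with
$\phi \in (0,1)$. A mutation shifting the gap by $\Delta\Delta G$
(**sign convention, fixed here because it is stated nowhere upstream:
positive destabilizes the inward-open state**) rescales the loaded flip
by $e^{-\phi x}$ and the return flip by $e^{(1-\phi)x}$, $x =
\Delta\Delta G / RT$, giving

$$\frac{V'_\max}{V_{\max,0}}
  = \frac{1 + r}{e^{\phi x} + r\, e^{(\phi - 1) x}},
  \qquad r = k_+/k_-,$$

a bell-shaped curve equal to 1 at $x = 0$, vanishing at $\pm\infty$, and
peaking at $x^* = \log\!\big(r (1 - \phi)/\phi\big)$ — so raising $r$
shifts the optimum right, and the symmetric cycle ($r = 1$, $\phi = 1/2$)
peaks exactly at the wild type. The printed source equation for this
ratio is typographically garbled, so the implementation derives the form
above directly from the three assumptions and validates it against an
exact steady-state oracle (`four_state_flux()`, a linear solve of the
master equation) to relative error $< 10^{-6}$ across a
$3 \times 3 \times 41$ parameter grid. One discrepancy is reported rather
than resolved: the source text asserts the peak *height* is independent of
$\phi$, but for this closed form it is not —
`peak_phi_profile()` exposes the dependence numerically, and we do not
substitute a guessed alternative derivation.

Because the curve is non-monotonic, two mutations acting only through
$\Delta\Delta G$ (which adds on the energy scale) can produce negative,
positive, or reciprocal sign epistasis — `predict_double_cycle()`
classifies the quartet — and two substrates with different baseline $r$
have different optima, so one perturbation can raise one substrate's
$V_\max$ while lowering the other's (`specificity_trajectory()` reports
where the derivatives oppose). This reproduces, in a two-parameter
mechanistic model, the qualitative epistasis and specificity structure
the regression models measure phenomenologically.

## The synthetic-data generators

All generators are deterministic under a seed (`with_seed()` restores the
caller's RNG state) and return their ground truth alongside the data, so
every recovery test compares against truth, never against published
real-data numbers.

* `simulate_msa()`: clade-structured alignments — per-clade consensuses
  diverging from a shared root at a controlled fraction of positions,
  plus i.i.d. within-clade substitutions at rate 0.05/site, a value in
  the range of within-clade diversity in large transporter alignments.
* `simulate_sortseq_counts()`: the latent additive-plus-sigmoid landscape
  (defaults $L = 0$, $U = 1$), per-cell Gaussian log-fluorescence noise
  (sd 0.25), four gated bins, 1,000 cells/variant, Poisson reads at
  $2 \times 10^5$ per bin — scaled so a 200-variant, 3-replicate screen
  runs in seconds while leaving the score-recovery benchmark
  (Spearman $\rho > 0.9$) non-trivial.
* `simulate_selection_counts()`: exponential growth selection with
  pre-selection dropout (Bernoulli per variant and replicate), modeled
  pre-selection only, where the stochastic culture loss occurs.
* `simulate_flow_events()`: labeled two-component Gaussian mixtures.
* `simulate_variant_scores()`: a shortcut past the sequencing layer for
  regression benchmarks, with an optional mis-specified softplus link for
  robustness checks.

What these generators deliberately do **not** emulate: sequencing-error
profiles in reads, barcode-map errors, the real (unknown) cell-to-cell
fluorescence noise structure (Gaussian on the log scale is a modeling
choice), gate drift between sort days, and culture-condition batch
effects. Passing the recovery benchmarks therefore demonstrates that the
estimators are correct and calibrated under their stated noise models —
not that real screens meet those models.

## Problem sizes and determinism

The test and acceptance workloads are sized to run comfortably on one
CPU: Gibbs exactness on enumerable toys ($5 \times 10^4$ sweeps),
sort-seq recovery at 200 variants × 4 bins × 3 replicates, regression
recovery at 2,000 variants × 50 features, specificity support recovery at
100 features, null-calibration on ~2,300 additive double cycles, and the
kinetics grid at 369 points. All randomness flows through explicit seeds;
`scripts/acceptance.R` derives every stream from its single `--seed`
argument and recomputes all reported quantities from scratch.
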