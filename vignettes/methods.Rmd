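---
title: "Translating bulk transcriptomes into predicted proteomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating bulk transcriptomes into predicted proteomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transprot)
```

## The problem

mRNA abundance is a weak surrogate for protein abundance: across aging
brain cohorts the average per-gene correlation between matched bulk
transcriptomes and proteomes is on the order of 0.1. Proteins, however,
are what most drugs target, and proteomic profiling lags transcriptomics
in sample size by an order of magnitude. `transprot` implements a
cross-omics translation framework: it learns, from a modest set of
paired transcriptome-proteome samples, to predict per-sample protein
abundance from transcriptional features, and then supports the
downstream systems analyses that predicted proteomes enable — trait
association, input attribution, and proteome pseudotime with disease
staging.

## The translation model

The central assumption is that a protein's abundance is determined not
only by its own mRNA but also by the global tissue state (cell-type
composition, translational and degradation machinery), which is diffusely
encoded across the whole transcriptome. Each submodel therefore has two
blocks:

1. **Variational encoder-decoder.** One transcriptional layer (mRNA,
   pre-mRNA, or normalized 3'UTR length), reduced to either its 5000
   most-variable features or its top 100 principal components, is
   encoded by a feed-forward trunk into a latent Gaussian
   ($\mu$, $\log\sigma^2$, the log-variance clamped to $[-15, 15]$).
   During training the decoder receives the reparameterized draw
   $z = \mu + e^{\log\sigma^2/2}\varepsilon$; at inference it receives
   $\mu$, so predictions are deterministic. The decoder maps $z$ to one
   decoded value per protein.
2. **Per-protein linear merge.** The final prediction for protein $g$
   in sample $s$ is
   $\hat{y}_{s,g} = a_g d_{s,g} + \sum_f c_{g,f}\, x_{s,g,f} + \beta_{0,g}$,
   where $d$ is the decoded value and $x_{s,g,f}$ is the gene's *own*
   value in each configured transcript layer (z-scored with training
   statistics; genes missing from a layer contribute 0, i.e. the
   training mean). The merge keeps the central-dogma signal explicit
   while the encoder supplies the tissue-state context.

The loss is a masked mean squared error over observed protein cells on
the final merged prediction, plus a small KL penalty
($\tfrac12(e^{\log\sigma^2} + \mu^2 - 1 - \log\sigma^2)$ per unit,
weight 0.005). The loss attaches to the *merged* output because the two
learning rates of the optimizer — Adam at 0.001 for the encoder/decoder
group and 0.01 for the merge layer — only make sense under joint
end-to-end optimization; a decoder-level loss is available as
`loss_target = "decoded"`. Training holds out a seeded 10% validation
split, stops after 30 epochs (`patience`) without a validation
improvement of at least `min_delta` ($10^{-4}$ by default), and returns
the best-validation-epoch weights. The `min_delta` threshold is what
turns "no further improvement" into a testable stopping contract: on a
constant target the loss keeps shrinking geometrically forever, and only
a material-improvement threshold makes training halt.

Protein targets are z-scored per protein with training-split statistics
(inverted at prediction time), making the squared error comparable
across proteins. Unstated architectural constants — latent dimension 32,
two hidden layers of 800 units, batch size 64 — are configuration
defaults, not commitments; every benchmark in this package runs reduced
versions (see *Problem sizes* below).

**Ensemble.** Twelve submodels cross the three encoder sources with the
two encoder representations and two merge-input sets (`decoded + mrna +
premrna + utr` and `decoded + mrna`). Each member's predictions are
z-scored per protein with its own statistics and averaged with equal
weight. Member-level z-scoring before averaging is a design choice (the
convention is not fixed by the method description this grid
reconstructs); it prevents a member with larger output variance from
dominating the consensus.

**Out-of-fold evaluation.** Samples are split into ten folds, stratified
by diagnosis crossed with tertiles of global pathology. For each fold the
entire grid is trained on the remaining folds — including refitting the
encoder feature spaces on those samples only, so no held-out value can
influence feature selection — and the holdout predictions are z-scored
per protein within the fold before concatenation. Out-of-fold purity is
asserted at run time from the recorded training-sample sets.

## Attribution

Input contributions use expected gradients: the contribution of input
$i$ to target $g$ is the average over background samples $b$ of
$\int_0^1 \partial_i f_g(b + t(x-b))\,dt \cdot (x_i - b_i)$. Because
every network here is ReLU-activated, $f$ is piecewise linear along any
straight path, and the integral is computed *exactly* by splitting the
path at each hidden-unit sign change (located layer-by-layer by linear
interpolation) — local accuracy, the requirement that contributions sum
to the prediction minus the mean background prediction, then holds to
floating-point precision. The conventional stratified sampled estimator
(`method = "sampled"`, `n_draws` evaluations) is retained for reference
and converges to the same values. Merge inputs have constant per-protein
gradients, so their contributions are closed-form. Attribution is most
meaningful with principal-component encoder inputs, whose approximate
independence matches the attribution model.

Removing an input's contribution from the prediction
(`remove_input_contribution`) is additive and order-independent;
`variance_explained_delta` then reports how much of a trait's partial
R² (after covariate adjustment) each component carried.

## Synthetic data as ground truth

No controlled-access cohort data are used anywhere; two generators
provide ground truth instead.

`simulate_dataset()` draws a low-dimensional latent tissue state
(default 10 dimensions) shared by mRNA, pre-mRNA and 3'UTR layers
(per-coordinate gene loadings of sd 0.3, layer noise sds 1 / 1.3 / 1),
and builds proteins as
`coupling * mRNA + w . latent + b * diagnosis + noise` with coupling
drawn from N(0.1, 0.05²), protein-specific latent loadings totaling
about 1.5 variance units, phenotype effects from N(0, 0.3²) and noise
sd 0.6. These values were chosen once, analytically, so that the
population mean mRNA-protein correlation is near 0.10 — the low-coupling
regime in which translation is hard and the latent tissue state is
informative — and the closed-form correlation implied by the drawn
coefficients is the oracle the tests compare against. A planted 1-D
progression enters the first latent coordinate; clinical metadata
(amyloid, tau, cognitive impairment) are logistic curves of the true
pseudotime with slope 10 centered at milestones (0.2, 0.5, 0.8), which
guarantees unambiguous 25%-variation crossings. A seeded fraction of
genes has the UTR layer missing entirely (gene-level missingness), and
one master seed drives labelled sub-streams so every draw is independent
and reproducible.

`simulate_replicate_pair()` embodies the measurement-noise model
`p = b x + N(0, σ²)`: two replicate measurements share the phenotype
signal and differ by independent noise, so the expected replicate
correlation is `b²Var(x) / (b²Var(x) + σ²)` while per-protein effect
estimates stay concordant even under heavy noise.
`calibrate_noise_sd()` inverts the closed form to hit a target mean
correlation (0.20 in the benchmarks, the regime where abundance
replicates poorly but effects replicate well).

`simulate_progression_dataset()` is the trajectory bench: features
follow module-wise logistic trajectories of a planted pseudotime (one
direction per module — coexpression modules covary by definition; a
random per-feature sign would cancel in the module summary), plus a
non-monotone half-period hump module. A half period, not a full sine:
a full-period module gives the two ends of the progression identical
molecular values, closing the sample graph into a loop and breaking any
linear-trajectory method — a generator artifact, not a property of
disease progression. The low-rank `simulate_dataset()` output is *not*
used for trajectory benchmarks: with isotropic latent noise the unit-norm
Laplacian eigenvectors give the noise axis the same amplitude as the
signal axis, which defeats a principal path regardless of implementation.
What the passing trajectory tests show is therefore recovery of a
progression that dominates the molecular variance; they do not show
performance when the progression is a minor axis of variation.

## Trajectory and staging

Pseudotime follows the standard linear-trajectory recipe: top 40
centered PCs, k-nearest-neighbour graph (k = 10, Euclidean, union
symmetrization, binary weights — the symmetrization convention is a
design choice), spectral embedding by eigenvectors 2-3 of the symmetric
normalized Laplacian (degree-renormalized, per-axis sign fixed by the
largest-magnitude coordinate; disconnected graphs embed the largest
component and flag the rest), and a principal path: seeded k-means into
three clusters, centers ordered to minimize polyline length, midpoints
inserted, then iterative refinement moving each vertex toward the
weighted mean of samples projecting onto its adjacent segments with a
0.1 smoothing pull toward neighbouring vertices, to a 1e-6 movement
tolerance. Pseudotime is the arc-length projection, min-max normalized
to [0, 1]; orientation is arbitrary unless anchored by a reference
column (here: global pathology increases along pseudotime).

Module curves are LOESS fits (tricube local quadratics, span 0.75,
direct surface, 100-point grid). A module's milestone is the earliest
grid time its curve has moved 25% of its overall variation from its
starting value; clinical milestones are computed the same way from the
amyloid/tau/cognition curves, and stages follow by comparison (ties at
a milestone fall to the earlier stage). Monotonicity is judged by
counter-trend movement — the fraction of total absolute curve movement
that runs against the net direction — with tolerance 0.15. A
step-counting rule (fraction of sign-discordant grid steps) was
considered and rejected: LOESS fits of steep sigmoids wiggle in their
flat tails (many tiny discordant steps), while wide transitions have few
material steps; measured on the generator, monotone modules show
counter-movement of 0.01-0.09 against ~0.47 for a genuine hump, so 0.15
separates the two regimes with a wide margin. Because staging compares
crossing *orderings*, it is invariant to any monotone distortion of
pseudotime — which is exactly what an estimated pseudotime is.

Variance decomposition of cognitive decline over pseudotime and
demographics uses the LMG method: each predictor's sequential R² gain
averaged over all predictor orderings, computed from all-subsets R²
with combinatorial weights (hence the hard cap at 6 predictors).

## Statistics

Trait associations are per-feature OLS (`feature ~ trait + age + sex +
education` by default) with two-sided t tests and Bonferroni adjustment;
moderated (empirical-Bayes) statistics are deliberately not used — plain
OLS keeps the null calibration testable, and the package's own null
test demands a Kolmogorov-Smirnov distance below 0.05 from uniformity.
Concordance between analyses is the Pearson correlation of t-statistics
over shared features; the top-N validation experiment counts direction
matches and nominal replications among the N smallest discovery
p-values, against a chance baseline of (sign-match probability 1/2) x
(overall validation p < 0.05 fraction). Enrichment is the exact
hypergeometric upper tail with a Haldane-corrected sample odds ratio; the
universe is always an explicit argument. The correlation test used for
"positively concordant at FDR 5%" is one-sided by construction, with
Benjamini-Hochberg adjustment.

## Problem sizes used in the benchmarks

The packaged benchmarks are desk-scale by design:

* translation: 600 samples x 2000 genes x 500 proteins, latent
  dimension 10; submodels with 300 HVG / 50 PC inputs, one hidden layer
  of 32 units, latent 8, at most 100 epochs (patience 10) — the
  12-member grid out-of-fold over 10 folds;
* noise model: 400 samples x 1000 proteins, σ calibrated to a mean
  replicate correlation of 0.20;
* trajectory and staging: 500 samples, four 40-feature modules, ten
  independent seeds for staging.

These sizes make the full pipeline rerunnable in minutes on one CPU
while keeping every qualitative regime of interest (low mRNA-protein
coupling, noisy replicates, dominant progression). Architecture
reductions are configuration, not code: the defaults remain the
full-scale values.

## Known limitations

* The generators are linear-Gaussian (plus logistic clinical curves);
  they do not emulate read counts, isoform structure, batch effects, or
  TMT reporter chemistry, so passing tests demonstrate correctness of
  the machinery, not performance on real cohort data.
* Pseudotime requires the disease progression to be a dominant axis of
  molecular variation and assumes a linear (non-branching) topology.
* The LMG decomposition is exact but factorial; more than 6 predictors
  are refused rather than approximated.
* Training is full-precision CPU matrix algebra; it is intended for
  hundreds of samples and thousands of features, not for
  single-cell-scale inputs.
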