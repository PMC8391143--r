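---
title: "Voxel-wise encoding with sparse regression: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise encoding with sparse regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxelencode)
```

## The model

A *linearizing encoding model* predicts the response $y$ of a single fMRI
voxel from a nonlinear feature transform of the stimulus followed by a
linear map.  For a feature matrix $X$ ($m$ stimuli by $n$ features, with a
constant column appended last),

$$ y = X w + \varepsilon, $$

where $w$ is a weight vector of length $n + 1$ (the intercept stored as the
last coefficient) and $\varepsilon$ is noise.  One such regression is fit
per voxel *per feature layer*: the nonlinear transform is a hierarchy of
layer representations (in applications, the layers of a deep network; here,
by default, a seeded random ReLU cascade), and the layer whose model
predicts a voxel best is that voxel's *optimal feature layer*.  The layer
assignment is the scientific payload: visual areas early in the ventral
stream should prefer early layers, higher areas later layers.

Since $n \gg m$, each layer's features are first reduced by PCA (default
cap 1249 components, further limited by the layer width and by the rank
bound $m - 1$), and the per-voxel regression is solved sparsely.

## Regularized orthogonal matching pursuit

`fit_romp()` implements regularized orthogonal matching pursuit, a greedy
sparse solver.  Per iteration, with current residual $r$:

1. compute correlations $u = \tilde X^\top r$ against unit-norm centered
   columns (normalisation affects selection only; reported weights are on
   the original feature scale);
2. take the $s$ largest $|u_j|$ (zeros excluded), sort them decreasingly,
   and among all contiguous windows whose largest entry is at most twice
   the smallest, add the window with maximal energy $\sum u_j^2$ to the
   support (truncated so the support never exceeds $2s$);
3. refit all supported coefficients by least squares and update $r$.

Iteration stops when the support reaches $2s$ or the residual norm drops
below `tol * ||y||`.  The final support is the set of *nonzero* refit
coefficients: indices collected along the way whose exact least-squares
coefficient is numerically zero (below $10^{-10}$ of the largest) are
dropped, which is what "recovered support" means in the sparse-recovery
literature.  The intercept is recovered from the centering and stored as
the last weight.

Defaults are `sparsity = 20` and `tol = 1e-4`.  The sparsity level trades
signal capture against selectivity — wider supports let neighbouring
layers imitate a voxel's generating layer, while `s = 20` is ample for the
sparse readouts being recovered.  Degenerate targets (zero or
constant $y$) return an intercept-only model; missing values are an error.

## Layer selection and the winner's curse

`encode_study()` scores every layer by the Pearson correlation between
measured and predicted validation responses (`prediction_accuracy()`), and
`select_optimal_layer()` takes the argmax, ties to the lowest layer.  Two
ranking modes exist:

* `"validation"` (default): argmax of validation accuracy.  This mirrors
  how optimal layers are reported alongside validation accuracy in
  encoding studies, but with only 50 validation stimuli the accuracy
  estimates have a standard error near $1/\sqrt{47} \approx 0.15$ at
  $\rho = 0$, so the argmax is mildly optimistic (a winner's curse) and
  occasionally picks a neighbouring layer.
* `"cv"`: argmax of 5-fold cross-validated training accuracy
  (deterministic interleaved folds).  Leakage-free and more stable (the
  training split is 6 times larger), at five times the fitting cost.

Both modes recover generating layers well on the default synthetic study;
the validation mode is the default because the reporting conventions the
package follows describe validation-set behaviour.

## Significance, model comparison, and noise ceilings

**Randomization test.**  `randomization_threshold()` scrambles the
correspondence between measured and predicted responses (1000 permutations
per voxel by default) and recomputes $\rho$.  The default pools all null
values into a single global cutoff — the higher nearest-rank
$1-\alpha$ quantile at $\alpha = 0.001$ — because a single cutoff is how
such thresholds are usually quoted; a per-voxel mode is available.  The
permutation null of $\rho$ with $n$ validation samples has mean exactly 0
and variance close to $1/(n-1)$, so at $n = 50$ the $99.9$th percentile
lands near $3.1 \sqrt{1/49} \approx 0.44$; the acceptance script
recomputes this from scratch.  Zero-variance vectors get accuracy 0 and
can never pass the cutoff.

**Model advantage.**  For two models over the same voxels,
`model_advantage()` restricts to voxels accurately predicted by *both*
and reports the percentage each model predicts better, ties split 50/50 so
the fractions always sum to 100.  `advantage_permutation_threshold()`
flips each voxel's winner with probability 0.5 (1000 times) and returns
the $1-\alpha$ nearest-rank quantile of the null advantage in percent;
this agrees with the Binomial$(n, 1/2)$ quantile to within a percentage
point, e.g. about 53.7% at $n = 500$, $\alpha = 0.05$.

**Noise ceiling.**  `noise_ceiling()` estimates, per voxel, what accuracy
a perfect model could reach given measurement noise.  From the stack of
repeated validation runs: the noise variance is the pooled squared
standard error of the across-run mean (across-run variance over the
number of runs, averaged over stimuli — pooling over stimuli within a
voxel); the signal mean is the grand mean; the signal variance is the
variance over stimuli of the across-run mean minus the noise variance,
clipped at zero (estimates can go negative when noise dominates; the
clip is a deliberate choice).  1000 Gaussian simulations of signal and
signal-plus-noise are drawn and the ceiling is the median correlation.
This median tracks the closed form
$\sigma_s / \sqrt{\sigma_s^2 + \sigma_n^2}$ to within $\pm 0.02$.

## Representational similarity analysis

`compute_rdm()` builds $50 \times 50$ representational dissimilarity
matrices from correlation distances $1 - r$; brain RDMs use all voxels of
an ROI (no reliability mask, configurable) represented by the across-run
mean validation response, model RDMs use raw (unreduced) layer features.
`rdm_correlation()` compares RDMs by Kendall's $\tau_a$ over the strict
upper triangles — the conventional statistic when tied dissimilarities
are rare; it is computed from the C implementation of $\tau_b$ with an
exact tie correction, and verified in the tests against direct pair
counting.  `inter_subject_ceiling()` averages $\tau_a$ over all subject
pairs.

A caveat established by the package's own synthetic experiments: with few
voxels per ROI, the inter-subject ceiling is *not* an upper bound on
model-to-brain correlations.  Each subject's RDM is the shared layer
geometry plus a large idiosyncratic term from its particular voxel draw,
so two subjects agree like $r^2$ while a model layer correlates like $r$;
noise enters subject-subject comparisons twice but model-brain comparisons
once.  This asymmetry is exactly why ceiling-normalised RSA scores exist
(out of scope here), and it is why the reported `inter_subject_ceiling`
column should be read as a reference, not a bound, at small voxel counts.

## The synthetic-study generator

`make_study()` replaces the real stimulus set, pretrained network and fMRI
recordings with a fully seeded generative model whose ground truth is
recorded:

* **Features** (`make_layer_features()`): layer 1 is i.i.d. standard
  Gaussian; layer $\ell+1 = \mathrm{ReLU}(X_\ell A_\ell + b_\ell)$ with
  $A_\ell$ Gaussian scaled by $1/\sqrt{d}$ and $b_\ell \sim N(0, 0.5^2)$.
  Every layer is standardized (centered, unit variance) on training-split
  statistics.  Two conditioning choices matter: *centering* (without it
  the shared positive mode of ReLU outputs dominates the next layer's
  pre-activations and deep layers collapse), and the *bias scale* 0.5
  (pre-activations are roughly $N(b, 1)$, so larger bias spread creates
  units active on a handful of stimuli whose standardized columns are
  ill-conditioned spikes that derail greedy selection and explode on
  held-out stimuli).  Near-dead columns (training sd below $10^{-3}$) are
  centered but not rescaled.
* **Voxels** (`make_voxel_responses()`): each voxel draws a generating
  layer from its ROI's preference distribution, a support of `k_true = 10`
  feature columns, and Gaussian readout weights.  The clean response is
  standardized with training statistics, so `snr` has one meaning across
  layers: observed responses add Gaussian noise of sd `1/snr`, making
  cor(clean, observed) $= \mathrm{snr}/\sqrt{\mathrm{snr}^2+1}$ exactly in
  expectation.  Each of the repeated validation runs adds further
  independent noise of sd `run_noise_sd`.
* **ROIs** (`default_rois()`): seven regions (V1–V4, LOC, PPA, FFA) with
  Gaussian layer-preference bumps of spread $L/10$ whose centres move from
  early to late layers, emulating the LVC-to-HVC gradient.
* **Seeding**: child seeds derive from the master seed by a fixed counter
  scheme (features stream 1, subject $s$ × ROI $r$ stream $100s + r$), so
  adding a subject never perturbs earlier subjects.  Identical
  configurations are bit-identical.
* **Categories**: 150 training / 50 validation category labels are
  generated for schema fidelity but never used by the pipeline.

Default condition values follow the study design the pipeline targets
(1200 training and 50 validation stimuli, 18 layers, 35 runs, 5 subjects);
values the design leaves open were fixed once on realism grounds:
`k_true = 10` (sparse readouts), `snr = 2`, and `run_noise_sd = 4`, which
yields median noise ceilings around 0.8, typical of repeated-run fMRI.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: hemodynamics and temporal autocorrelation,
spatial correlation between voxels, retinotopic structure within ROIs,
non-Gaussian noise, stimulus-category structure in the features, and
trained-network feature statistics (the cascade is random; it has
hierarchy but no semantics).  Conclusions about real brains require real
features and recordings plugged in through the extractor registry and the
study container.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → reduce → encode → evaluate → RSA →
report, writes figure-shaped CSV tables (ROI accuracy summary, RSA
summary, advantage table, optimal-layer distributions, per-layer accuracy
curves) plus a provenance sidecar, and is byte-identical on reruns of the
same configuration.  The default two models are the study's own generating
features and a degraded copy with i.i.d. feature noise (sd 0.7) — a
controlled stand-in for comparing a stronger and a weaker feature model,
which exercises the advantage machinery with a known direction of effect.

The bundled default configuration is desk-scale: 5 subjects, 7 ROIs × 60
voxels, 8 layers × 200 features, 300 training / 50 validation stimuli, 35
runs, full 1000-permutation and 1000-simulation nulls.  A complete
two-model run takes a few minutes on one core; all sizes scale up through
`study_config()`.

```{r example}
config <- pipeline_config(seed = 1)
report <- run_pipeline(config, out_dir = "results")
report$tables$roi_summary
plot_layer_distribution(report$tables$layer_distribution)
```

## Numerical conventions

* Empirical quantiles are higher nearest-rank order statistics —
  conservative and exactly reproducible.
* PCA component signs are fixed (largest-magnitude loading positive) so
  downstream weights are reproducible; PCA is fit on the training split
  only, mean-centered without variance scaling.
* Argmax ties (layer selection, best RSA layer) break toward the lowest
  layer id.
* Zero-variance vectors yield correlation 0 with a warning rather than NA.
* All randomness flows through explicit seeds; helpers never disturb the
  caller's RNG state.

## Known limitations

* The inter-subject RSA ceiling caveat above.
* The pooled randomization cutoff assumes exchangeable voxels; strongly
  heterogeneous validation responses would argue for the per-voxel mode.
* ROMP has no theoretical recovery guarantee at the correlated designs PCA
  produces; empirically it recovers supports and layers well here, but a
  ridge or lasso baseline is a sensible robustness check (only a plain
  least-squares baseline is used in the tests).
* The study container stores matrices as CSV for portability; very large
  studies are better regenerated from their seed than stored.
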