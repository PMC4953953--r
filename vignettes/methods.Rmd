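---
title: "From scalp EEG to compact cortical regions of interest: the models behind eegroi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scalp EEG to compact cortical regions of interest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegroi)
```

## The problem

Scalp EEG mixes the activity of many cortical generators through the head's
volume conduction, so features computed channel by channel inherit poor
spatial specificity. `eegroi` implements a pipeline that first *images* the
cortical current distribution from the sensors, then restricts feature
extraction to a small set of spatially compact, data-driven regions of
interest (ROIs), and finally asks whether those ROI features discriminate a
binary affective state (for example low versus high valence on a 9-point
self-assessment scale) better than features taken straight from the
channels.

## Forward model and inverse solutions

The measurement model is the standard distributed-dipole linear model

$$X = MJ + \epsilon,$$

with $X \in \mathbb{R}^{C\times T}$ the sensor data, $J \in
\mathbb{R}^{D\times T}$ the amplitudes of $D$ dipoles fixed on a cortical
surface and oriented along its normals, $M$ the lead field, and Gaussian
sensor noise with covariance $Q_\epsilon$. Estimation penalizes a prior
Mahalanobis norm on the currents,

$$\hat J = \arg\min_J \; \|X - MJ\|^2_{Q_\epsilon}
  + \lambda \|J\|_{Q_J},$$

whose closed form $\hat J = Q_J M^\top (\lambda Q_\epsilon + M Q_J
M^\top)^{-1} X$ only ever solves a $C \times C$ system
(`solve_regularized()`).

Two priors are provided:

* **Smoothness prior (LORETA-style)** - `loreta_solve()` takes $Q_J = Q_G$,
  where $Q_G = \exp(\sigma G)$ is the matrix exponential of the scaled mesh
  graph Laplacian. $Q_G$ is a symmetric stochastic kernel whose columns are
  locally smooth cortical patches; $\sigma$ (default 0.6, dimensionless)
  controls their spatial extent - at 0.6 appreciable weight reaches vertices
  three to four edges from the center. The solution is spatially smooth and
  characteristically blurred.
* **Multiple sparse priors** - `msp_solve()` models the source covariance as
  a weighted sum of rank-1 patch components, $Q_J = \sum_p e^{\lambda_p}
  q_p q_p^\top$, with the patches $q_p$ being $Q_G$ columns at 512 centers
  spread by farthest-point sampling (`build_patch_dictionary()`), and
  $Q_\epsilon = e^{\lambda_\epsilon} I$. The weights are optimized by
  restricted maximum likelihood on the sensor sample covariance
  (`reml_optimize()`).

### Hyperparameter optimization

`reml_optimize()` ascends the Gaussian restricted likelihood with a
safeguarded scheme. Each iteration first evaluates a multiplicative
fixed-point candidate
$v_p \leftarrow v_p \,(u_p^\top\Sigma^{-1} C_y \Sigma^{-1}u_p)/(u_p^\top
\Sigma^{-1}u_p)$ (with $u_p = Mq_p$, $\Sigma$ the current model
covariance), which decays the weights of irrelevant components
geometrically. If that candidate would lower the objective, the iteration
falls back to the exact expectation-maximization update, whose posterior
moments guarantee ascent; the recorded objective trace is therefore
non-decreasing by construction. Pure EM alone was rejected because its
update shrinks irrelevant weights only hyperbolically ($v \sim 1/t$), so
no practical iteration count ever drives them to numerical zero.

Components are flagged *pruned* when their converged weight falls below
$10^{-3}$ of the largest weight. The converged weight spectra show a clear
gap - dominant components sit at $10^{-2}$ of the maximum or above, the
diffuse tail below $10^{-4}$ - so the threshold sits inside a wide valley
and the surviving set is insensitive to its exact value; components below
it contribute under 0.1% of the prior variance. Initialization is
scale-balanced: the noise weight starts at the smallest eigenvalue of
$C_y$ and all patch weights start equal with source and sensor model
covariances of equal trace. Defaults: `max_iter = 256` (convergence is
typically reached within about 50 iterations at `tol = 1e-6`).

## Region-of-interest selection

The source energy map is $\bar e_d = \frac{1}{T}\sum_t \hat J_{dt}^2$.
`select_rois()` implements greedy peak picking: dipoles below 10% of the
maximum energy are ineligible as centers; the highest-energy unlabeled
eligible dipole seeds the next ROI, which absorbs every unlabeled dipole
within geodesic radius $\rho$; the loop ends when no eligible dipole is
left, so the number of ROIs is set by the energy landscape, not by the
user. ROI time courses are the arithmetic means of member dipole currents.

Two readings of the 10% rule are possible for sub-threshold dipoles that
fall *inside* a selected radius: absorbing them (default) keeps regions
spatially solid; `strict_threshold = TRUE` leaves them unlabeled. Both are
implemented and tested; neither changes which dipoles may seed a region.
Ties in peak energy go to the lowest dipole index, which makes the greedy
loop deterministic. Distances are geodesic (shortest path along mesh edges
with Euclidean weights) rather than straight-line, so regions cannot leap
across folds of a non-convex surface. The radius default $\rho = 20$ mm
spans roughly three edges of the default mesh, giving compact multi-vertex
patches comparable to the smoothing scale of $Q_G$ at $\sigma = 0.6$.

## Feature set

`extract_signal_features()` returns 45 named statistics per signal, the
concatenation of four families, each summarized by max / mean / variance
per band or parameter:

| family | what is summarized | count |
|---|---|---|
| Welch PSD | band density in alpha, beta, gamma, delta | 12 |
| Hjorth | activity, mobility, complexity across short-time segments | 9 |
| Morlet CWT | instantaneous amplitude at 10, 20, 50, 2 Hz centers | 12 |
| db4 DWT | absolute detail signal per band-mapped dyadic level | 12 |

Choices that the band layout forces:

* Band edges are the standard clinical ones (delta 0.5-4, theta 4-8, alpha
  8-13, beta 13-30, gamma 30-Nyquist Hz); with 4 Hz high-passed input the
  delta block effectively captures low-theta content, and
  `spectral_bands(merge_delta_theta = TRUE)` merges the two lowest bands.
* Welch segments default to one second (`L = fs`), covering a full period
  of the 4 Hz analysis floor, with 50% overlap and a Hamming taper; the
  density is one-sided in units$^2$/Hz, so a unit-variance white signal
  integrates back to its variance (Parseval, tested to 10%).
* Hjorth mobility is implemented with the conventional square root,
  $\phi = \sqrt{\mathrm{var}(\dot v)/\mathrm{var}(v)}$, and complexity as
  the mobility ratio $\phi(\dot v)/\phi(v)$, because only this form gives
  the textbook calibration - mobility $2\pi f$ rad/s and complexity 1 for a
  pure $f$ Hz tone (tested to 2%). Derivatives are first differences
  scaled by `fs`. Segments reuse the Welch segmentation but not the taper,
  which would otherwise bias the variance ratios.
* The Morlet width is $\eta = 6$ cycles, the usual admissibility
  compromise; the 50 Hz (gamma) center survives at `fs = 128` (Nyquist
  64 Hz) and is dropped with a warning below `fs = 100`.
* The discrete transform uses Daubechies db4 filters with periodic
  boundaries, so the detail signals plus final approximation reconstruct
  the input exactly (tested to 1e-8). At `fs = 128` the level-to-band map
  is 1 → gamma, 2 → beta, 3 → alpha, and all levels centered below 4 Hz
  aggregate to delta; level 4 (4-8 Hz) belongs to theta and is unused by
  the four-band set. The map is configurable because dyadic bands can
  never match clinical edges exactly.

`build_feature_matrix()` concatenates the per-signal vectors into the
trial-by-feature matrix; with 32 channels that is $32 \times 45 = 1440$
columns per trial.

## Relevance ranking and evaluation

`pca_relevance()` standardizes features, takes the principal components
that reach 90% of total variance, and scores feature $j$ by
$\sum_{i\le k} |v_{ij}|\,\lambda_i$ - eigenvalue-weighted absolute
loadings, so features correlated with the dominant components rank first.
The decomposition runs through the SVD of the standardized data matrix, so
wide matrices (1440 features, 40 trials) never require a 1440 x 1440
eigenproblem.

`loo_evaluate()` is leave-one-out: standardization, relevance ranking,
feature selection (smallest prefix holding 90% of relevance mass) and the
RBF SVM (cost 1, $\gamma = 1/\#\text{features}$ on the standardized scale)
are all refit on the 39 retained trials of each fold, so the held-out
trial cannot leak into any fitted component (tested by tampering with the
held-out row). With only 40 trials per session no inner hyperparameter
search is attempted. Accuracy and F1 (positive class `high`) are reported
in percent; F1 is the robust summary under the class imbalance that
midpoint thresholding of ratings produces. Method comparisons across
sessions use a classical one-sided paired t-test; the degenerate all-zero
difference vector returns $t = 0$, $p = 0.5$ by symmetry, while any other
zero-variance difference vector is refused rather than silently assigned
a p-value.

## The synthetic study conditions

Because the pipeline must be testable without external recordings, the
package carries its own head model and data generator, which define the
study conditions used by the tests and the acceptance script:

* **Head model** (`make_head_model()`): an icosphere of radius 80 mm with
  `D = 642` radially oriented dipoles, unit-conductivity single-sphere
  dipole potentials, common-average referenced, and 32 sensors on a
  concentric sphere of radius 96 mm. The sensor lattice covers the *whole*
  sphere by default: the synthetic source space is a full sphere, and a
  hemispheric cap would leave the lower half of the sources essentially
  unobservable - an identifiability artifact of the spherical stand-in,
  not a property of real heads, where the cortex lies under the cap. A
  `montage = "cap"` option restores the upper-hemisphere geometry for
  experiments on exactly that effect.
* **Two-class sessions** (`simulate_emotion_dataset()`): 40 trials of 4 s
  at 128 Hz. Every trial contains a beta-band distractor patch (amplitude
  0.6) and two random background patches (amplitude 0.3, 4-30 Hz). Trials
  of the `high` class additionally drive one fixed target patch with an
  alpha oscillation whose per-trial amplitude is log-normal (median 1,
  log-sd 0.4), reflecting the roughly log-normal trial-to-trial
  variability of cortical oscillatory power; `low` trials lack the target
  patch entirely. Sensor noise is set to 5 dB total-power SNR. Ratings are
  drawn consistently with the class (6-9 versus 1-5) and binarized at the
  scale midpoint.

What the generator deliberately does **not** emulate: 1/f background
spectra, non-sinusoidal and non-stationary oscillations, correlated sensor
noise, artifacts (ocular, muscular), realistic folded cortical geometry
and BEM volume conduction, and rating noise near the midpoint. Passing
tests therefore demonstrate the algebraic and statistical correctness of
the pipeline and its qualitative behavior (sparse solutions are more focal
than smooth ones; ROI features preserve class structure), not performance
on real recordings.

## Problem sizes used by tests and the acceptance script

Module tests run on meshes of 42-162 vertices; the end-to-end studies use
the default 642-vertex model with 512 dictionary patches. The test suite's
paired study covers 20 sessions of 40 trials; the acceptance script runs
10 single-patch recovery sessions, 20 localization sessions and a
12-session end-to-end comparison. Trials are 4 s rather than the 60 s of a
typical music-video protocol; since features are short-time statistics,
longer trials mainly narrow their sampling variability.

## Numerical choices

* Sensor-space systems are solved symmetrically with a jitter rescue of
  $10^{-10}\,\mathrm{tr}(\Sigma)/C$; genuinely singular systems raise an
  error naming the condition number.
* The matrix exponential of the graph Laplacian is computed by symmetric
  eigendecomposition, which keeps $Q_G$ exactly symmetric; it is checked
  against an independent scaling-and-squaring implementation in the tests.
* Model covariance eigenvalues are floored at $10^{-12}$ of the largest
  before inversion.
* Farthest-point sampling starts deterministically at vertex 1 and breaks
  ties by lowest index, as does ROI peak picking.
* Ratings exactly at the midpoint 5 label `low`; the choice is arbitrary
  but fixed and documented.

## Known limitations

* The spherical geometry makes all lead-field columns of similar norm;
  depth-bias phenomena of realistic cortices are invisible here.
* LORETA's regularization parameter is exposed (`lam`) but not selected
  automatically; no L-curve or cross-validation helper is provided.
* Hyperparameters are optimized per trial; a per-session (`subject`) fit
  scope would share patch weights across trials and is not implemented.
* The DWT delta block aggregates levels below 4 Hz, which under-represents
  a 4 Hz high-pass regime exactly as any dyadic filter bank must.
* With 40 trials, leave-one-out accuracy has a granularity of 2.5
  percentage points; differences smaller than that are only detectable
  across many sessions. Under the default conditions both source-imaging
  arms classify well, and their mean accuracy difference is of the same
  order as that granularity: the packaged 20-session study finds the
  sparse arm ahead of the smoothness arm (one-sided paired test), but a
  different draw of sessions can reverse the sign of so small a margin.
  The *focality* contrast between the two priors - the smoothness prior's
  half-maximum support is several times larger - is robust in every run.
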