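---
title: "Encoding models for closed-loop virtual navigation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models for closed-loop virtual navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(navgam)
```

## The problem

In the "firefly" task a subject steers by joystick through a virtual
environment to the remembered location of a briefly flashed target, using
optic flow to path-integrate. No two trials are alike: trial durations,
trajectories, and gaze vary continuously, so classical trial-averaged tuning
curves are confounded. `navgam` models each unit's spike train directly as an
inhomogeneous Poisson process whose log rate is an additive combination of
smooth functions of task covariates:

$$\log \mu_t = \beta_0 + \sum_j f_j(x_{j,t}) + \sum_k (f_k * z_k)_t$$

where the $x_j$ are continuous covariates (linear/angular velocity and
acceleration, distance and angle from the origin and to the hidden target,
horizontal and vertical eye position, and the instantaneous LFP phase in the
theta, alpha, and beta bands), and the $z_k$ are point events (target onset,
movement onset/offset, reward, the unit's own spike history, and partner
units' spike trains) convolved with causal lag filters $f_k$. Counts are
binned at 6 ms with no baseline correction; all covariates are resampled to
the same grid. With all families present the model has 17 task inputs, plus
spike history and any coupling filters.

## Bases and penalties

Each $f_j$ is a cubic B-spline. Knots are placed at equi-probable quantiles
covering the 2nd to the 98th percentile of the covariate (15 knots by
default), so flexibility follows the sampling density. Values beyond the
knot span are clamped to the boundary before basis evaluation: the spline is
never extrapolated, and the fitted tuning is interpreted only over the
sampled range. LFP-phase terms use periodic B-splines on $(-\pi, \pi]$, so
tuning is continuous across the wrap point. Smoothness is enforced by the
curvature penalty $S_f = \int b'' b''^{\mathsf T}\,dx$, computed exactly by
per-interval Gauss--Legendre quadrature; its null space is the set of affine
tuning functions, so an infinitely-penalized term degenerates to a line, not
to zero.

Temporal filters live on a lag grid of the model bin width. Short filters
(36 ms: spike history and within-area coupling) use linearly spaced lag
knots; long filters (600 ms: across-area coupling, task events) use
log-spaced knots so that early lags get finer resolution. All filters are
strictly causal (lag $\geq 1$ bin); whether long cross-area filters should
also include negative lags is genuinely open, and we chose causal filters so
that a directed interpretation of coupling is coherent. Each basis block is
reparameterized against a sum-to-zero constraint over the observed data so
smooth terms are identifiable next to the intercept.

## Fitting and smoothness selection

The penalized Poisson log-likelihood is maximized by iteratively reweighted
least squares with step halving (the penalized problem is strictly concave
for positive smoothness scales; the objective is verified non-decreasing
across iterations). Smoothness scales $\lambda_f$ are chosen to minimize the
k-fold cross-validated held-out deviance; folds are contiguous trial blocks
rather than shuffled bins, because shuffled bins leak the strong temporal
autocorrelation of the covariates between train and validation sets. Each
term's penalty is normalized to unit mean diagonal so a single log-spaced
$\lambda$ grid serves all terms; selection does a shared-grid pass followed
by per-term coordinate passes, with the IRLS weights frozen between
refits (a standard performance iteration). Before any fitting, a seeded 20%
of trials is set aside; the cross-validated pseudo-R² is always reported on
those test trials. The only randomness in fitting is the seeded trial split;
everything else is deterministic.

Model quality is the Poisson pseudo-R²,
$1 - [L(y) - L(\hat y)]/[L(y) - L(\bar y)]$, with $L(y)$ the saturated
likelihood and $L(\bar y)$ a constant-rate null: 0 at the null model, 1 at a
perfect fit, negative on held-out data when overfitting occurs (such units
are excluded from population analyses).

## The inclusion test

A term is declared "tuned" when a Wald-type quadratic form on its
coefficient block rejects the null that the block is zero at $p < 0.01$. Two
design choices matter here, and both were made for calibration:

1. **Covariance.** The quadratic form uses the frequentist (sandwich)
   covariance of the penalized estimator, $V X^{\mathsf T} W X V$ with
   $V = (X^{\mathsf T} W X + S_\lambda)^{-1}$, not the Bayesian posterior
   covariance $V$. Under the null the penalized estimate of a zero block is
   unbiased (shrinking zero leaves zero), so the statistic referenced to a
   chi-square with the covariance's numerical rank is asymptotically
   calibrated; the Bayesian covariance overstates the variance of strongly
   shrunk directions and makes the test conservative.
2. **A lightly-penalized test fit.** p-values are computed on a parallel
   refit with a small common smoothness scale rather than on the
   CV-smoothed fit. The reason is subtle: CV-selected smoothing biases the
   *true* tuning functions, and because the task's covariates are strongly
   correlated (travelled distance integrates linear velocity; eye position
   tracks the target), that bias projects systematic signal into other
   terms' blocks and inflates their statistics. A zero block has no
   smoothing bias, so testing on a near-unpenalized fit removes the leak
   while the CV-smoothed fit is kept for tuning curves and prediction. In
   our null simulations this brings the empirical flag rate at
   $\alpha = 0.01$ from several percent down to the nominal range, at a
   small cost in power for weak terms.

The reduced model refits only the selected terms (smoothness scales kept);
on synthetic data its held-out pseudo-R² is indistinguishable from the full
model's, which is the property the reduction is meant to preserve.

## Behavioral analyses

Endpoints and targets are expressed in polar coordinates; trials where the
subject stopped within 0.5 m of the origin or never stopped within 7 s are
excluded. Bias is the slope of the no-intercept regression of response on
target (radial and angular separately): 1 is unbiased, below 1 undershoots.
Predicted gaze assumes fixation on the target center, projecting it into
per-eye visual angles with the eyes 0.1 m above the ground plane and a
3.5 cm interocular distance (vergence is negligible at task distances; the
value only matters for the binocular geometry to be well defined). The
target-tracking index is the square root of the rectified fraction of
variance in observed eye position explained by that prediction, computed
against the prediction directly with no fitted gain or offset -- an index of
1 means the gaze followed the target exactly, 0 means no correspondence.
Horizontal and vertical components are pooled within each eye before the
variance ratio and the index is averaged across eyes; a gain-fitting variant
is available behind a flag. The bimodality coefficient is Sarle's
skewness/kurtosis statistic with finite-sample correction, whose uniform
null is $5/9 \approx 0.556$ -- the reason this formula was chosen over
uncorrected variants.

## Population structure and coupling

Binary tuning profiles (17 indicators per unit) are clustered by spectral
clustering on the Jaccard-similarity graph, k-means on the row-normalized
leading eigenvectors of the normalized Laplacian (k = 7 by default; the
finding should be robust for k at or above 3, and a subsample-to-match
control repeats the clustering with areas subsampled to a common size).
Tuning *shapes* are z-scored per curve (so high-rate units do not dominate),
stacked, reduced by PCA to the smallest dimension explaining over 90% of
variance, embedded in 2D, and clustered by density. For the 2D step we use a
spectral neighborhood-preserving embedding (a Laplacian eigenmap on the
symmetrized kNN graph with heat-kernel weights); the density step is DBSCAN
with the neighborhood radius taken from the upper bend (90th percentile) of
the k-distance curve -- the geometric chord knee sits below the last dense
shelf when cluster densities differ and over-fragments clusters. Exact
duplicate shapes are collapsed before embedding and share their
representative's label, which keeps the pipeline equivariant. Both
clustering stages are seed-deterministic.

Coupling filters that pass the inclusion test define a directed graph.
Within-area coupling probability is corrected for electrode distance by a
penalized logistic spline $p(c{=}1) = \mathrm{logit}^{-1}(f(d))$ fitted per
area with the package's own spline machinery, reported at a 500 µm
reference distance; electrode distance is undefined across areas and never
used there. Session-level associations between area-pair coupling fractions
and the target-tracking index (averaged within trial, then across trials)
are ordinary least squares, reported raw and Bonferroni-corrected over the
3-by-3 sender/receiver grid. The default "coupling fraction" counts sender
units with at least one significant edge into the receiver area; an
edge-density variant is available.

## The synthetic session generator

The generator emulates the task's study conditions: targets uniform over
1--4 m and ±40°, 300 ms target visibility, joystick caps of 2 m/s and
90 deg/s, a 0.6 m reward boundary, inter-trial delays from a truncated
exponential (0.2--2 s, mean 0.5 s), and planted fractions of no-stop (13%)
and near-origin (5%) trials. Trajectories follow a smooth steering
controller: a quadratic Bezier arc from the start pose to the planned
endpoint with a raised-cosine speed profile, retimed whenever a speed cap
would bind -- this produces curvilinear, task-like paths whose endpoints are
exactly `gain x target + noise` (default gains 0.89 radial, 0.79 angular;
noise 40 cm and 5°). Gaze is the fixation prediction plus smooth AR(1)
drift, scaled per trial so the measured tracking index equals the requested
quality (independent white noise at quality 0). LFP phases advance at the
band-center frequency with phase diffusion. Spikes are Poisson draws from
the additive log-rate composition, generated sequentially in time so that
spike-history and coupling kernels have a causal ground truth (the inner
loop is compiled code).

Ground-truth tuning can be parametric (bumps, sigmoids, cosine phase
locking) or *spline-class*: a parametric shape projected onto the model's
own basis with the same equi-probable knot rule (`spline_truth()`). The
spline-class option makes the generated log rate lie exactly in the fitted
model family, which is what the selection-calibration benchmarks use --
with out-of-class truth, spline approximation error is real signal and
correlated covariates absorb it, so a calibration experiment would partly
measure approximation error rather than the test.

What the generator does **not** emulate: non-Poisson dispersion, slow
excitability drift, behavioral learning across a session, saccades (gaze
drifts smoothly), electrode drift, or spike-sorting contamination. Passing
the recovery and calibration suites therefore shows the estimator is
correct and calibrated *under the model's assumptions*; on real recordings
the additional variance sources will lower pseudo-R² and can inflate
false-positive tuning if strongly autocorrelated processes are omitted from
the model.

## Problem sizes and numerical choices

The validation suites run at desk scale, chosen to finish in minutes while
keeping each check statistically meaningful: tuning-shape recovery uses one
~30-minute, 10 Hz unit (about 300 trials; recovery criterion r > 0.95
against truth); selection calibration and reduction use an ensemble of 100
short sessions (24 trials each, 3 strong spline-class terms + 5 null terms,
10 knots per covariate); clustering recovery uses 600 units with 10%
bit-flip noise and 20 subsampling draws; coupling recovery uses 8
simultaneously recorded units with 3 planted kernels. Smoothness grids are
log-spaced over $10^{-3}$ to $10^5$ on the normalized-penalty scale. IRLS
converges at a relative penalized-likelihood change of $10^{-8}$; linear
systems carry a $10^{-7}$ ridge; log rates are clamped at $\pm 30$ before
exponentiation; Poisson entropy sums are truncated beyond the
$1 - 10^{-10}$ quantile with a safety margin. Mutual information is
reported in bits; the stimulus distribution defaults to the empirical pmf
with a moment-matched binomial behind a flag. LFP phase is resampled to the
model grid by unwrap-interpolate-rewrap at bin centers (a per-bin circular
mean is available behind a flag).

## Known limitations

The inclusion test is asymptotic: with very low-count terms (rare events,
near-silent units) its calibration degrades, and zero-spike units are
returned as flagged degenerate fits. Coupling estimation assumes partners
are simultaneously recorded and treats filters as constant within a
session. The distance-corrected coupling probability extrapolates poorly
beyond the sampled electrode distances. The 2D embedding preserves local
neighborhoods; between-cluster distances (and the centroid-ratio summary)
should be read as ordinal, not metric.
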