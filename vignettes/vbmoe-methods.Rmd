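---
title: "Bayesian mixtures of experts for sEMG force regression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian mixtures of experts for sEMG force regression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myoelectric control of dexterous prostheses needs two things at once from
the surface EMG (sEMG): *which* movement the user intends (classification)
and *how much* force to apply (proportional regression). `vbmoe` implements
a multivariate Bayesian mixture of experts (MoE) that delivers both from a
single model: Gaussian gates partition the sEMG feature space into movement
regions and double as an unsupervised classifier, while a linear regression
expert inside each region maps features to the multi-DoF fingertip forces.
Bayesian inference supplies predictive distributions — hence confidence
bounds on every force prediction — and an automatic choice of the number of
experts.

## Model

For a feature vector $x_n \in \mathbb{R}^{d_x}$ (one per analysis window)
and force vector $y_n \in \mathbb{R}^{d_y}$,

$$y_n = \sum_{i=1}^{M} g_i(x_n)\, W_i^\top [x_n; 1], \qquad
g_i(x) = \frac{\pi_i\, \mathcal{N}(x \mid \mu_i, \Lambda_i^{-1})}
              {\sum_l \pi_l\, \mathcal{N}(x \mid \mu_l, \Lambda_l^{-1})},$$

with expert noise $y_n \mid x_n, z_n{=}i \sim \mathcal{N}(W_i^\top[x_n;1],
\chi_i^{-1})$. The gating network is a Gaussian mixture over the *inputs*,
so the same object that routes the regression also clusters the windows
into movements. Conjugate priors make every variational update closed form:

* gates: Gaussian–Wishart on $(\mu_i, \Lambda_i)$ with hyperparameters
  $m_0$ (set per expert from a K-means partition), $\beta_0 = 0.01$,
  $B_0 = I$, $\nu_0 = d_x$;
* experts: matrix-Normal–Wishart on $(W_i, \chi_i)$ with $Q_0 = I$,
  $\lambda_0 = d_y$;
* ARD: each row $j$ of $W_i$ (each input channel, plus the bias) gets a
  Gamma$(c_0{=}0.01,\ d_0{=}10^{-4})$ precision $a_{ij}$. When the
  posterior precision expectation $c_i/d_{ij}$ grows large, channel $j$ is
  effectively switched off in expert $i$ — automatic relevance
  determination, the basis of the electrode-reduction analysis.

The mixing coefficients $\pi_i$ are point-estimated
($\pi_i = \tfrac1N \sum_n r_{ni}$). Surplus experts see their $\pi_i$
driven toward zero and are pruned when $\pi_i < 1/(2N)$ — supported by
less than half a data point — so the model selects its own complexity from
a deliberately generous initialization.

These hyperparameter values assume features standardized to zero mean and
unit variance; the preprocessing pipeline enforces that (see below).

## Variational inference and the lower bound

`moe_fit()` iterates the variational Bayes EM cycle: mixing update →
pruning → gate posteriors → expert posteriors → ARD posteriors →
responsibilities. Every step is exact coordinate ascent on one evidence
lower bound, which the package derives in the standard
conjugate-exponential form (expected complete-data log joint minus the
entropy of the variational posterior). The bound is computed every
iteration; it is the stopping criterion (relative change below `tol`,
default $10^{-6}$, or 200 iterations) and the model-selection criterion
across restarts. Because the bound formula is easy to get subtly wrong, the
test suite checks it three independent ways: per-update ascent (every one
of the five updates must not decrease it), a 20-seed monotonicity sweep,
and agreement to $10^{-6}$ relative with a from-scratch single-component
implementation.

### Numerical form of the updates

The textbook updates for $B_i^{-1}$ and $Q_i^{-1}$ subtract large,
nearly-equal outer-product matrices; as experts tighten, that cancellation
destroys the small residual scales and can collapse a noise covariance
entirely. The package therefore evaluates the algebraically identical
residual forms

$$B_i^{-1} = B_0^{-1} + \textstyle\sum_n r_{ni}(x_n - m_i)(x_n - m_i)^\top
  + \beta_0 (m_0 - m_i)(m_0 - m_i)^\top,$$
$$Q_i^{-1} = Q_0^{-1} + (Y - \tilde{X} \hat W_i)^\top V_i (Y - \tilde{X}
  \hat W_i) + \hat W_i^\top \Upsilon_i \hat W_i,$$

which are sums of positive-semidefinite terms. All densities are evaluated
in log space through Cholesky factors; responsibilities are normalized by
log-sum-exp (a row can never become NaN); symmetrization plus escalating
diagonal jitter guards the factorizations; an expert whose responsibility
mass falls below $10^{-10}$ keeps its prior until pruned.

### Initialization and restarts

Initialization is the one place where the package deviates from the naive
prescription, and deliberately. Drawing all responsibilities uniform on
$[0,1]$ looks random, but after row normalization every expert starts as an
almost identical copy of the population (the noise is $O(N^{-1/2})$ in the
expert means): on strongly clustered data every restart then relaxes into
the *same* local optimum, typically one that merges a pair of nearby
movements, and no number of restarts helps. We verified this directly —
seeding the responsibilities from the true movement labels reaches a
clearly higher bound than any uniform-init restart ever finds.

`moe_fit(init = "kmeans")` (the default) therefore seeds each restart's
responsibilities softly (weight 0.7) from a K-means partition of the
column-scaled **joint** $(X, Y)$ space. The joint space matters: two
movements can produce similar sEMG envelopes yet different force targets,
and each expert is a joint model of both. Restarts differ through the
K-means starting points and the soft noise, and routinely reach higher
final bounds — which is exactly the criterion the method itself prescribes
for choosing among runs. `init = "uniform"` retains the fully random
initialization. With either option, `m0` is set from the partition/K-means
centroids, one per initial expert, and all randomness flows from the
restart's seed (fits are bit-reproducible).

The number of initial experts should be generous: pruning can only remove
experts, never add them, and K-means tends to spend several centroids on
the diffuse rest cluster. For a protocol with nine movements plus rest we
initialize with 15 experts in the package's own benchmarks; the mixing
update prunes the surplus.

## Prediction, classification, uncertainty

At a query $x$, gates are evaluated at MAP estimates: the posterior means
$m_i$ and the Wishart posterior means $\nu_i B_i$ for the precisions (the
posterior mean is always defined, unlike the mode). The winning gate's
expert provides a multivariate Student-$t$ predictive with mean
$[x;1]^\top \hat W_i$, degrees of freedom $\kappa_i = \lambda_i - d_y + 1$
and covariance

$$\mathrm{cov}[y] = Q_i^{-1}\,\bigl(1 + [x;1]^\top L_i [x;1]\bigr) /
(\kappa_i - 2),$$

the exact matrix-$t$ marginal of the matrix-Normal–Wishart posterior; a
$10^5$-draw Monte-Carlo oracle in the test suite confirms both moments to
within sampling error. The $(1 + x^\top L x)$ factor inflates uncertainty
away from the training data. Per-DoF confidence intervals are Student-$t$
quantiles; `classify()` returns the arg-max gate (ties to the lowest
index), and `map_experts_to_movements()` converts unsupervised expert
indices into movement labels by training-set majority vote.

## Preprocessing pipeline

`prepare_dataset()` reproduces the standard protocol: split raw samples by
repetition id (default test repetitions 2 and 5), standardize the raw
channels with training statistics, extract windowed features per side (no
window straddles the train/test boundary), standardize the features (again
training statistics only), then thin the training rows at regular
intervals. Features are the classic low-dimensional time-domain set — MAV,
WL, RMS on 400 ms windows with 10 ms increments at 2 kHz — plus FILT, a
zero-phase 2 Hz second-order Butterworth envelope of the rectified signal
subsampled every 200 samples. Window labels follow the *last* sample of the
window (the causal choice; the alignment is otherwise a free convention).
The zero-phase filter initializes each pass at the steady state for a
constant input, so DC gain is exactly 1 and there is no start-up transient
— R's textbook `filtfilt` zero-padding would need thousands of padding
samples to achieve that at a 2 Hz cutoff.

## The synthetic generator

`make_ground_truth()` and its samplers exist so that every stage is
testable without any external recording. It mirrors the generative form of
the model itself: well-separated Gaussian clusters in feature space (means
drawn in a positive box with a minimum pairwise distance, default
separation 8 with unit-scale cluster covariances), one linear feature→force
map per movement, SPD noise covariances scaled by `noise_scale` (default
0.1). Rest is modeled as an explicit extra near-zero-force expert at the
origin, because a protocol's rest period is a state the gating must learn
like any movement. `sample_raw_semg()` additionally emulates the
*recording*: per-channel amplitude-modulated Gaussian noise whose RMS/MAV
envelope tracks the active cluster mean, raised-cosine on/off ramps, and a
protocol of 5 s movement blocks with 3 s rests repeated six times at 2 kHz
— the defaults reflect a realistic force-pattern acquisition. No
physiological motor-unit content is claimed: carriers are white, so
spectral features would be meaningless, and electrode shift, fatigue and
crosstalk are absent. Passing tests therefore demonstrate correct inference
under the model's own assumptions, not robustness to real-world
non-stationarity.

Transition windows — those overlapping a ramp — are genuinely ambiguous
(neither rest nor movement), exactly as in real recordings; they dominate
the misclassification budget, which is why evaluation also reports
center-segment accuracy (middle third of every movement block, rest
retained, remainders absorbed by the middle segment).

## Benchmark configuration

The package's own end-to-end benchmark (test suite and
`scripts/acceptance.R`) simulates the full 12-channel, 6-DoF protocol with
nine movements plus rest, extracts RMS features, and trains on repetitions
{1,3,4,6} thinned by a factor of 5 (about 5,800 windows), with 15 initial
experts. Two findings fixed those two numbers. At a factor-10 thinning
(about 2,900 windows) the evidence *correctly* trades one close movement
pair against the per-expert parameter cost and merges it — the bound
decomposition shows the per-expert KL is of the same order as the gate
evidence gained by splitting — so the denser training set is used, where
the split solution dominates. And 10 initial experts leave pruning no
slack, while 15 let K-means cover the rest cluster and every movement.
Smaller unit-test problems use 2–3 movements with a few hundred windows so
the whole suite stays fast.

## Sensitivity analysis for electrode reduction

`sensitivity_indices()` implements regression-based first-order indices
for *correlated* inputs: the contribution $V_j$ of channel $j$ (variance
of the fitted values of a regression of the predictive-mean output on
$x_j$) splits into an uncorrelated part $VU_j$ (the same regression on the
residual of $x_j$ after regressing it on all other channels) and a
correlated remainder $VC_j = V_j - VU_j$; shares $S_j = SU_j + SC_j$ are
reported per force DoF. Inputs are sampled by Latin hypercube with the
Iman–Conover rank shuffle so that both the training marginals (empirical
quantiles) and the training Spearman correlation are respected; the target
Spearman matrix is mapped to the normal-score Pearson scale by
$2\sin(\pi\rho/6)$. A spurious channel — influential only through its
correlation with informative ones — shows $SU_j \approx 0$ with
$SC_j \approx S_j$. The grouped variant regresses on a channel group
jointly (default grouping: forearm electrodes 1–8, finger extensor/flexor
9–10, upper arm 11–12); since the printed description of the grouping and
the electrode map disagree about the last pair, the package follows the
electrode map (biceps 11, triceps 12) and the grouping is configurable.
Because no closed-form reference exists in the source material, correctness
is validated against the analytic variance decomposition of a
Gaussian-linear system, where all three shares are available exactly.

## Known limitations

* Experts are linear; strongly nonlinear feature–force relationships
  within one movement are out of scope by design.
* Winner-takes-all gating makes the predictive mean piecewise-linear and
  discontinuous at gate boundaries; no soft mixture predictive is offered.
* The lower bound is a local criterion: restarts mitigate but cannot
  guarantee escape from merged-expert optima; the joint-space seeding is a
  heuristic, not a proof.
* The synthetic generator does not model electrode shift, fatigue, motor
  unit dynamics, or between-subject variability; conclusions about real
  sEMG transfer only to the extent those factors are secondary.
* NinaPro-dialect data is accepted as an in-memory structure
  (`as_session()`); MATLAB files must be converted to the TSV session
  format first.
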