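---
title: "Decision-fusion gait recognition: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-fusion gait recognition: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfuse)
```

## The problem

Optical motion-capture systems track reflective markers on a walking person
with millimeter precision. Given short recordings (a few gait cycles at
5 Hz) of ten lower-body markers — thigh, shank, two ankle positions and
tiptoe on each side — the task is to identify which of $N$ enrolled
subjects is walking. Two facts shape the method:

* each *single* frame already carries identity information (body segment
  proportions show up in inter-marker distances, walking speed in marker
  velocities), but a single frame is noisy;
* a recording supplies many frames, so per-frame decisions can be *fused*,
  and frames should not contribute equally — a frame whose soft decision
  disagrees with most others is probably corrupted and deserves less
  weight.

`gaitfuse` implements the resulting first-classify-then-fuse pipeline:
feature extraction, unreliable-feature calibration, single-frame
classification with a kernel extreme learning machine (KELM), and
reliability-weighted-sum (RWS) fusion of the per-frame fuzzy decisions,
plus five reference fusion rules.

## Data model and features

A `gait_trajectory` holds an ordered $T \times 10 \times 3$ array of marker
positions in meters, the subject label, and the sampling interval $\tau$
(default $0.2$ s, i.e. 5 Hz). From frame $t$ the package extracts

* the $\binom{10}{2} = 45$ pairwise Euclidean marker distances
  $d_{i,j}^t = \lVert p_i^t - p_j^t \rVert$, flattened from the strict
  upper triangle in row-major order ($d_{1,2}, d_{1,3}, \dots, d_{9,10}$);
* the 10 forward-difference walking-axis velocities
  $v_i^t = (x_i^{t+1} - x_i^t)/\tau$ (signed).

The last frame has no forward difference, so a $T$-frame recording yields
$T-1$ feature rows of length 55. Distances are invariant to rigid motion
of the whole marker set; velocities only to translation. Any fixed
flattening order would do; what matters is that training and test use the
same one. Because distances (meters, order $10^{-1}$) and velocities
(m/s, order $10^0$) live on different scales, features are z-scored with
mean and sample (n−1) standard deviation fitted **on the training split
only**; zero-variance columns get scale 1 and map to zero.

Calibration operates on *raw* features and normalization afterwards: the
tail bounds below are interpretable on the physical scale (meters, m/s),
and the normalizer is then fitted on the calibrated matrix so the
classifier never sees values the calibrator would have flagged.

## Unreliable-feature calibration

Sensing failures displace single markers and inflate individual features.
Rather than deleting frames (the other features of the frame are still
informative), the package clamps outliers per feature. On the pooled
training values $z_1,\dots,z_L$ of one feature:

1. a Gaussian kernel density estimate with bandwidth
   $\rho = \sigma \left( \tfrac{4}{3L} \right)^{1/5}$ (Silverman's rule,
   sample standard deviation $\sigma$) yields the smooth CDF
   $\Phi(z) = \tfrac1L \sum_i \Phi_{\mathcal N}\!\big(\tfrac{z - z_i}{\rho}\big)$;
2. the tail threshold $P_{th}$ (default 0.999) is converted once into
   fixed bounds $z_{ub} = \Phi^{-1}(P_{th})$,
   $z_{lb} = \Phi^{-1}(1 - P_{th})$ by bisection on
   $[\min z - 5\rho,\; \max z + 5\rho]$ (a proper CDF always brackets);
3. any value outside $[z_{lb}, z_{ub}]$ — training or test, the bounds are
   never refitted on test data — is replaced by the violated bound
   (`strategy = "clamp"`, idempotent) or by the training mean
   (`strategy = "mean"`).

A design note: a literal radial-basis kernel $\exp(-|z - z_i|^2/\rho)$
without normalization, integrated "from 0", is not a proper density, so
the package uses the standard normalized Gaussian KDE with standard
deviation $\rho$ and a CDF from $-\infty$. Only the quantiles enter the
procedure, so this choice affects nothing but well-definedness. On smooth
unimodal features the flagged fraction is $\approx 2(1 - P_{th})$ by
construction, which the tests check by Monte Carlo; constant (degenerate)
features are left uncalibrated. Bounds are fitted per feature on the
pooled training split — one density per feature, not per subject.

## Single-frame classification: kernel ELM

The KELM is a kernel ridge classifier trained in one closed-form solve.
With training features $Z$ (rows $z_i$), the RBF Gram matrix is
$K_{i,j} = \exp(-\lVert z_i - z_j \rVert^2 / h)$, and class labels are
one-vs-rest coded in $C \in \{\pm1\}^{n \times N}$ (+1 in the true-class
column). The output weights solve

$$\beta = \left(K + \tfrac{1}{\lambda} I\right)^{-1} C,$$

computed by Cholesky factorization of the symmetric positive-definite
system (machine-precision accurate; never an explicit inverse). A new
frame scores $o^t = k(z^t, Z)\,\beta$, one real value per class, and the
hard decision is the arg-max (ties to the lowest class index). As
$\lambda \to \infty$ training outputs interpolate $C$; the tests assert
$\max |o - C| < 10^{-3}$ at $\lambda = 10^9$.

Defaults are $h = 2^3$ and $\lambda = 10^4$, with the conventional search
grids $h \in 2^{-9..9}$, $\lambda \in 10^{-9..9}$. Both parameters should
be set by validation trials for a given population; see below.

## From outputs to fuzzy decisions

Fusion needs commensurable soft decisions, so outputs are mapped to
memberships

$$\mu_i^t = \exp\!\left( -\left( \frac{o_i^t}{\bar o + \gamma\,
\sigma(o^t)} \right)^{\!2} \right) \in (0, 1],$$

with $\bar o$ the mean, $\sigma$ the sample standard deviation of $o^t$,
and $\gamma = 0.5$ by default ($\gamma$ widens the membership spread).
This exact reading — sample (n−1) standard deviation, squared ratio — is
pinned by a worked five-class example reproduced to four decimals in the
test suite. Two consequences are worth knowing:

* for a constant output vector the formula forces all memberships to
  $e^{-1}$; if $\bar o + \gamma\sigma = 0$ exactly the package warns and
  returns equal memberships;
* the map is even in $o_i$: outputs $+c$ and $-c$ receive the same
  membership. With one-vs-rest $\pm1$ coding the output mean is negative,
  so moderately positive true-class outputs land closest to zero and win —
  but outputs that overshoot far past $+1$ (which happens in the
  near-interpolation regime $\lambda \gg 1$ on easily separated data) get
  *small* memberships. This is a property of the published transformation
  and is deliberately not "fixed"; it is the reason parameter selection
  scores the membership pathway (below).

## RWS fusion

Given memberships $\mu^1,\dots,\mu^T$ for the frames of one recording:

1. **Consistency matrix** $A_{t,k} = \langle \mu^t, \mu^k \rangle$ — the
   belief-theoretic consistency degree reduces to the inner product when
   all focal elements are singletons. $A$ is symmetric, nonnegative and
   positive semidefinite (a Gram matrix), and if $\mu^1 \succeq \mu^2$
   elementwise then $\langle\mu^1,\mu\rangle \ge \langle\mu^2,\mu\rangle$
   for any $\mu \succeq 0$; both are property-tested.
2. **Reliabilities**: the unit-norm principal eigenvector $w$ of $A$
   (nonnegative orientation, which exists by Perron–Frobenius) scores each
   frame's agreement with the rest; it is rescaled affinely to
   $r_t = a + b\,(w_t - w_{\min})/(w_{\max} - w_{\min}) \in [a, a+b]$.
   The package default is $a = 0.6$, $b = 0.4$. If all $w_t$ coincide
   (mutually identical frames) every $r_t = a + b$: identical frames are
   maximally mutually consistent. The bundled worked example
   (`toy_fuzzy_decisions()`) is tabulated with $a = 0.3$, $b = 0.7$, and
   the examples and tests use those bounds when reproducing it digit for
   digit.
3. **Global decision**: $\mu_g = \tfrac1T \sum_t r_t\,\mu^t$, winner by
   arg-max (ties to the lowest index). For $T = 1$ the reliability
   defaults to $a + b$.

Five baselines are provided for comparison: sum, product
($\prod_t(\mu_i^t + \delta)$), majority vote (hard per-frame votes; vote
ties resolved by larger average membership, then lowest index), belief
($\prod_t 1/(1 - \mu_i^t + \delta)$) and reliability-weighted belief
($\prod_t 1/(1 - r_t \mu_i^t + \delta)$), with $\delta = 10^{-3}$. The
RWS winner is invariant to frame order and to scaling all memberships by
a common positive constant; the $\delta$-floored product/belief rules are
not scale-invariant, and the tests assert exactly that split.

## The synthetic gait simulator

The real capture campaign behind this method is not public, so the
package ships a generator whose outputs play the role of study data. Each
subject draws anthropometric and gait parameters once: height uniform on
1.44–1.78 m, thigh/shank/foot lengths as standard fractions of height
(24.5%, 24.6%, 15.2%; hip height 53%) with ±4–5% individual variation,
gait frequency uniform on 0.8–1.2 Hz, stride length ∝ height (speed =
stride × frequency), plus swing/knee-flexion amplitudes, a phase offset
and a lateral hip half-width. A recording is planar two-link forward
kinematics: hips advance along x at walking speed, thigh angles follow
antiphase sinusoids, knees flex once per cycle, and the five per-side
markers sit at fixed positions along the segments. I.i.d. Gaussian noise
(default σ = 2 mm, optical-capture jitter) corrupts every coordinate;
sensing failures are emulated by displacing random marker-frames by a
fixed magnitude along a random axis (`inject_outliers()`). Everything is
deterministic given a seed, down to byte-identical CSV files.

What the simulator does **not** model: soft-tissue artifact, 3-D joint
constraints, double-support foot-ground interaction, marker-placement
variability between sessions, or the idiosyncratic style differences that
make real gait biometric. Subjects here are separable mainly through
segment geometry and speed. Passing benchmarks on this generator
therefore demonstrates that the pipeline's machinery is correct and that
fusion behaves as the theory predicts — not that any particular accuracy
will transfer to real captures.

## Evaluation design and problem sizes

The bundled benchmark follows the protocol the method targets: 10
subjects, one training recording of 121 frames and one test recording of
61 frames each (≈ 2:1 train:test feature rows), noise σ = 2 mm.
`fusion_accuracy_curve()` fuses the leading $\lceil \rho T \rceil$
feature frames of each test recording at ratios 0.1–1.0 for all six rules
(contiguous leading frames; a seeded random-subset mode exists). Two
companion experiments:

* **Accuracy versus fused-frame count** uses σ = 10 mm — a deliberately
  noisy capture scenario in which single frames are fallible — so the
  monotone benefit of fusing more frames is visible rather than saturated
  at 100%.
* **Calibration benefit** injects outliers (probability 0.02 per
  marker-frame, 0.3 m displacement) into both splits over ten seeds and
  compares mean single-frame accuracy with clamping on versus off.

Because the synthetic subjects are easily separated, KELM parameters are
chosen by the prescribed validation trials rather than taken from the
defaults: `select_kelm_params()` holds out the trailing quarter of each
training recording and scores each $(h, \lambda)$ grid point by the
accuracy of the *membership* arg-max on the held-out frames. Scoring the
membership pathway (not the hard output decisions) matters: in the
near-interpolation regime the outputs overshoot $\pm 1$, hard decisions
stay accurate, but the even membership map collapses — and fusion
consumes memberships. The selected models keep outputs conservative, and
fused accuracy then dominates single-frame accuracy for every rule.

## Numerical choices and degenerate inputs

* Bound-finding uses `uniroot` at tolerance `.Machine$double.eps^0.5` on
  a bracket that always contains both quantiles.
* The KELM solve is a Cholesky factorization; the system is positive
  definite for any finite $\lambda > 0$.
* Eigen-decomposition of $A$ uses the symmetric path; the principal
  eigenvector is sign-fixed to the nonnegative orientation. Ties among
  top eigenvalues cannot occur for strictly positive $A$.
* All arg-max tie-breaks go to the lowest class index, deterministically.
* Degenerate cases: constant features are skipped by calibration;
  zero-variance normalizer columns get scale 1; `w_max = w_min` sets all
  reliabilities to $a+b$; $T = 1$ fuses trivially; a degenerate
  membership scale warns and returns equal memberships.

## Known limitations

* The membership transformation's evenness means a wildly overconfident
  classifier (outputs far beyond +1) degrades fusion; use the provided
  validation selection, or stronger regularization, when the base task is
  nearly separable.
* Calibration is univariate; a failure that shifts several features
  jointly but each within bounds passes through.
* The simulator's planar kinematics cannot certify real-world accuracy;
  it certifies the algorithmic claims (consistency weighting, fusion
  monotonicity, calibration behavior) under controlled conditions.

## A worked fusion example

```{r toy}
mu <- toy_fuzzy_decisions()
round(consistency_matrix(mu)[1:3, 1:3], 2)
g <- rws_fuse(mu, a = 0.3, b = 0.7)
round(g$reliabilities$r, 2)
g
```

Frames 1, 3 and 6 (whose arg-max is not class 2) receive the smallest
reliabilities, and the fused decision recovers class 2.
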