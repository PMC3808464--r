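---
title: "Granger causality with signal-dependent noise: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger causality with signal-dependent noise: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdngc)
```

## The problem

Classical Granger causality asks whether the past of one time series
improves the prediction of another beyond the latter's own past, and
operationalizes the question with vector autoregressions whose
innovation covariance is constant in time.  Many biological recordings
violate that assumption: cortical spike counts are near-Poisson, so
their variance grows with their mean, and the same coupling between
first- and second-order statistics survives the hemodynamic transform
into the fMRI BOLD signal — the variance of the unpredictable part of a
BOLD trial grows approximately linearly with the *square* of its
predictable part.  A causal analysis that ignores this both loses power
(influences carried by the variance are invisible to a constant-variance
model) and risks distorted inference (heteroskedastic residuals violate
the classical test's assumptions).

`sdngc` implements an autoregressive model whose conditional covariance
is a quadratic function of the lagged process, a likelihood-ratio test
for directed influence in mean *and* variance under that model, and the
simulation and diagnostic machinery needed to validate both.

## The AR-BEKK process

The `k`-dimensional process is

$$x_t = \sum_{i=1}^{p} A_i x_{t-i} + H_t^{1/2}\,\epsilon_t, \qquad
  H_t = W + \sum_{j=1}^{q} B_j\, x_{t-j} x_{t-j}^{\top} B_j^{\top},$$

with $\epsilon_t$ i.i.d. standard Gaussian.  The volatility recursion is
a BEKK form driven by the lagged *process values* rather than the
residuals: the noise covariance is thereby an explicit quadratic
function of the signal, and it is positive definite by construction
($W$ is kept positive definite through its Cholesky factor).  Setting
every $B_j = 0$ recovers the Gaussian VAR exactly — simulation,
likelihood and both tests then reduce to their classical counterparts,
which the test suite checks numerically.

Two stability conditions govern the model:

* **first order** — the companion matrix of $\{A_i\}$ has spectral
  radius below one (the mean recursion is stable);
* **second order** — for the first-order model ($p = q = 1$), the
  stationary second moment $S$ obeys the linear fixed point
  $\mathrm{vec}(S) = (A_1\!\otimes\!A_1 + B_1\!\otimes\!B_1)\,
  \mathrm{vec}(S) + \mathrm{vec}(W)$, which has a positive definite
  solution exactly when that operator's spectral radius is below one.

`first_order_stable()`, `second_order_stable()` and
`stationary_second_moment()` expose these, and `simulate()` refuses
unstable models unless explicitly overridden.  A scalar model gives the
closed form $S = w/(1 - a^2 - b^2)$, which serves as a simulation
oracle throughout the tests.  Mean orders $p > 1$ are supported through
the companion embedding; the second-order condition and all causal
testing are restricted to $p = q = 1$, the regime appropriate for the
slow sampling of BOLD data.

### The joint model and causality

For a pair of blocks $(x, y)$ the joint model stacks the state but
keeps the two innovation processes independent, so the joint
conditional covariance is block-diagonal: block $x$ is driven by its
volatility rows $B^{(x)}$ applied to the *joint* lagged state, and
likewise for $y$.  The source text leaves the partitioned covariance
ambiguous; we adopt the block-diagonal reading because the two noise
processes are declared independent, and we carry the same structure
into the second-moment operator (the cross-block rows of
$\tilde B \otimes \tilde B$ are projected out).  "$y$ does not cause
$x$" means: the $y$-columns of the $x$-rows of every $A_i$ *and* the
$y$-columns of every $B^{(x)}_j$ vanish.  A directed influence can
therefore act on the target's mean, its noise variance, or both.

## Estimation

The conditional log-likelihood conditions on the first $\max(p, q)$
observations of every trial — identically in full and restricted fits,
so likelihoods are comparable across nested models — and sums the
Gaussian conditional log-densities over all trials (trials are treated
as independent realizations of one model, which is how pooled
multi-subject fMRI trials are analyzed).

Starting values follow the standard two-stage recipe: $A$ from
per-equation ordinary least squares, then, per channel, the squared AR
residuals are regressed on the squared lagged values; the intercept
(floored at $10^{-6}$) initializes the baseline variance and the square
root of the clipped slope initializes the diagonal of $B$.
Off-diagonal volatility entries start at zero.

The constrained optimization is a penalized quasi-Newton scheme:

* $W$ enters through the log of its Cholesky diagonal, so positive
  definiteness costs no constraint;
* both spectral radii enter as smooth quadratic penalties with margin
  $10^{-6}$ (weight $10^{6}$), active only outside the stable region —
  on stable data the optimum is interior and the penalty never binds;
* BFGS (relative tolerance $10^{-12}$, 500 iterations) is the primary
  method, with a Nelder–Mead simplex restart as fallback, and a final
  guard that shrinks coefficients just inside the stable region should
  an optimum sit on the boundary;
* a fit can never end below its starting point: if no candidate
  improves on the initial value, the initial model is returned with
  `converged = FALSE`.

Because the joint likelihood separates over the two blocks
(block-diagonal covariance, independent innovations), `fit_joint_arbekk()`
optimizes each block's equation independently — a 5-parameter problem
per scalar block instead of a 10-parameter joint one — and re-runs a
jointly penalized fit only in the rare case that the assembled model
violates stability.  The volatility surface is multimodal in the
cross-coefficients (only the linear combination entering the squared
term is observed, and rows are identified only up to sign — we fix the
sign by making the own-channel entry nonnegative).  Unrestricted fits
therefore use several starts: the least-squares start, cross-volatility
perturbations of either sign, and, inside the causality test, a warm
start at the restricted optimum.  The warm start guarantees the nested
inequality $\ln L_{\text{full}} \ge \ln L_{\text{restr}}$ up to
optimizer round-off.

## Causal inference

`sdn_gc()` forms $G = 2(\ln L_{\text{full}} - \ln L_{\text{restr}})$
and refers it to $\chi^2_{(p+q)\,k_x k_y}$ — the degrees of freedom
count the zeroed coefficients (2 for a scalar pair at $p = q = 1$).
The restricted model is the *zero-constrained joint* model, not the
marginal model, so the two likelihoods live on the same sample space
and nest properly.  The df choice is validated empirically: under the
null (independent AR-BEKK series, 400 replicates at the study scale)
the rejection rate at $\alpha = 0.05$ falls inside the binomial 95%
band and the p-values pass a Kolmogorov–Smirnov uniformity check at
distance < 0.1.

`classical_gc()` is the Gaussian VAR baseline, fitted by pooled least
squares; it reports both the likelihood-ratio statistic and Geweke's
measure $F = \ln(\det\Sigma_r/\det\Sigma_f)$, with $G = nF$ exactly.

`difference_test()` addresses a different question — is the influence
in one direction *stronger* than in the other?  The difference of two
independent $\chi^2_{\nu}$ variables has the symmetric variance-gamma
density

$$f(d) = \frac{(1/2)^{\nu}}{\sqrt{\pi}\,\Gamma(\nu/2)}\,
  |d|^{(\nu-1)/2} K_{(\nu-1)/2}(|d|/2),$$

with $K$ the modified Bessel function of the second kind;
`difference_cdf()` integrates it numerically (CDF(0) is exactly 1/2 by
symmetry) and is cross-checked against the closed form at $\nu = 2$
(a Laplace law with scale 2, so $P(|D|>d) = e^{-d/2}$) and against
$10^6$ simulated differences.  Note that at $\nu = 2$ a difference of
4.61 corresponds to a two-sided tail of about 0.10, not 0.01
($4.61 = -2\ln 0.1$); both the degrees of freedom and the level are
therefore explicit arguments, never hard-coded.

`pair_table()` runs a chosen test over every ordered pair of regions,
Bonferroni-corrects over the number of directed tests actually run,
and attaches the difference test per unordered pair, using the
row-to-column convention of the field's connectivity tables.
Non-convergent fits are flagged in the report, never dropped silently.

## Diagnostics for signal-dependent noise

The empirical definitions deliberately avoid the parametric model: the
*signal* at time $t$ is the projection of $x_t$ onto a subspace spanned
by functions of its past, the *noise* is the projection residual, and
the noise variance at a within-trial time point is the variance of the
residuals across trials.  Three projection families are provided —
linear lags, second-order polynomials of the lags, and order-1..6
Fourier pairs of range-normalized lags ("sixth-order Fourier" is
under-specified in the source; this is our reading) — with default lag
sweeps of 9, 6 and 2 respectively.  `sdn_correlation()` then tests for
a (by default Pearson, since the relation of interest is linear)
correlation between the per-time mean squared signal and the
across-trial noise variance.

Two facts about power are worth stating plainly, because they shaped
the test suite:

* On *stationary* panels the within-trial profile of both quantities is
  flat in expectation; the correlation is carried only by shared
  sampling fluctuations, and it does **not** grow with the number of
  trials (both the signal and the noise of the comparison shrink at the
  same $1/\sqrt{n}$ rate).  Significance then comes from the number of
  within-trial time points; the unit tests use 100-point trials with
  trial-locked onset transients (no burn-in, zero initial state), which
  is also the structure real trial data have.
* The across-trial variance estimator carries irreducible
  $\chi^2$-type sampling noise, so even for data simulated from the
  fitted model class the correlation between empirical and model-based
  noise variance (`model_concordance()`) plateaus well below one
  (typically 0.3–0.6 at 100 trials of 25 points) while the signal
  concordance sits near 1.  The tests assert exactly that pattern.

BOLD-like panels are different: the stimulus-locked response makes the
squared-signal profile strongly nonstationary, and the diagnostic is
then sharp — the packaged BOLD simulation detects the effect at
$p < 0.01$ with a single default panel.

## The BOLD illustration

`simulate_bold_trials()` shows how signal-dependent noise *arises*:
Poisson spike trains (count variance equal to the count mean) drive the
balloon-model state equations — vasodilatory signal $s$, inflow $f$,
volume $v$ and deoxyhemoglobin $q$, with
$E(f, E_0) = 1-(1-E_0)^{1/f}$ — and the BOLD readout
$y = V_0\{k_1(1-q) + k_2(1-q/v) + k_3(1-v)\}$.  Trial-to-trial count
variability scales with the rate, so the across-trial variance of the
response tracks its squared mean.  Defaults: 100 trials, a 1-s spike
burst at 5/40/80 Hz, 25 s integrated at 1 ms by explicit Euler
(a fourth-order Runge–Kutta option exists for convergence checks;
halving the Euler step moves the trace by well under 0.1%), decimated
to 1 Hz by plain subsampling.  The biophysical constants are canonical
literature values for a 1.5-T readout
($\tau_s = 0.8$ s, $\tau_f = 0.4$ s, $\tau_0 = 1.0$ s, $\alpha = 0.32$,
$E_0 = 0.34$, $V_0 = 0.02$, $k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0-0.2$),
all overridable; the neuronal efficacy (0.5 per spike per bin) sets an
overall response scale that none of the qualitative claims depend on.
Only ordering, sign and significance statements are made about this
module — the exact constants behind any particular published figure are
not recoverable.

## Preprocessing

Trials destined for causal analysis are denoised with a Daubechies-2
maximal-overlap discrete wavelet transform (circular boundary, exact
reconstruction — the transform is unit-tested to machine precision),
soft-thresholded at the universal threshold
$\lambda = \hat\sigma\sqrt{2\ln N}$ with
$\hat\sigma = \mathrm{median}(|W_1|)/0.6745$ estimated once from the
first-level details, then linearly detrended and centered.  The
shift-invariant transform was chosen over a decimated one because it is
defined for any trial length and avoids alignment artifacts at the
short lengths typical of fMRI trials (16 samples at a 2-s repetition
time is the package default for synthetic trials); hard thresholding
and a no-denoise path are available.  Decomposition depth defaults to
$\lfloor\log_2 N\rfloor - 1$.  Numerical agreement with any particular
proprietary wavelet routine is not claimed; the denoise–detrend–center
chain is validated functionally (variance shrinkage on pure noise,
idempotence, preservation of a planted causal effect).

## Synthetic studies and their scope

`run_roc_study()` reproduces the methodology benchmark: random
scalar-pair models whose directed links exist independently with
probability 0.4, simulated at 1000 points with 2 replicate trials, both
tests applied in both directions, performance summarized by ROC/AUC.
Where the source left coefficient distributions unreadable we fixed
them once: diagonal mean and volatility coefficients uniform on
(0.3, 0.7), present mean cross-couplings uniform on (0.1, 0.5),
volatility cross-coupling 1 scaled down by factors of 0.9 under
rejection until both stability conditions hold.  A `variance_only` mode
(links act on the variance alone) isolates the regime where the
classical test is structurally blind; there the SDN test's AUC exceeds
the classical AUC by a wide margin (the acceptance run asserts > 0.1
with 30 models).

`synth_fmri_panel()` generates the stand-in for the four-region,
two-condition attention study: 12 subjects × 9 trials (108 pooled
trials per condition) of 16 samples at 2 s over OFC, AntINS, AntLPFC
and PostLPFC, from a four-node AR-BEKK network whose planted links
differ by condition (PostLPFC→AntINS under attention to intensity;
AntLPFC→OFC, PostLPFC→OFC and AntINS→OFC under attention to
pleasantness).  The planted graphs are deliberately confound-free
(sources are mutually independent), so the pairwise tests' ground truth
equals the adjacency; couplings default to 0.3 (mean) and 0.5
(volatility) on top of 0.5/0.4 diagonals, all stable by construction.
This panel validates the *pipeline* — it makes no claim of reproducing
any particular empirical connectivity values, which would require the
original recordings.

## Problem sizes and seeds

All randomness flows through explicit integer seeds, and every
simulation-backed assertion states its scale: the stationary-moment
check uses $10^5$ points with batch-means Monte-Carlo error; null
calibration uses 400 replicates of 2 × 1000 points; the ROC acceptance
run uses 30 models; recovery uses 20 models at 2 × 1000 points; the
difference-distribution oracle uses $10^6$ draws per df; the synthetic
four-region study uses 10 seeds each for the strong-effect and null
settings.  These sizes were chosen so the full validation runs on a
single CPU in minutes while leaving every binomial/Monte-Carlo margin
comfortably wide.

## Known limitations

* Joint fitting (and hence `sdn_gc`) is implemented for univariate
  blocks at $p = q = 1$; multivariate blocks are modeled and simulated
  but not fitted, and conditional (partial) causality over more than
  two simultaneous blocks is out of scope.
* The $\chi^2$ null of the likelihood-ratio test is asymptotic;
  panels much shorter than the ~1600 pooled observations exercised
  here may need calibration.
* Parameter counts grow quadratically with dimension; the model is not
  intended for large region sets.
* Standard errors of the fitted coefficients are not provided; the
  package's inferential object is the likelihood-ratio test.
* The diagnostics' power caveats on stationary panels are described
  above.
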