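---
title: "Error calibration for serial crystallography: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error calibration for serial crystallography: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxcal)
```

## The problem

A serial crystallography (SX) data set is assembled from thousands of
still shots, each contributing the diffraction of one small crystal (a
*lattice*). After indexing, integration and scaling, every observation of
a symmetry-reduced Miller index $h$ carries an intensity $I_{hk}$ and a
counting-statistics sigma $\sigma_{hk}$. Counting statistics are a *lower
bound* on the real measurement error: they know nothing about scaling
residuals, partiality, beam jitter or detector miscalibration. Because
the missing error sources cannot be enumerated, the field calibrates
empirically — it finds a transformation of $\sigma_{hk}$ that explains
the observed spread of redundant measurements. The calibrated sigmas then
drive inverse-variance weighted merging (the maximum-likelihood mean) and
everything downstream that consumes uncertainties.

`sxcal` implements two calibrations operating on already-scaled,
symmetry-reduced observations:

* **Ev11** (baseline): the classic three-parameter transform
  $\sigma'_{hk} = s_{\mathrm{fac}}\,[\sigma_{hk}^2 + s_B \langle I_h\rangle
  + s_{\mathrm{add}}^2 \langle I_h\rangle^2]^{1/2}$, fitted so that
  normalized leave-one-out deviations have unit RMS within intensity bins.
* **MM24** (robust, per-lattice): removes $s_B$, makes the additional
  error lattice-specific through the correlation $cc_l$ of each lattice to
  a scaling reference, and replaces the moment-matching target with a
  maximum-likelihood fit to normalized pairwise differences under a
  half-normal or half-t kernel.

## The Ev11 target

For each observation in a group of multiplicity $n \ge 2$, the
leave-one-out residual $I_{hk} - \langle I_h\rangle_{\neq k}$ has modeled
variance $\sigma'^2_{hk} + \sum_{j \ne k} \sigma'^2_{hj}/(n-1)^2$
(variances add linearly; the second term is the variance of the mean of
the other $n-1$ observations without assuming they share a common
variance value). The normalized deviation $\delta_{hk}$ divides the
residual by the square root of that variance; at correct calibration its
RMS is one. Note an asymmetry that matters in the implementation: the
*residual* uses the leave-one-out mean, while $\langle I_h\rangle$ inside
the sigma transform is the plain all-in mean — the transform is a
function of the group, not of the held-out observation.

Miller groups are binned by $\langle I_h\rangle$ into 100 bins evenly
spaced from the minimum to the maximum mean intensity; assignment is
half-open on the left edge with the last bin closed, so both extremes are
binned. The loss is $\sum_b \sqrt{m_b}\,(\mathrm{RMS}_b(\delta) - 1)^2$,
with $m_b$ counting observations. The square-root weight is the midpoint
between weighting bins equally ($w_b = 1$) and weighting observations
equally ($w_b = m_b$). Empty bins contribute nothing. Optimization is
bounded quasi-Newton (L-BFGS-B) with analytic gradients, verified against
central finite differences in the test suite. $s_{\mathrm{fac}}$ starts
at the overall RMS of $\delta$ computed at the identity transform,
$s_B = 0$, $s_{\mathrm{add}} = 0.01$; bounds are
$s_{\mathrm{fac}} \in [10^{-3}, 10^{3}]$, $s_B \in [-10^3, 10^3]$
intensity units, $s_{\mathrm{add}} \in [0, 10]$. When a trial $s_B$
pushes the variance bracket non-positive the objective returns a large
smooth penalty with a matching gradient rather than `Inf`, which L-BFGS-B
cannot digest.

## The MM24 model

### Per-lattice additional error

$s_{\mathrm{add}}(cc_l) = s_{\mathrm{add},0} + s_{\mathrm{add},1}
\exp(-s_{\mathrm{add},2}\, cc_l)$. The exponential form keeps the curve
positive and monotonically decreasing in $cc_l$ for non-negative
coefficients, and collapses to a constant when $s_{\mathrm{add},1} = 0$
(recovering an Ev11-like global behavior). A polynomial could cross zero
and divide the likelihood by zero; the exponential cannot. The form lives
behind `s_add_of_cc()` so it can be swapped without touching the fit.

### Pairwise differences and the likelihood

For two observations of the same Miller index,
$\omega_{hjk} = |I_{hj} - I_{hk}| / (\sigma'^2_{hj} +
\sigma'^2_{hk})^{1/2}$: uncertainties add in quadrature, no mean estimate
is needed, and the statistic is symmetric by construction — three
assumptions fewer than the deviation route. At correct calibration and
normal errors, $\omega$ is half-normal with unit scale. The fitted loss
is the negative log-likelihood *of the pairwise differences themselves*:
each pair contributes $-\log p(\omega) + \tfrac12 \log(\sigma'^2_{hj} +
\sigma'^2_{hk})$, the second term being the change-of-variable factor
from the normalized statistic back to the measured difference. That term
is essential: without it the objective decreases monotonically as sigmas
inflate and has no finite minimizer. The kernel $p$ is either the
half-normal or the half-t,
$$p(\omega;\nu) = \frac{2\,\Gamma\!\left(\frac{\nu+1}{2}\right)}
{\sqrt{\nu\pi}\,\Gamma\!\left(\frac{\nu}{2}\right)}
\left(1 + \frac{\omega^2}{\nu}\right)^{-(\nu+1)/2},$$
computed in log space via `lgamma`. $\nu = 1$ is the half-Cauchy;
$\nu \to \infty$ recovers the half-normal. Heavy tails make the fit
resistant to outlier lattices: a gross outlier contributes
$O(\log \omega)$ to the half-t loss instead of $O(\omega^2)$.

### Deterministic subsampling

All pairs of a deep Miller group are too many ($O(n^2)$), so at most 100
pairs per group (the `cap`) are drawn without replacement from the
canonical lexicographic pair enumeration. Reproducibility across runs and
across any partitioning of the data is guaranteed by seeding a fresh
generator per group with a Cantor-pairing seed:
$\pi(\kappa_1,\kappa_2) = (\kappa_1+\kappa_2)(\kappa_1+\kappa_2+1)/2 +
\kappa_2$ applied iteratively to the index components shifted by $+1000$,
plus an optional user offset. The generator is pinned (Mersenne-Twister,
inversion normals, rejection sampling) so the draw is identical across
platforms and R versions, and the caller's RNG state is saved and
restored around every internal draw. For the seeding to be well defined
the table must have a *total* canonical order; observations are sorted by
(h, k, l, lattice id, intensity, sigma) — value tie-breaks, not input
position, so any row permutation of the same data produces bit-identical
pair sets. Subsampled parameters: `cap = 100` and `extra_offset = 0` by
default.

### Initialization

If two observations share true intensity and error SD
$\sigma_{\mathrm{err}}$, their difference is normal with SD
$\sqrt2\,\sigma_{\mathrm{err}}$, so the *mean absolute* difference is
$(2/\sqrt\pi)\,\sigma_{\mathrm{err}}$. `initialize_mm24()` computes mean
raw pairwise differences in 100 even intensity bins spanning $[0,\,
0.1\max\langle I_h\rangle]$ (zero lower edge for numerical stability
under the square root; the 0.1 factor reflects that the bulk of
intensities sits an order of magnitude below the maximum) and fits
$(s_{\mathrm{fac}}, s_{\mathrm{add},1})$ by least squares against
$(2/\sqrt\pi)\,s_{\mathrm{fac}}[\langle\sigma^2\rangle_b +
s_{\mathrm{add},1}^2 I_b^2]^{1/2}$ with $I_b$ the bin centers.
$s_{\mathrm{add},0}$ and $s_{\mathrm{add},2}$ start at 0.001. The first
non-empty bin — the expected nonzero error of low-intensity reflections —
anchors the *starting* $s_{\mathrm{fac}}$ through the half-normal mean
relation at $I \approx 0$. We deliberately did not add the anchor as a
fixed additive constant in the least-squares model: on data whose
counting sigma is flat in intensity, an additive constant equal to the
first bin's mean absorbs the entire signal and drives the fitted
$s_{\mathrm{fac}}$ toward zero, which defeats the initializer's purpose
(and fails parameter-recovery checks). With fewer than three usable bins
the initializer falls back to $(1.0, 0.05)$ with a warning.

### Optimization

$(s_{\mathrm{fac}}, s_{\mathrm{add},0}, s_{\mathrm{add},1},
s_{\mathrm{add},2})$ and, for the half-t kernel, $\nu$ are optimized by
L-BFGS-B with analytic gradients (including the digamma terms for $\nu$).
Bounds: $s_{\mathrm{fac}} \in [10^{-3}, 10^3]$, $s_{\mathrm{add},0},
s_{\mathrm{add},1} \in [0, 10]$, $s_{\mathrm{add},2} \in [0, 50]$,
$\nu \in [1.5, 200]$, with $\nu$ parameterized on a log scale for
conditioning. On data with genuinely normal errors the fitted $\nu$ runs
into its upper bound — that is the expected signature of "no heavy tails
detected", not a failure. $\nu$ starts at 10, comfortably inside the
range of values typically fitted on experimental SX data (roughly 4–10).

## Merging and statistics

`merge_reflections()` implements inverse-variance weighting
($I_h = \sum w I / \sum w$, $w = 1/\sigma'^2$, merged sigma
$(\sum w)^{-1/2}$) and the unweighted mean with standard-error sigma.
CC$_{1/2}$ splits each group into two random halves with the same
deterministic per-group seeding machinery (an odd group's extra
observation is placed by the same RNG — parity-based splits would be
biased by input ordering), merges each half, and correlates the two
half-sets, overall and in resolution shells. Resolution shells are
equal-volume in $1/d^3$. The correlation outlier filter removes lattices
with $cc_l$ below a threshold; the default threshold of $-1$ disables it
(removing lattices costs real signal; 0.1 is the conventional choice when
low-quality data are suspected). No other outlier rejection is applied at
merge time.

## Diagnostics

**Second moments.** For acentric Wilson intensities
($\rho(Z) = e^{-Z}$, $Z = I/\Sigma$ with $\Sigma$ the shell mean) the
second moment $\langle Z^2\rangle / \langle Z\rangle^2$ is exactly 2.
Gaussian measurement error of normalized SD $\sigma_Z$ turns the observed
marginal into an exponentially modified Gaussian with mean 1 and variance
$1 + \sigma_Z^2$, so the expected second moment is
$2 + \langle\sigma_Z^2\rangle$ per shell (mean of squares: the
variance-consistent aggregate). Observed above expected means
under-estimated sigmas; observed *below* two at high resolution is the
signature of background under-estimation during integration. The implementation is acentric-only; centric
populations need a different reference and are out of scope. No outlier
rejection or anisotropic correction precedes the calculation here —
numbers will differ from pipelines that apply them. An optional MAD-based
Z filter is available but off by default and is not equivalent to those
procedures.

**Rankits.** Calibration statistics are sorted and paired with expected
order statistics of the half-normal or half-t reference at Blom plotting
positions $(i - 0.375)/(n + 0.25)$ (exact order-statistic means cost
$O(n^2)$ and change nothing visible). Correct calibration gives a line
through the origin with slope one; heavy tails bend the upper end
upward against a half-normal reference.

## The synthetic generator

`simulate_experiment()` mirrors the generative assumptions exactly: true
intensities are exponential with mean $\Sigma(d) = \mathrm{scale}\cdot
\exp(-B/2d^2)$ on Miller indices drawn from a real unit-cell grid inside
the resolution window; counting sigma is the Poisson-motivated
$[\max(I_h, \mathrm{floor}) + \mathrm{background}]^{1/2}/\mathrm{gain}$
(the floor prevents degenerate sigmas near $I = 0$); each observation's
error SD is $s_{\mathrm{fac}}[\sigma^2 + s_{\mathrm{add}}(cc_l)^2
I_h^2]^{1/2}$ with noise drawn normal or SD-standardized t. Defaults are
the calibration study conditions: $s_{\mathrm{fac}} = 1.2$,
$s_{\mathrm{add},0} = 0.01$, $s_{\mathrm{add},1} = 0.15$,
$s_{\mathrm{add},2} = 2.0$, cubic 79 Å cell, 1.8–20 Å window, Wilson
scale 1000 and $B = 20$ Å$^2$, multiplicity Poisson with mean 6 floored
at 1, lattice correlations uniform on $[0.2, 0.95]$.

One subtlety is deliberately resolved in favor of model conformance: the
lattice record stores the *generating* $cc_l$ — the value fed through the
$s_{\mathrm{add}}(cc)$ law — rather than the correlation re-measured
against the truth. Measuring it after the fact is circular (the noise
level depends on the score being measured), and the stored value is what
makes "the empirical variance equals $\sigma_{\mathrm{err}}^2$ in every
$(\langle I\rangle, cc)$ cell" hold exactly. The realized correlation is
kept in the ground truth, and is monotone in the latent quality; at the
default (mild) error levels that monotonicity is statistically invisible
because every lattice correlates with the truth at $\approx 0.99$, so the
test of this construction property uses a strong-error configuration
where the ordering is resolvable. A mis-specified power-law quality map
is available for robustness studies.

What the generator does **not** emulate: partiality, per-image scale
error, detector gain structure, spatial correlations, centric
reflections, or non-exponential intensity populations (twinning,
pseudo-symmetry). Passing recovery tests therefore demonstrates
correctness of the estimators under their own assumptions, not
performance on real XFEL data.

## Numerical and testing choices

* Problem sizes: the recovery checks run at $\sim 10^5$ observations
  (15000 groups, mean multiplicity 7), where both fits complete in
  seconds; distributional checks use $10^5$–$5\times10^5$ draws with
  $3\sigma$ Monte-Carlo tolerances computed from the relevant moments
  (e.g. $\mathrm{Var}(Z^2) = 20$ for unit exponentials).
* The Kolmogorov–Smirnov self-consistency check uses one pair per Miller
  group: pairs sharing an observation are dependent, and feeding
  dependent values to a KS test inflates the statistic and rejects a
  correct fit.
* TSV floats are written with 17 significant digits, making
  write-read round trips lossless.
* All likelihood math is in log space; no direct `gamma()` calls.
* Bin assignment conventions (half-open, last bin closed) are fixed and
  tested at the boundaries.

## Known limitations

* Input must be scaled and symmetry-reduced upstream; no space-group
  machinery, partiality or absorption corrections are included.
* MTZ files are not read directly; the native format is the TSV dialect
  described in `read_unmerged_table()`.
* The Ev11 $s_B$ term can make the variance bracket non-positive for
  extreme parameters; the optimizer is steered away smoothly, but final
  parameters should be checked against the bracket on new data.
* Merged sigmas receive no post-merge rescaling; consumers who expect a
  SCALEPACK-style error inflation must apply their own.
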