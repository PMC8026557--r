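---
title: "Voigt lineshapes: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voigt lineshapes: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voigtline)
```

## The model

The Voigt profile is the convolution of a unit-area Gaussian of 1/e
half-width $\omega_G'$ with a unit-area Lorentzian of half-width at half
maximum $\omega_L$. In reduced coordinates $v = (x - x_0)/\omega_G'$ it
depends on a single shape parameter, the line-damping parameter
$\xi = \omega_L/\omega_G'$:

$$V(v,\xi) = \frac{1}{\pi}\int_0^\infty e^{-\xi y - y^2/4}\cos(v y)\,dy .$$

Throughout the package this cosine-transform form is the single source of
truth for normalization: its $\xi = 0$ limit is exactly
$e^{-v^2}/\sqrt{\pi}$, which integrates to one, and every other evaluator
is calibrated against it. Two printed conventions had to be resolved
numerically against this anchor:

* the complex-function representation $V = \mathrm{Re}\,W(v + i\xi)$ holds
  up to scale; the calibrated identity is
  $\mathrm{Re}\,W(v+i\xi) = \sqrt{\pi}\,V(v,\xi)$ (at $v=\xi=0$, $W=1$
  while $V = 1/\sqrt{\pi}$);
* in the series representation the sum's coefficient is $2\xi/\pi$ inside
  an overall $1/\sqrt{\pi}$, i.e. $2\xi/\pi^{3/2}$ in total — the same
  constant as the intermediate-range Lorentzian-dominance sum, which is
  just that series without its correction term. Both calibrations are
  pinned by tests against the quadrature oracle and against
  $V(0,\xi) = e^{\xi^2}\mathrm{erfc}(\xi)/\sqrt{\pi}$.

The assumptions behind using this profile on data are modest but worth
stating: the distribution is symmetric about a single mode (per
component), the Gaussian and Lorentzian broadening mechanisms are
independent (so they convolve), and mixture components are additive.
Skewed profiles are out of scope.

## Exact evaluation

`voigt_series()` evaluates the exact theta-like series

$$V(v,\xi) = \frac{e^{-v^2}}{\sqrt{\pi}}\,e^{\xi^2}\cos(2\xi v)
\left[1-\coth(2\pi\xi)\right] + \frac{2\xi}{\pi^{3/2}}
\sum_{n=-\infty}^{\infty}\frac{e^{-(v-n/2)^2}}{n^2+4\xi^2}.$$

Three numerical hazards are handled structurally:

* **Term combination.** Each summand is evaluated as
  $e^{-(v \mp n/2)^2}$ rather than $e^{-v^2-n^2/4}\cosh(nv)$; the latter
  overflows once $|nv| \gtrsim 700$. The paired form is also exactly even
  in $v$, so symmetry holds to the last bit.
* **Truncation.** Terms are kept while the Gaussian envelope exceeds the
  tolerance, $N = \lceil 2(|v| + \sqrt{-\ln(\mathrm{tol}/100)})\rceil + 4$
  — about 30 terms on the usual grids.
* **Small-$\xi$ cancellation.** The correction term and the $n=0$ summand
  both diverge like $1/\xi$ as $\xi \to 0$ and cancel. Instead of a
  switch to the Gaussian below some threshold, the two are recombined
  algebraically: with $g(\xi) = \coth(2\pi\xi) - 1/(2\pi\xi)$ (series form
  below $2\pi\xi = 10^{-2}$) and
  $h = \mathrm{expm1}(\xi^2)\cos(2\xi v) - 2\sin^2(\xi v)$, the combined
  head term is $\frac{e^{-v^2}}{\sqrt{\pi}}[e^{\xi^2}\cos(2\xi v)(1-g) -
  h/(2\pi\xi)]$, stable all the way to $\xi = 0$. This removes the usual
  fallback-threshold tuning entirely.

The series has a genuine validity ceiling: its correction term grows like
$e^{\xi^2 - 4\pi\xi}$, so beyond $\xi \approx 4\pi$ the printed formula
diverges from the true profile, and the error is already $\sim 10^{-8}$
at $\xi = 11$. `voigt_series()` documents the supported domain
$\xi \le 10$ (absolute error below $10^{-11}$ there, verified against the
oracle); the front end `voigt(..., method = "auto")` uses the series up to
$\xi = 8$ and switches to the Faddeeva route beyond, and also hands points
with $|v| > 30$ to that route so the series never builds needlessly long
term tables for stray far-tail abscissas.

`faddeeva_w()` implements Weideman's rational approximation of
$W(z)$ for $\mathrm{Im}\,z \ge 0$ (FFT-derived coefficients, order 64,
cached). It contains no large intermediate exponentials, behaves correctly
for large $|z|$ by construction, and is the independent second route used
in tests (its anchors come from `pracma`'s scaled complementary error
function, which the series path never calls). The Dawson function is read
off its imaginary part on the real axis.

`voigt_oracle()` is the slow, trusted reference: adaptive quadrature of
the cosine form on $[0,\ 2(\xi + \sqrt{-\ln 10^{-18}})]$, splitting at
half-periods of $\cos(vy)$ when $|v|$ is large; the Gaussian–Lorentzian
convolution form and the $y \to y/\xi$ substituted form are available as
cross-checks.

### Limiting approximations

The printed Gaussian-dominance forms (near the maximum; the second also
requires $\xi \ll 1$) and Lorentzian-dominance forms (intermediate range
$\xi \ge 1$; far tail $\xi \gg 1$) are implemented verbatim, with their
qualitative regimes turned into a committed, machine-checked error-bound
table (`inst/extdata/approx_error_bounds.csv`): for instance the
near-maximum form stays within $1.5\times10^{-4}$ relative of the oracle
for $|v| \le 0.3$ at $\xi = 0.3$, and the far-tail form within
$6.5\times10^{-3}$ at $\xi = 10$ over $|v| \le 5\xi$. The test suite
re-measures these errors on every run. Out-of-regime evaluation is
permitted and flagged via an `in_regime` attribute rather than blocked.
`voigt_regime()` exposes the regime-router logic (thresholds 0.3 and 1 as
configurable defaults) for studying the approximations; the fitting
engines deliberately do *not* use it — they call the exact evaluator,
because percent-level approximation bias would contaminate fitted $\xi$
at no computational saving.

## Variance

The full profile has $1/v^2$ tails for every $\xi > 0$, so its variance
is divergent; `variance_full()` returns an explicit infinite sentinel with
a finiteness flag rather than a floating overflow, reserving the finite
value $1/2$ for $\xi = 0$. The closed-form variances of the two
Gaussian-dominance profiles are finite (their $e^{-v^2}$ envelope is kept
everywhere): both tend to $1/2$ as $\xi \to 0$ via `expm1`-stabilized
limit forms, the near-maximum one turns to growth past $\xi \approx 3$ as
the shape becomes Lorentzian, and the small-$\xi$ one decays at large
$\xi$ only because it is then outside its validity region.

One quantitative caveat the tests document: the two formulas agree only
in the $\xi \to 0$ limit, not over an extended plateau. Their difference
grows like $0.38\,\xi$ — the first-order contribution of the $v^2, v^4$
polynomial corrections that only the near-maximum form retains — so they
are within $10^{-4}$ of each other only for $\xi \lesssim 2.6\times
10^{-4}$ (at $\xi = 0.005$ the gap is already $1.9\times10^{-3}$). Both
formulas were verified independently against numerical
$\int v^2\,\cdot$ (their generating profiles) $\,dv$, so the gap is a
property of the printed forms, not an implementation artifact. Similarly,
the truncated numeric second moment at $(\xi = 0.01, v_{max} = 6)$ sits
*above* the closed form by the nascent tail contribution
$(2\xi/\pi)v_{max} \approx 0.038$; the tests assert that relationship
rather than a spurious coincidence.

## Lévy-stable laws and the truncated Lévy flight

`levy_pdf()` evaluates $P(v) = (1/\pi)\int_0^\infty e^{-\gamma y^\alpha}
\cos(vy)\,dy$ for $\alpha \in (0,2]$ (values outside error out; no
clamping). The quadrature strategy mirrors the profile oracle but must
survive far harsher regimes — for $\alpha = 0.5$ the envelope horizon is
$y \sim 1700$ and tail evaluations sit at $|v| \sim 10^4$:

* moderate oscillation: adaptive integration over the envelope support;
* strong oscillation: Gauss–Legendre panels on half-periods of the cosine
  (15 nodes each), the first panel integrated adaptively when
  $\alpha < 1$ because the envelope then has a derivative singularity at
  the origin;
* long horizons (more than 400 panels): 100 panels summed directly, then
  the alternating tail collapsed by iterated averaging of its partial
  sums — the slowly varying envelope makes consecutive partial sums
  bracket the limit, so repeated halving converges geometrically and the
  cost becomes independent of the horizon. Agreement with the Gaussian
  and Lorentzian closed forms is at machine precision out to
  $|v| = 1000$.

The truncated Lévy flight keeps the printed hard cutoff literal: density
exactly zero beyond $\pm l$, normalizer $c = 1/\int_{-l}^{l}P \ge 1$ by
quadrature. Sampling is exact rejection — from the untruncated Cauchy or
Gaussian when $\alpha \in \{1, 2\}$ (the inverse-CDF tangent method for
the Cauchy), otherwise from a Cauchy envelope of scale $\gamma^{1/\alpha}$
with the envelope constant measured on a grid and inflated by 5%; an
envelope violation raises an error rather than silently truncating the
accept ratio. `cutoff_from_xi()` exposes the reciprocal line-damping
parameter as the effective cutoff scale with its dominance label; the
correspondence is qualitative and the package asserts no quantitative
equivalence between Voigt tails and the hard cutoff.

## Fitting

`fit_voigt()` fits one or two Voigt components to an empirical density by
bounded Levenberg–Marquardt on weighted density residuals. Design points:

* **Parameterization.** Width, area and $\xi$ are fitted in log space;
  $\xi$ is bounded to $[10^{-4}, 10^3]$, covering its large dynamic range
  while keeping the optimizer off exact zero. A fit ending on a $\xi$
  bound is flagged and reported as not converged.
* **Initialisation.** Mode locations and half-widths come from
  `detect_modes()` (topographic prominence on the density grid,
  deterministic); $\xi_0 = 0.5$ sits mid-range. Three deterministic
  starts (the detected peak, and the peak shifted by a quarter half-width
  with $\xi_0$ scaled to 0.15 and 1.5) guard against local minima without
  consuming random numbers; the lowest loss wins.
* **Joint fitting.** Two-mode densities are fitted jointly; the
  overlapping Lorentzian tails otherwise bias mode-by-mode fits. A `mask`
  window supports the per-mode treatment, and the masked-fit test
  documents the upward $\xi$ bias the leaking neighbour tail causes.
* **Bin-aware model.** Histogram bins report average density, not
  midpoint density; the model is therefore evaluated as a Simpson average
  over each bin whenever the fit target is a uniform-grid histogram. On
  a noiseless binned profile at $\xi = 2$ this removes a $-1.7\%$
  deterministic $\xi$ bias.
* **Pearson reweighting.** Observed-count Poisson errors over-weight
  downward fluctuations (an empty tail bin gets the largest weight in the
  suite), biasing $\xi$ low by $\sim 10\%$ at $\xi = 0.1$. After the
  first fit the per-bin errors are re-derived from the *expected* counts
  under the current model and the fit repeated (twice); recovery errors
  drop to the 1–4% level across $\xi \in [0.1, 2]$ at $n = 10^5$
  samples. Externally supplied uncertainties (e.g. instrument errors on a
  spectrum) are honoured as given.
* **Likelihood mode.** `method = "mle"` maximizes the raw-sample
  likelihood instead — statistically preferable under heavy tails, but
  minutes-scale at $n = 10^5$ in pure R, so least squares remains the
  default and the likelihood route is validated at test scale.
* **Uncertainties.** Parameter covariance comes from the scaled inverse
  Hessian (pseudo-inverse fallback), delta-method-propagated to $\xi$;
  honest `converged` reporting (max-iteration exits are failures).

`fit_qens()` fits $e^{-Q^2\langle u^2\rangle/3}[A_0\delta(\omega) +
\sum_i A_i L(\omega,\Gamma_i)]$ convolved with the Gaussian resolution:
the elastic line becomes the resolution Gaussian and each Lorentzian a
Voigt profile with $\xi_i = \Gamma_i/\omega_G'$ — evaluated in closed form
through the profile evaluator, never by numerical convolution. The
elastic/quasielastic weights live on the simplex (logit parameterization)
so $A_0 + \sum A_i = 1$ by construction; $\Gamma_i$ are log-parameterized;
the resolution width is held fixed (it is the instrument's, not the
sample's); an optional flat background is off by default to match the
bare model; a `window` on $|\omega|$ supports restricted-range fits such
as the high-energy region, where a Gaussian-dominated spectrum yields a
very small fitted $\xi$. Widths collapsing below $10^{-3}$ resolution
widths or exceeding the window are flagged as non-identifiable, not
returned silently. The number of Lorentzians is a required user choice
(1–3); no information-criterion selection is attempted.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical structure* the fitting
pipelines are built for, not the physics that produced it:

* `gen_voigt_samples()` uses the defining convolution exactly
  ($x_0 + \mathcal{N}(0,\omega_G'/\sqrt{2}) + \omega_L\tan(\pi(U-1/2))$),
  so sampled data follow the fitted model family by construction.
* `gen_two_state()` is a two-state Markov chain (geometric dwell times,
  exact run-length construction) with per-state Voigt observation noise —
  chosen Voigt rather than Gaussian so each mode has a ground-truth $\xi$
  for recovery tests. Defaults (levels 1.0/1.8 nm, widths 0.08/0.12 nm,
  $\xi$ 0.3/0.5, switching 0.01 per step) give a clearly bimodal,
  Rg-like distribution with dwell times of order $10^2$ steps.
* `gen_dihedral()` integrates overdamped Langevin dynamics on a circle
  (Euler–Maruyama, wrap to $(-\pi,\pi]$, stability guard
  $D\,U''/k_BT < 0.1$ per step, burn-in ten relaxation times) under free,
  harmonic, or double-well potentials, and returns wrapped increments at
  a chosen lag. Harmonic wells give near-Gaussian increment
  distributions; a deep double well adds rare hops, i.e. positive excess
  kurtosis — the qualitative single-well/multi-well contrast.
* `gen_qens()` adds heteroscedastic Gaussian noise
  $\sigma = \mathrm{noise}\cdot I + 0.01\,\mathrm{noise}\cdot I_{max}$
  (the floor keeps least-squares weights finite in the far tails), or
  Poisson counting noise at a chosen count scale.

The pipeline composes into the motivating end-to-end demonstration, which
the test suite runs: generate two-state trajectories whose unfolded-state
noise carries a growing Lorentzian (long-jump) contribution, fit both
modes jointly, and observe the fitted $\xi$ of the unfolded mode grow
with the generating one:

```{r trend, eval = FALSE}
xi_unf <- c(0.15, 0.45, 0.9)
fitted <- sapply(seq_along(xi_unf), function(i) {
  tr <- gen_two_state(6e4, 1.0, 1.8, k_unfold = 0.01, k_fold = 0.01,
                      noise_folded = voigt_shape(0, 0.08, 0.2),
                      noise_unfolded = voigt_shape(0, 0.12, xi_unf[i]),
                      seed = 60 + i)
  fit_voigt(histogram_pdf(tr$observation, n_bins = 200),
            n_components = 2)$components[[2]]$xi
})
```

None of this is molecular dynamics: there are no forces between residues,
no solvent, no real free-energy surface, and the mapping from residence
times or temperature to $\xi$ is imposed by construction (monotone
ladders), not derived. Passing round-trip tests therefore demonstrates
that the estimators recover what the model family encodes at realistic
noise and sample sizes — not that any particular protein behaves this
way. Real data add baseline drift, resolution-function imperfections,
multiple-$Q$ structure and asymmetries that are explicitly out of scope.

## Problem sizes and runtime choices

Test and acceptance runs use $10^5$-sample recoveries (20 seeds per $\xi$
for the recovery study), $10^6$ steps for dwell-time statistics (so the
5% mass-balance band is a $>3\sigma$ check), $2\times10^5$-step Langevin
trajectories with subsampling beyond the relaxation time for
equilibrium-law tests, and 801–1201-point spectra — sizes at which every
stage completes in seconds to a couple of minutes on one core while
leaving Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

* The exact series is not used past $\xi = 10$ (Faddeeva route instead);
  arbitrary-precision evaluation is out of scope.
* Stable-law *parameter estimation* (fitting $\alpha$) is not provided;
  the Lévy module evaluates and samples only.
* `fit_voigt()` handles one or two components; more would need a model
  of how many modes the density has, which is the user's call here.
* The raw-sample likelihood fitter is slow at $10^5$+ samples in pure R.
* QENS fitting is single-spectrum; no global multi-$Q$ analysis or EISF
  extraction.
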