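## Core evaluators for the reduced Voigt profile V(v, xi).
##
## Normalization convention: V integrates to 1 over v, so the xi -> 0 limit
## is exp(-v^2)/sqrt(pi) and the xi -> infinity limit (after rescaling) is
## the reduced Lorentzian (1/pi) xi/(v^2 + xi^2).

.check_v_xi <- function(v, xi) {
  if (!is.numeric(v) || !all(is.finite(v))) stop("`v` must be finite numeric")
  if (length(xi) != 1L || !is.finite(xi) || xi < 0)
    stop("`xi` must be a single finite value >= 0")
}

## Terms of the theta-like sum: sum over n >= 1 of
## [exp(-(v - n/2)^2) + exp(-(v + n/2)^2)] / (n^2 + 4 xi^2),
## the Gaussian-envelope truncation keeping every term above `tol`.
## Combining the exponentials this way (rather than exp(-v^2 - n^2/4) cosh(nv))
## avoids cosh overflow for |n v| beyond ~700.
.theta_sum <- function(v, xi, tol) {
  N <- ceiling(2 * (max(abs(v)) + sqrt(-log(tol * 1e-2)))) + 4L
  n <- seq_len(N)
  e <- exp(-outer(v, n / 2, "-")^2) + exp(-outer(v, n / 2, "+")^2)
  drop(e %*% (1 / (n^2 + 4 * xi^2)))
}

#' Evaluate the Voigt profile by its exact rapidly converging series
#'
#' Evaluates the unit-area reduced Voigt profile through the exact series
#' representation
#' \deqn{V(v,\xi) = \frac{e^{-v^2}}{\sqrt{\pi}} e^{\xi^2}\cos(2\xi v)
#'   \left[1 - \coth(2\pi\xi)\right] + \frac{2\xi}{\pi^{3/2}}
#'   \sum_{n=-\infty}^{\infty} \frac{e^{-(v - n/2)^2}}{n^2 + 4\xi^2},}
#' truncated under its Gaussian envelope. The correction term and the
#' \eqn{n = 0} summand individually diverge as \eqn{\xi \to 0}; they are
#' recombined algebraically (with `expm1` and a series form of
#' \eqn{\coth x - 1/x}) so the evaluation is stable for every
#' \eqn{\xi \ge 0} down to 0. Because the correction term grows like
#' \eqn{e^{\xi^2 - 4\pi\xi}}, the series representation is accurate only
#' for \eqn{\xi \lesssim 10} (absolute error below 1e-11 at \eqn{\xi = 10});
#' use [voigt()] with `method = "auto"` for larger \eqn{\xi}.
#'
#' @param v Numeric vector of reduced abscissa values
#'   \eqn{v = (x - x_0)/\omega_G'}.
#' @param xi Line-damping parameter, a single value \eqn{\ge 0}.
#' @param tol Series truncation tolerance in (0, 1e-6].
#' @return Densities \eqn{V(v,\xi)}, same length as `v`.
#' @examples
#' voigt_series(0, 0)   # 1/sqrt(pi)
#' voigt_series(c(-1, 0, 1), 0.5)
#' @seealso [voigt_oracle()] for the quadrature reference, [voigt()] for the
#'   dispatching front end.
#' @export
voigt_series <- function(v, xi, tol = 1e-12) {
  .check_v_xi(v, xi)
  stopifnot(length(tol) == 1L, tol > 0, tol <= 1e-6)
  if (xi == 0) return(exp(-v^2) / .SQRT_PI)
  if (xi < 1) {
    ## e^{xi^2} cos(2 xi v) [1 - coth(2 pi xi)] plus the n = 0 term
    ## e^{-v^2} / (2 pi^{3/2} xi), written without the 1/xi cancellation:
    y <- 2 * pi * xi
    g <- if (y < 1e-2) y / 3 - y^3 / 45 + 2 * y^5 / 945 else 1 / tanh(y) - 1 / y
    h <- expm1(xi^2) * cos(2 * xi * v) - 2 * sin(xi * v)^2  # e^{xi^2}cos(2 xi v) - 1
    head_term <- exp(-v^2) / .SQRT_PI *
      (exp(xi^2) * cos(2 * xi * v) * (1 - g) - h / (2 * pi * xi))
  } else {
    x <- 4 * pi * xi
    head_term <- -2 * exp(xi^2 - x - v^2) * cos(2 * xi * v) /
      (1 - exp(-x)) / .SQRT_PI +
      exp(-v^2) / (2 * pi^1.5 * xi)
  }
  head_term + 2 * xi / pi^1.5 * .theta_sum(v, xi, tol)
}

.integrate_or_stop <- function(f, lower, upper, what, ...) {
  res <- tryCatch(integrate(f, lower, upper, ...),
                  error = function(e)
                    stop(sprintf("quadrature for %s failed on [%g, %g]: %s",
                                 what, lower, upper, conditionMessage(e)),
                         call. = FALSE))
  if (res$message != "OK")
    stop(sprintf("quadrature for %s did not converge: %s", what, res$message),
         call. = FALSE)
  res$value
}

## integral of f over [0, ymax], splitting at half-periods of cos(v y)
## when the integrand oscillates many times over the range
.osc_integral <- function(f, ymax, v_freq, rel_tol, what) {
  if (abs(v_freq) * ymax > 10 * pi) {
    bp <- unique(c(seq(0, ymax, by = pi / abs(v_freq)), ymax))
    sum(vapply(seq_len(length(bp) - 1L), function(i)
      .integrate_or_stop(f, bp[i], bp[i + 1L], what,
                         rel.tol = rel_tol, abs.tol = rel_tol * 1e-3,
                         subdivisions = 200L),
      numeric(1)))
  } else {
    .integrate_or_stop(f, 0, ymax, what, rel.tol = rel_tol,
                       subdivisions = 1000L)
  }
}

#' Voigt profile by adaptive quadrature (reference oracle)
#'
#' Direct numerical evaluation of the defining integrals. The default
#' `"cosine"` form computes
#' \eqn{(1/\pi)\int_0^\infty e^{-\xi y - y^2/4}\cos(v y)\,dy}; the
#' `"lorentzian"` form computes the Gaussian-Lorentzian convolution
#' \eqn{(\xi/\pi^{3/2})\int e^{-y^2}/[\xi^2 + (v-y)^2]\,dy} (requires
#' \eqn{\xi > 0}); the `"scaled"` form is the cosine form after the
#' substitution \eqn{y \to y/\xi} (requires \eqn{\xi > 0}). Oscillation of
#' the cosine kernel at large \eqn{|v|} is handled by splitting the range at
#' half-periods. Intended as the slow, trusted reference for the fast
#' evaluators.
#'
#' @inheritParams voigt_series
#' @param rel_tol Relative quadrature tolerance, in (0, 1e-4].
#' @param form Which integral representation to evaluate.
#' @return Densities, same length as `v`. Errors (with a diagnostic) if the
#'   quadrature does not converge.
#' @examples
#' voigt_oracle(0, 1)                  # = exp(1) * erfc(1) / sqrt(pi)
#' voigt_oracle(2, 0)                  # pure-Gaussian limit exp(-4)/sqrt(pi)
#' @export
voigt_oracle <- function(v, xi, rel_tol = 1e-10,
                         form = c("cosine", "lorentzian", "scaled")) {
  .check_v_xi(v, xi)
  form <- match.arg(form)
  stopifnot(length(rel_tol) == 1L, rel_tol > 0, rel_tol <= 1e-4)
  if (form != "cosine" && xi == 0)
    stop("forms 'lorentzian' and 'scaled' require xi > 0")
  vapply(v, function(vi) {
    switch(form,
      cosine = {
        ymax <- 2 * (xi + sqrt(-log(1e-18)))
        .osc_integral(function(y) exp(-xi * y - y^2 / 4) * cos(vi * y),
                      ymax, vi, rel_tol, "voigt_oracle") / pi
      },
      lorentzian = {
        xi / pi^1.5 *
          .integrate_or_stop(function(y) exp(-y^2) / (xi^2 + (vi - y)^2),
                             -Inf, Inf, "voigt_oracle", rel.tol = rel_tol,
                             subdivisions = 1000L)
      },
      scaled = {
        ymax <- xi * 2 * (xi + sqrt(-log(1e-18)))
        .osc_integral(function(y) exp(-y - (y / (2 * xi))^2) * cos(vi * y / xi),
                      ymax, vi / xi, rel_tol, "voigt_oracle") / (pi * xi)
      })
  }, numeric(1))
}

#' Gaussian-dominance approximations to the Voigt profile
#'
#' Closed-form approximations valid near the maximum (\eqn{|v| \ll 1}).
#' `voigt_gauss_dominant()` evaluates
#' \deqn{V \approx \frac{e^{-v^2}}{\sqrt{\pi}}\left\{e^{\xi^2}
#'   \mathrm{erfc}(\xi)\cos(2\xi v) + \frac{2\sin^2(\xi v)}{\sqrt{\pi}\,\xi}
#'   \left[1 + 0.1379 v^2 + (0.0120 + 0.0434\,\xi^2) v^4\right]\right\},}
#' and `voigt_gauss_dominant_small()` its further reduction for
#' \eqn{\xi \ll 1},
#' \eqn{V \approx e^{-v^2}[a(\xi) + b(\xi)\cos(2\xi v)]} with
#' \eqn{a = 1/(\pi\xi)} and
#' \eqn{b = \pi^{-1/2}[e^{\xi^2}\mathrm{erfc}(\xi) - 1/(\sqrt{\pi}\xi)]}
#' (the two terms recombined stably near \eqn{\xi = 0}).
#' Both are evaluable anywhere; a logical attribute `in_regime` flags where
#' the stated validity region holds.
#'
#' @inheritParams voigt_series
#' @return Approximate densities with attribute `in_regime`.
#' @examples
#' voigt_gauss_dominant(0, 0.2)    # = erfcx(0.2)/sqrt(pi) = 0.45644
#' @export
voigt_gauss_dominant <- function(v, xi) {
  .check_v_xi(v, xi)
  sin_term <- if (xi == 0) {
    ## lim 2 sin^2(xi v) / (sqrt(pi) xi) = 0
    numeric(length(v))
  } else {
    2 * sin(xi * v)^2 / (.SQRT_PI * xi)
  }
  out <- exp(-v^2) / .SQRT_PI *
    (pracma::erfcx(xi) * cos(2 * xi * v) +
       sin_term * (1 + 0.1379 * v^2 + (0.0120 + 0.0434 * xi^2) * v^4))
  attr(out, "in_regime") <- abs(v) < 1
  out
}

#' @rdname voigt_gauss_dominant
#' @export
voigt_gauss_dominant_small <- function(v, xi) {
  .check_v_xi(v, xi)
  out <- if (xi == 0) {
    exp(-v^2) / .SQRT_PI
  } else {
    ## a + b cos = [1 - cos(2 xi v)]/(pi xi) + erfcx(xi) cos(2 xi v)/sqrt(pi),
    ## with 1 - cos(2 xi v) = 2 sin^2(xi v) (stable as xi -> 0)
    exp(-v^2) * (2 * sin(xi * v)^2 / (pi * xi) +
                   pracma::erfcx(xi) * cos(2 * xi * v) / .SQRT_PI)
  }
  attr(out, "in_regime") <- abs(v) < 1 & xi < 1
  out
}

#' Lorentzian-dominance approximations to the Voigt profile
#'
#' `voigt_lorentz_dominant_sum()` evaluates the intermediate-range form
#' (\eqn{\xi \ge 1})
#' \deqn{V \approx \frac{2\xi}{\pi^{3/2}} \sum_{n=-\infty}^{\infty}
#'   \frac{e^{-(v - n/2)^2}}{n^2 + 4\xi^2},}
#' truncated under the same Gaussian-envelope rule as the exact series.
#' `voigt_lorentz_tail()` evaluates the far-from-maximum form
#' (\eqn{\xi \gg 1})
#' \deqn{V \approx \frac{1}{\pi}\frac{\xi}{\xi^2 + v^2}
#'   \left[1 + \frac{v^2}{(\xi^2 + v^2)^2}\right].}
#' Both reduce to the reduced Lorentzian \eqn{(1/\pi)\,\xi/(v^2+\xi^2)} at
#' leading order for large \eqn{\xi}.
#'
#' @inheritParams voigt_series
#' @return Approximate densities with attribute `in_regime`.
#' @examples
#' voigt_lorentz_tail(0, 50)   # ~ 1/(50 * pi)
#' @export
voigt_lorentz_dominant_sum <- function(v, xi, tol = 1e-12) {
  .check_v_xi(v, xi)
  if (xi == 0) stop("the Lorentzian-dominance form is undefined at xi = 0")
  out <- 2 * xi / pi^1.5 *
    (exp(-v^2) / (4 * xi^2) + .theta_sum(v, xi, tol))
  attr(out, "in_regime") <- rep(xi >= 1, length(v))
  out
}

#' @rdname voigt_lorentz_dominant_sum
#' @export
voigt_lorentz_tail <- function(v, xi) {
  .check_v_xi(v, xi)
  if (xi == 0) stop("the Lorentzian-dominance form is undefined at xi = 0")
  s <- xi^2 + v^2
  out <- xi / (pi * s) * (1 + v^2 / s^2)
  attr(out, "in_regime") <- rep(xi >= 10, length(v))
  out
}

## Weideman-style rational approximation coefficients for w(z), cached per N
.faddeeva_cache <- new.env(parent = emptyenv())
.faddeeva_coef <- function(N) {
  key <- as.character(N)
  if (!is.null(.faddeeva_cache[[key]])) return(.faddeeva_cache[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- seq(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  t <- L * tan(pi * k / M / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  n <- length(f)
  f <- f[c((n %/% 2 + 1L):n, 1:(n %/% 2))]          # fftshift
  a <- Re(fft(f)) / M2
  coef <- list(L = L, a = rev(a[2:(N + 1L)]))
  .faddeeva_cache[[key]] <- coef
  coef
}

#' Faddeeva-type function W(z)
#'
#' Evaluates \eqn{W(z) = e^{-z^2}\mathrm{erfc}(-iz)} for \eqn{\mathrm{Im}\,
#' z \ge 0} by Weideman's rational approximation (an FFT-derived polynomial
#' in the Moebius-transformed variable; no overflow-prone intermediate
#' exponentials, uniformly accurate over the closed upper half-plane
#' including the real axis and large \eqn{|z|}). On the line
#' \eqn{z = v + i\xi} its real part equals \eqn{\sqrt{\pi}\,V(v,\xi)}; the
#' imaginary part is the dispersive companion used in resonance lineshape
#' work.
#'
#' @param z Complex vector with non-negative imaginary parts.
#' @param n_terms Order of the rational approximation (64 reaches close to
#'   machine precision).
#' @return Complex values \eqn{W(z)}.
#' @examples
#' faddeeva_w(0 + 0i)                    # 1
#' Re(faddeeva_w(0 + 1i))                # exp(1) * erfc(1)
#' Re(faddeeva_w(1.5 + 0.5i)) / sqrt(pi) # V(1.5, 0.5)
#' @export
faddeeva_w <- function(z, n_terms = 64L) {
  z <- as.complex(z)
  if (any(!is.finite(Re(z)) | !is.finite(Im(z)))) stop("`z` must be finite")
  if (any(Im(z) < 0))
    stop("faddeeva_w is defined here for the upper half-plane (Im z >= 0)")
  cf <- .faddeeva_coef(as.integer(n_terms))
  iz <- complex(imaginary = 1) * z
  Z <- (cf$L + iz) / (cf$L - iz)
  p <- rep(0 + 0i, length(z))
  for (a_k in cf$a) p <- p * Z + a_k
  2 * p / (cf$L - iz)^2 + (1 / .SQRT_PI) / (cf$L - iz)
}

#' Dawson function
#'
#' \eqn{F(t) = e^{-t^2}\int_0^t e^{y^2} dy}, the odd special function
#' entering \eqn{W(z) = e^{-z^2} + (2i/\sqrt{\pi})F(z)} on the real axis.
#' Computed from [faddeeva_w()]: \eqn{F(t) = (\sqrt{\pi}/2)\,
#' \mathrm{Im}\,W(t)} for real \eqn{t}.
#'
#' @param t Real numeric vector.
#' @return \eqn{F(t)}, same length as `t`.
#' @examples
#' dawson(0)          # 0
#' dawson(1)          # 0.5380795
#' @export
dawson <- function(t) {
  if (!is.numeric(t) || !all(is.finite(t))) stop("`t` must be finite numeric")
  s <- sign(t)
  s * .SQRT_PI / 2 * Im(faddeeva_w(complex(real = abs(t))))
}

#' Evaluate the reduced Voigt profile
#'
#' Front end dispatching between the exact series, the quadrature oracle,
#' the Faddeeva route, and the printed limiting approximations. The default
#' `"auto"` method is exact everywhere: the series for \eqn{\xi \le 8}
#' (where it carries machine precision) and
#' \eqn{\mathrm{Re}\,W(v + i\xi)/\sqrt{\pi}} beyond.
#'
#' @inheritParams voigt_series
#' @param method One of `"auto"`, `"series"`, `"oracle"`, `"faddeeva"`,
#'   `"gauss"` (near-maximum Gaussian-dominance form), `"gauss_small"`
#'   (its small-xi reduction), `"lorentz_sum"` (intermediate-range sum),
#'   `"lorentz_tail"` (far-from-maximum form).
#' @param tol Tolerance forwarded to the series / oracle evaluators.
#' @return Densities \eqn{V(v,\xi)}.
#' @examples
#' voigt(seq(-3, 3, 0.5), xi = 1)
#' voigt(0, 50)      # Faddeeva route, Lorentzian-dominated peak
#' @export
voigt <- function(v, xi, method = "auto", tol = 1e-12) {
  method <- match.arg(method, c("auto", "series", "oracle", "faddeeva",
                                "gauss", "gauss_small", "lorentz_sum",
                                "lorentz_tail"))
  if (method == "auto") {
    .check_v_xi(v, xi)
    if (xi > 8) {
      method <- "faddeeva"
    } else {
      ## the series cost grows with max |v|; hand far-tail points (where
      ## the theta sum would need thousands of terms) to the Faddeeva route
      big <- abs(v) > 30
      if (any(big)) {
        out <- numeric(length(v))
        if (any(!big)) out[!big] <- voigt_series(v[!big], xi, tol = tol)
        out[big] <- voigt(v[big], xi, method = "faddeeva")
        return(out)
      }
      method <- "series"
    }
  }
  switch(method,
    series       = voigt_series(v, xi, tol = tol),
    oracle       = voigt_oracle(v, xi, rel_tol = min(tol, 1e-6)),
    faddeeva     = {
      .check_v_xi(v, xi)
      av <- abs(v)  # structural symmetry in v
      Re(faddeeva_w(complex(real = av, imaginary = rep(xi, length(av))))) /
        .SQRT_PI
    },
    gauss        = voigt_gauss_dominant(v, xi),
    gauss_small  = voigt_gauss_dominant_small(v, xi),
    lorentz_sum  = voigt_lorentz_dominant_sum(v, xi, tol = tol),
    lorentz_tail = voigt_lorentz_tail(v, xi))
}

#' Route each point to the printed approximation for its regime
#'
#' Demonstration dispatcher mirroring the qualitative validity regions of
#' the limiting forms: for \eqn{\xi} below `xi_gauss` the Gaussian-dominance
#' form is used near the maximum (series elsewhere); between `xi_gauss` and
#' `xi_series` the exact series; above, the Lorentzian-dominance sum near
#' the maximum and the tail form far from it. Exact evaluation (see
#' [voigt()]) is preferred for fitting; this router exists to study the
#' approximations themselves.
#'
#' @inheritParams voigt_series
#' @param xi_gauss,xi_series Regime thresholds (defaults 0.3 and 1).
#' @param v_near Half-width of the "close to the maximum" window in units
#'   of \eqn{\max(1, \xi)}.
#' @return Densities with attribute `method` naming the form used per point.
#' @export
voigt_regime <- function(v, xi, xi_gauss = 0.3, xi_series = 1, v_near = 2) {
  .check_v_xi(v, xi)
  out <- numeric(length(v))
  meth <- character(length(v))
  near <- abs(v) <= v_near * max(1, xi)
  if (xi < xi_gauss) {
    meth[near] <- "gauss"; meth[!near] <- "series"
    if (any(near)) out[near] <- voigt_gauss_dominant(v[near], xi)
    if (any(!near)) out[!near] <- voigt_series(v[!near], xi)
  } else if (xi < xi_series || xi > 10) {
    meth[] <- "series"
    out <- voigt(v, xi)
  } else {
    meth[near] <- "lorentz_sum"; meth[!near] <- "lorentz_tail"
    if (any(near)) out[near] <- voigt_lorentz_dominant_sum(v[near], xi)
    if (any(!near)) out[!near] <- voigt_lorentz_tail(v[!near], xi)
  }
  attributes(out) <- NULL
  attr(out, "method") <- meth
  out
}

#' Voigt density in physical units
#'
#' \eqn{f(x) = A\,V((x - x_0)/\omega_G', \xi)\,/\,\omega_G'}: integrates to
#' the component area over \eqn{x \in \mathbb{R}}, peaks at `center`.
#'
#' @param x Physical abscissa values.
#' @param shape A [voigt_shape()].
#' @param method Forwarded to [voigt()].
#' @return Densities per physical unit.
#' @examples
#' sh <- voigt_shape(center = 0, gauss_width = 2, xi = 0)
#' voigt_pdf(0, sh)    # 1 / (2 sqrt(pi))
#' @export
voigt_pdf <- function(x, shape, method = "auto") {
  stopifnot(inherits(shape, "voigt_shape"))
  shape$area * voigt(reduce_abscissa(x, shape), shape$xi, method = method) /
    shape$gauss_width
}
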