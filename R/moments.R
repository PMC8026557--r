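## Variance of the Voigt profile in reduced (v) units.
##
## The full profile has Lorentzian 1/v^2 tails for any xi > 0, so its
## variance diverges; only the Gaussian-dominance approximations (which
## keep the exp(-v^2) envelope everywhere) admit finite closed forms.

#' Variance computation result
#'
#' Container pairing a variance value (reduced \eqn{v} units) with an
#' explicit finiteness flag, the method that produced it, and the
#' truncation half-range for numeric truncated integrals. Divergence is a
#' flagged mathematical state (`value = Inf`, `finite = FALSE`), never a
#' floating-point accident.
#'
#' @param value Variance in reduced units (may be `Inf`).
#' @param finite Logical; `FALSE` iff `value` is the infinite sentinel.
#' @param method One of `"full"`, `"gauss_a"`, `"gauss_b"`, `"numeric_truncated"`.
#' @param vmax Truncation half-range (> 0) for the numeric method, else `NA`.
#' @return An object of class `variance_result`.
#' @export
variance_result <- function(value, finite, method, vmax = NA_real_) {
  stopifnot(is.numeric(value), length(value) == 1L,
            is.logical(finite), length(finite) == 1L)
  method <- match.arg(method,
                      c("full", "gauss_a", "gauss_b", "numeric_truncated"))
  if (finite != is.finite(value))
    stop("`finite` must be FALSE exactly when `value` is infinite")
  if (method == "numeric_truncated" && !(is.finite(vmax) && vmax > 0))
    stop("`vmax` must be > 0 for the numeric_truncated method")
  structure(list(value = value, finite = finite, method = method,
                 vmax = vmax),
            class = "variance_result")
}

#' @export
print.variance_result <- function(x, ...) {
  cat(sprintf("<variance_result> %s: %s%s\n", x$method,
              if (x$finite) format(x$value) else "divergent (Inf)",
              if (!is.na(x$vmax)) sprintf(" [vmax = %g]", x$vmax) else ""))
  invisible(x)
}

.check_xi_scalar <- function(xi) {
  if (length(xi) != 1L || !is.finite(xi) || xi < 0)
    stop("`xi` must be a single finite value >= 0")
}

#' Variance of the full Voigt profile
#'
#' The exact second moment of the Voigt profile reduces to
#' \deqn{\mathrm{Var}(\xi) = \tfrac{1}{2}\left[1 - \coth(2\pi\xi)\right]
#'   (1 - 2\xi^2) + \frac{\xi}{\sqrt{\pi}} \sum_{n=0}^{\infty}
#'   \frac{n^2 + 2}{n^2 + 4\xi^2},}
#' whose series has terms tending to 1: it diverges for every
#' \eqn{\xi > 0}, so the variance of the full profile is undefined. At
#' \eqn{\xi = 0} the profile is the Gaussian \eqn{e^{-v^2}/\sqrt{\pi}} with
#' variance 1/2.
#'
#' @param xi Line-damping parameter, a single value \eqn{\ge 0}.
#' @return A [variance_result()]: finite 1/2 at \eqn{\xi = 0}, the infinite
#'   sentinel for \eqn{\xi > 0}.
#' @export
variance_full <- function(xi) {
  .check_xi_scalar(xi)
  if (xi == 0) variance_result(0.5, TRUE, "full")
  else variance_result(Inf, FALSE, "full")
}

#' Variance of the Gaussian-dominance approximations
#'
#' Closed-form variances of the two Gaussian-dominance profiles.
#' `variance_gauss_a()` (from the near-maximum form with polynomial
#' corrections):
#' \deqn{\mathrm{Var} = \tfrac{1}{2}(1 - 2\xi^2)\,\mathrm{erfc}(\xi)
#'  + \frac{1 - e^{-\xi^2}}{\sqrt{\pi}\,\xi}(0.6259 + 0.0814\,\xi^2)
#'  + \frac{e^{-\xi^2}}{\sqrt{\pi}}\left(1.5486\,\xi + 0.2605\,\xi^3
#'  - 0.3136\,\xi^5 + 0.0434\,\xi^7\right).}
#' `variance_gauss_b()` (from the small-\eqn{\xi} two-term form):
#' \deqn{\mathrm{Var} = \tfrac{1}{2}(1 - 2\xi^2)\,\mathrm{erfc}(\xi)
#'  + \frac{1 - (1 - 2\xi^2)e^{-\xi^2}}{2\sqrt{\pi}\,\xi}.}
#' Both tend to 1/2 as \eqn{\xi \to 0}; the \eqn{(1 - e^{-\xi^2})/\xi}
#' factors are evaluated with `expm1` so the limit is reached without 0/0.
#' `variance_gauss_b` is meaningful only for \eqn{\xi \ll 1} (its decrease
#' at large \eqn{\xi} reflects the breakdown of the underlying two-term
#' form); `variance_gauss_a` turns to growth for \eqn{\xi > 3} as the
#' profile becomes Lorentzian. The two formulas differ at first order in
#' \eqn{\xi} (by about \eqn{0.38\,\xi}), the contribution of the
#' \eqn{v^2, v^4} polynomial corrections kept only by the first.
#'
#' @inheritParams variance_full
#' @return A [variance_result()] (always finite).
#' @examples
#' variance_gauss_a(0)$value       # 0.5
#' variance_gauss_a(5)$value > variance_gauss_a(3)$value
#' @export
variance_gauss_a <- function(xi) {
  .check_xi_scalar(xi)
  if (xi == 0) return(variance_result(0.5, TRUE, "gauss_a"))
  val <- 0.5 * (1 - 2 * xi^2) * pracma::erfc(xi) +
    (-expm1(-xi^2)) / (.SQRT_PI * xi) * (0.6259 + 0.0814 * xi^2) +
    exp(-xi^2) / .SQRT_PI *
      (1.5486 * xi + 0.2605 * xi^3 - 0.3136 * xi^5 + 0.0434 * xi^7)
  variance_result(val, TRUE, "gauss_a")
}

#' @rdname variance_gauss_a
#' @export
variance_gauss_b <- function(xi) {
  .check_xi_scalar(xi)
  if (xi == 0) return(variance_result(0.5, TRUE, "gauss_b"))
  ## 1 - (1 - 2 xi^2) e^{-xi^2} = -expm1(-xi^2) + 2 xi^2 e^{-xi^2}
  bracket <- -expm1(-xi^2) + 2 * xi^2 * exp(-xi^2)
  val <- 0.5 * (1 - 2 * xi^2) * pracma::erfc(xi) +
    bracket / (2 * .SQRT_PI * xi)
  variance_result(val, TRUE, "gauss_b")
}

#' Truncated second moment of the Voigt profile by quadrature
#'
#' \eqn{\int_{-v_{max}}^{v_{max}} v^2\,V(v,\xi)\,dv}, the numeric oracle for
#' the variance formulas. Monotone non-decreasing in `vmax`; converges to
#' 1/2 for \eqn{\xi = 0} and grows without bound like
#' \eqn{(2\xi/\pi)\,v_{max}} for \eqn{\xi > 0} (the Lorentzian tails).
#'
#' @inheritParams variance_full
#' @param vmax Truncation half-range (> 0).
#' @param rel_tol Relative quadrature tolerance.
#' @return A [variance_result()] with `method = "numeric_truncated"`.
#' @examples
#' variance_numeric_truncated(0, 8)$value    # ~ 0.5
#' @export
variance_numeric_truncated <- function(xi, vmax, rel_tol = 1e-9) {
  .check_xi_scalar(xi)
  stopifnot(length(vmax) == 1L, is.finite(vmax), vmax > 0)
  val <- 2 * .integrate_or_stop(
    function(v) v^2 * voigt(v, xi), 0, vmax,
    "variance_numeric_truncated", rel.tol = rel_tol, subdivisions = 500L)
  variance_result(val, TRUE, "numeric_truncated", vmax = vmax)
}

#' Convert a reduced-units variance to physical units
#'
#' Variances above are in reduced \eqn{v} units; multiplying by
#' \eqn{\omega_G'^2} restores the physical scale.
#'
#' @param result A [variance_result()].
#' @param gauss_width Gaussian 1/e half-width \eqn{\omega_G'} (> 0).
#' @return The physical-units variance (numeric; `Inf` if divergent).
#' @export
variance_physical <- function(result, gauss_width) {
  stopifnot(inherits(result, "variance_result"),
            is.finite(gauss_width), gauss_width > 0)
  result$value * gauss_width^2
}
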