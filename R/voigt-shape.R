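#' Voigt component in physical units
#'
#' A single Voigt component parameterized by its center, the 1/e half-width
#' of the Gaussian part, the dimensionless line-damping parameter
#' \eqn{\xi = \omega_L / \omega_G'}, and an area (weight).
#'
#' The Gaussian part has half-width at half-maximum
#' \eqn{\omega_G = \sqrt{\ln 2}\,\omega_G'}; the Lorentzian part has HWHM
#' \eqn{\omega_L = \xi\,\omega_G'}. \eqn{\xi \to 0} gives a pure Gaussian,
#' \eqn{\xi \to \infty} a pure Lorentzian.
#'
#' @param center Peak position \eqn{x_0}, in the physical units of the
#'   abscissa (nm, meV, rad, ...).
#' @param gauss_width Gaussian 1/e half-width \eqn{\omega_G'} (> 0), same
#'   units as `center`.
#' @param xi Line-damping parameter \eqn{\xi \ge 0} (dimensionless).
#' @param area Total area \eqn{A > 0} of the component (dimensionless
#'   weight; the profile integrates to `area`).
#'
#' @return An object of class `voigt_shape` with fields `center`,
#'   `gauss_width`, `xi`, `area`, plus derived `lorentz_hwhm`
#'   (\eqn{\omega_L}) and `gauss_hwhm` (\eqn{\omega_G}).
#' @examples
#' sh <- voigt_shape(center = 1.2, gauss_width = 0.3, xi = 0.5)
#' sh$lorentz_hwhm   # 0.15
#' @export
voigt_shape <- function(center = 0, gauss_width = 1, xi = 0, area = 1) {
  stopifnot(length(center) == 1L, length(gauss_width) == 1L,
            length(xi) == 1L, length(area) == 1L)
  if (!is.finite(center)) stop("`center` must be finite")
  if (!is.finite(gauss_width) || gauss_width <= 0)
    stop("`gauss_width` (the 1/e Gaussian half-width) must be > 0")
  if (!is.finite(xi) || xi < 0) stop("`xi` must be >= 0")
  if (!is.finite(area) || area <= 0) stop("`area` must be > 0")
  structure(
    list(center = center, gauss_width = gauss_width, xi = xi, area = area,
         lorentz_hwhm = xi * gauss_width,
         gauss_hwhm = .SQRT_LN2 * gauss_width),
    class = "voigt_shape")
}

#' @export
print.voigt_shape <- function(x, ...) {
  cat(sprintf(
    "<voigt_shape> center = %g, gauss 1/e half-width = %g (HWHM %.4g), xi = %g (lorentz HWHM %.4g), area = %g\n",
    x$center, x$gauss_width, x$gauss_hwhm, x$xi, x$lorentz_hwhm, x$area))
  invisible(x)
}

#' Reduce a physical abscissa to dimensionless Voigt coordinates
#'
#' Maps `x` to \eqn{v = (x - x_0)/\omega_G'} so that the component center
#' sits at \eqn{v = 0} and one Gaussian 1/e half-width equals one unit.
#'
#' @param x Numeric vector of physical abscissa values (finite).
#' @param shape A [voigt_shape()].
#' @return Dimensionless reduced coordinates, same length as `x`.
#' @examples
#' sh <- voigt_shape(center = 2, gauss_width = 0.5)
#' reduce_abscissa(c(2, 2.5, 1), sh)   # 0, 1, -2
#' @export
reduce_abscissa <- function(x, shape) {
  stopifnot(inherits(shape, "voigt_shape"))
  if (!all(is.finite(x))) stop("`x` must be finite")
  (x - shape$center) / shape$gauss_width
}
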