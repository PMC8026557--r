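# Shared helpers: high-precision special-function references and small
# numeric oracles kept independent of the code paths they check.

# reference peak value V(0, xi) = e^{xi^2} erfc(xi) / sqrt(pi), through the
# scaled complementary error function (stable for large xi)
ref_peak <- function(xi) pracma::erfcx(xi) / sqrt(pi)

# reduced Lorentzian, the xi -> Inf limit shape
ref_lorentz <- function(v, xi) (1 / pi) * xi / (v^2 + xi^2)

# Voigt CDF on a grid by cumulative trapezoid integration of voigt_pdf
# (used to test samplers against the density they claim to follow)
ref_cdf_fun <- function(shape, lo, hi, n = 4001) {
  x <- seq(lo, hi, length.out = n)
  d <- voigt_pdf(x, shape)
  cdf <- cumsum(c(0, diff(x) * (head(d, -1) + tail(d, -1)) / 2))
  ## account for mass outside [lo, hi] via the Lorentzian tail integral
  approxfun(x, cdf + (1 - cdf[n]) / 2, rule = 2)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# total integral of an even density f(v) with explicit 1/v^2 tail
# treatment: adaptive quadrature on [0, v0] plus the substituted tail
# integral of f(1/u)/u^2 on (0, 1/v0]
even_density_area <- function(f, v0 = 30, rel_tol = 1e-10) {
  core <- integrate(f, 0, v0, rel.tol = rel_tol, subdivisions = 500L)$value
  tail <- integrate(function(u) f(1 / u) / u^2, 0, 1 / v0,
                    rel.tol = rel_tol, subdivisions = 500L)$value
  2 * (core + tail)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
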