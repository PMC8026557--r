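## Quasielastic incoherent neutron scattering (QENS) lineshapes.
##
## The theoretical scattering function for internal protein motion is a
## Debye-Waller-scaled sum of an elastic delta line and quasielastic
## Lorentzians,
##   S(Q, w) = exp(-Q^2 <u^2>/3) [ A0(Q) d(w) + sum_i Ai(Q) L(w, Gamma_i) ].
## The spectrometer contributes a Gaussian resolution, so the measured
## spectrum is this model convolved with a Gaussian: the delta becomes the
## resolution Gaussian, each Lorentzian a Voigt profile with
## xi_i = Gamma_i / omega_G' (resolution 1/e half-width).

#' Convert between a Gaussian FWHM and its 1/e half-width
#'
#' Instrument resolutions are usually quoted as full width at half maximum;
#' the Voigt parameterization here uses the 1/e half-width
#' \eqn{\omega_G' = \mathrm{FWHM} / (2\sqrt{\ln 2})}.
#'
#' @param fwhm,gauss_width Widths in the same physical units (e.g. meV).
#' @return The converted width.
#' @export
gauss_width_from_fwhm <- function(fwhm) fwhm / (2 * .SQRT_LN2)

#' @rdname gauss_width_from_fwhm
#' @export
fwhm_from_gauss_width <- function(gauss_width) gauss_width * 2 * .SQRT_LN2

#' QENS model for internal protein motion
#'
#' @param elastic_weight Elastic fraction \eqn{A_0(Q) \in [0, 1]}.
#' @param components Data frame with columns `weight` (\eqn{A_i \ge 0}) and
#'   `hwhm` (Lorentzian HWHM \eqn{\Gamma_i > 0}, meV); may have zero rows.
#'   `elastic_weight + sum(weight)` must equal 1 (the structure-factor
#'   normalization before the Debye-Waller prefactor); small departures
#'   (\eqn{\le 10^{-6}}) are renormalized exactly.
#' @param resolution_width Gaussian resolution 1/e half-width
#'   \eqn{\omega_G'} (meV, > 0); see [gauss_width_from_fwhm()].
#' @param Q Momentum transfer (\eqn{\AA^{-1}}).
#' @param msd Mean-square vibrational amplitude \eqn{\langle u^2\rangle}
#'   (\eqn{\AA^2}).
#' @param background Flat background (intensity units, \eqn{\ge 0}).
#' @return An object of class `qens_model`. Each quasielastic component
#'   carries its line-damping parameter \eqn{\xi_i = \Gamma_i/\omega_G'}
#'   in the `xi` column.
#' @examples
#' qens_model(0.6, data.frame(weight = 0.4, hwhm = 0.1),
#'            resolution_width = 0.0721)
#' @export
qens_model <- function(elastic_weight, components = NULL,
                       resolution_width, Q = 1, msd = 0, background = 0) {
  if (is.null(components))
    components <- data.frame(weight = numeric(0), hwhm = numeric(0))
  stopifnot(is.data.frame(components),
            all(c("weight", "hwhm") %in% names(components)))
  if (!is.finite(elastic_weight) || elastic_weight < 0 || elastic_weight > 1)
    stop("`elastic_weight` must lie in [0, 1]")
  if (nrow(components)) {
    if (any(components$weight < 0)) stop("component weights must be >= 0")
    if (any(components$hwhm <= 0)) stop("Lorentzian HWHMs must be > 0")
  }
  if (!is.finite(resolution_width) || resolution_width <= 0)
    stop("`resolution_width` must be > 0")
  if (!is.finite(background) || background < 0)
    stop("`background` must be >= 0")
  if (!is.finite(Q) || Q < 0 || !is.finite(msd) || msd < 0)
    stop("`Q` and `msd` must be >= 0")
  tot <- elastic_weight + sum(components$weight)
  if (abs(tot - 1) > 1e-6)
    stop(sprintf("elastic + quasielastic weights must sum to 1 (got %.8g)",
                 tot))
  elastic_weight <- elastic_weight / tot
  components$weight <- components$weight / tot
  components$xi <- components$hwhm / resolution_width
  structure(list(elastic_weight = elastic_weight, components = components,
                 resolution_width = resolution_width, Q = Q, msd = msd,
                 background = background),
            class = "qens_model")
}

#' @export
print.qens_model <- function(x, ...) {
  cat(sprintf("<qens_model> A0 = %.4g, %d Lorentzian(s), resolution omega_G' = %g, Q = %g, <u^2> = %g, bg = %g\n",
              x$elastic_weight, nrow(x$components), x$resolution_width,
              x$Q, x$msd, x$background))
  if (nrow(x$components))
    for (i in seq_len(nrow(x$components)))
      cat(sprintf("  A%d = %.4g, Gamma = %g meV (xi = %.4g)\n", i,
                  x$components$weight[i], x$components$hwhm[i],
                  x$components$xi[i]))
  invisible(x)
}

#' Resolution-convolved QENS spectrum
#'
#' Closed-form evaluation of the model convolved with the Gaussian
#' instrument resolution: the elastic delta becomes the unit-area
#' resolution Gaussian, each Lorentzian a Voigt profile with the
#' resolution's Gaussian width and \eqn{\omega_L = \Gamma_i}; everything is
#' scaled by the Debye-Waller-type factor
#' \eqn{e^{-Q^2\langle u^2\rangle/3}}, and the flat background added.
#'
#' @param omega Energy-transfer grid (meV); a grid symmetric about 0 is
#'   recommended.
#' @param model A [qens_model()].
#' @param method Voigt evaluation method, forwarded to [voigt()].
#' @return Intensities on `omega`.
#' @examples
#' m <- qens_model(0.5, data.frame(weight = 0.5, hwhm = 0.1),
#'                 resolution_width = 0.0721)
#' s <- qens_spectrum(seq(-2, 2, 0.01), m)
#' @export
qens_spectrum <- function(omega, model, method = "auto") {
  stopifnot(inherits(model, "qens_model"))
  if (!all(is.finite(omega))) stop("`omega` must be finite")
  w <- model$resolution_width
  dw_factor <- exp(-model$Q^2 * model$msd / 3)
  out <- model$elastic_weight * exp(-(omega / w)^2) / (w * .SQRT_PI)
  if (nrow(model$components))
    for (i in seq_len(nrow(model$components)))
      out <- out + model$components$weight[i] *
        voigt(omega / w, model$components$xi[i], method = method) / w
  dw_factor * out + model$background
}

#' Fit a QENS spectrum with Voigt lineshapes
#'
#' Weighted least-squares fit of a measured spectrum by the
#' resolution-convolved model: an overall intensity scale (absorbing the
#' Debye-Waller prefactor), the elastic fraction \eqn{A_0} and quasielastic
#' weights \eqn{A_i} constrained to the simplex
#' \eqn{A_0 + \sum A_i = 1}, the Lorentzian HWHMs \eqn{\Gamma_i} in log
#' space, and optionally a flat background. The resolution width is known
#' from the instrument and held fixed. Each fitted component's line-damping
#' parameter \eqn{\xi_i = \Gamma_i\sqrt{\ln 2}/\omega_G =
#' \Gamma_i/\omega_G'} is reported.
#'
#' `window`, given as `c(lo, hi)` on \eqn{|\omega|}, restricts the fit to
#' that energy band: `window = c(1, Inf)` reproduces the
#' high-energy-region fitting mode in which a Gaussian-dominated spectrum
#' yields a very small \eqn{\xi}.
#'
#' @param omega,intensity,err Spectrum columns (energy transfer in meV,
#'   measured intensity, optional positive uncertainties).
#' @param resolution_width Gaussian resolution 1/e half-width (meV); use
#'   [gauss_width_from_fwhm()] if the instrument quotes a FWHM.
#' @param n_lorentz Number of quasielastic Lorentzians (1-3).
#' @param fit_background Add a flat background parameter (default off, as
#'   in the bare model).
#' @param window Optional `c(lo, hi)` band on \eqn{|\omega|}.
#' @param init_gamma Optional initial \eqn{\Gamma_i} values (meV).
#' @param max_iter Maximum optimizer iterations.
#' @return A list of class `qens_fit`: `model` (the fitted [qens_model()]),
#'   `scale`, `xi`, `xi_se`, `gamma`, `gamma_se`, `loss`, `converged`,
#'   `iterations`, `flags` (character vector; non-identifiable widths --
#'   \eqn{\Gamma} collapsing to zero or growing past the fitted window --
#'   are flagged here and `converged` is set `FALSE`, never silently
#'   returned).
#' @export
fit_qens <- function(omega, intensity, err = NULL, resolution_width,
                     n_lorentz = 1, fit_background = FALSE, window = NULL,
                     init_gamma = NULL, max_iter = 300) {
  stopifnot(n_lorentz %in% 1:3, length(omega) == length(intensity))
  if (!is.finite(resolution_width) || resolution_width <= 0)
    stop("`resolution_width` must be > 0")
  keep <- is.finite(omega) & is.finite(intensity)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- keep & abs(omega) >= window[1] & abs(omega) <= window[2]
  }
  if (sum(keep) < 4 + 2 * n_lorentz) stop("too few points in fitting window")
  om <- omega[keep]; y <- intensity[keep]
  wts <- if (!is.null(err)) {
    e <- err[keep]
    if (any(!is.finite(e) | e <= 0)) stop("`err` must be positive and finite")
    1 / e^2
  } else rep(1, length(om))
  sw <- sqrt(wts)
  nl <- as.integer(n_lorentz)

  if (is.null(init_gamma))
    init_gamma <- resolution_width * .SQRT_LN2 * 4^seq(0, nl - 1)
  stopifnot(length(init_gamma) == nl, all(init_gamma > 0))

  ## parameters: log scale, weight logits z_1..z_nl (A0 reference),
  ## log Gamma_1..nl, [background]
  model_of <- function(p) {
    sc <- exp(p[1])
    z <- p[1 + seq_len(nl)]
    wts_simplex <- c(1, exp(z)) / (1 + sum(exp(z)))
    gam <- exp(p[1 + nl + seq_len(nl)])
    bg <- if (fit_background) exp(p[2 + 2 * nl]) else 0
    list(scale = sc, A0 = wts_simplex[1], Ai = wts_simplex[-1], gamma = gam,
         bg = bg)
  }
  eval_spec <- function(mp) {
    s <- mp$A0 * exp(-(om / resolution_width)^2) /
      (resolution_width * .SQRT_PI)
    for (i in seq_len(nl))
      s <- s + mp$Ai[i] *
        voigt(om / resolution_width, mp$gamma[i] / resolution_width) /
        resolution_width
    mp$scale * s + mp$bg
  }
  resid_fn <- function(p) {
    r <- sw * (eval_spec(model_of(p)) - y)
    if (any(!is.finite(r))) stop("non-finite residuals during QENS fit")
    r
  }
  p0 <- c(log(max(.trapz(om, pmax(y, 0)), 1e-12)), rep(0, nl),
          log(init_gamma))
  if (fit_background) p0 <- c(p0, log(max(min(pmax(y, 0)) , 1e-10)))
  span <- max(abs(om))
  lower <- c(-30, rep(-15, nl), rep(log(resolution_width * 1e-4), nl))
  upper <- c(30, rep(15, nl), rep(log(span * 20), nl))
  if (fit_background) { lower <- c(lower, -40); upper <- c(upper, 30) }

  res <- minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12,
                              ptol = 1e-12))
  mp <- model_of(res$par)

  flags <- character(0)
  if (any(mp$gamma < resolution_width * 1e-3))
    flags <- c(flags, "gamma collapsed toward zero (unresolved component)")
  if (any(mp$gamma > span * 5))
    flags <- c(flags, "gamma exceeds the fitted energy window")
  converged <- res$info %in% 1:3 && length(flags) == 0
  if (length(flags)) warning(paste(flags, collapse = "; "))

  dof <- max(length(om) - length(res$par), 1)
  sigma2 <- res$deviance / dof
  cov_t <- tryCatch(sigma2 * solve(res$hessian / 2), error = function(e) NULL)
  gam_se <- rep(NA_real_, nl)
  if (!is.null(cov_t)) {
    ig <- 1 + nl + seq_len(nl)
    gam_se <- mp$gamma * sqrt(pmax(diag(cov_t)[ig], 0))
  }
  fitted_model <- qens_model(
    elastic_weight = mp$A0,
    components = data.frame(weight = mp$Ai, hwhm = mp$gamma),
    resolution_width = resolution_width, background = mp$bg)
  structure(list(model = fitted_model, scale = mp$scale,
                 xi = mp$gamma / resolution_width,
                 xi_se = gam_se / resolution_width,
                 gamma = mp$gamma, gamma_se = gam_se,
                 loss = res$deviance, converged = converged,
                 iterations = res$niter, flags = flags, cov = cov_t,
                 n_points = length(om)),
            class = "qens_fit")
}

#' @export
print.qens_fit <- function(x, ...) {
  cat(sprintf("<qens_fit> %sconverged, loss %.4g, scale %.4g\n",
              if (x$converged) "" else "NOT ", x$loss, x$scale))
  print(x$model)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
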