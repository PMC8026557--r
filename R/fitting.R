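## Extraction of Voigt parameters -- above all the line-damping parameter
## xi -- from empirical probability distributions (histograms of order
## parameters such as the radius of gyration, or of dihedral-angle
## increments).

#' Empirical probability density on a grid
#'
#' @param x Strictly increasing abscissa grid (physical units).
#' @param density Non-negative densities per physical unit.
#' @param err Optional per-point uncertainties (> 0 where given).
#' @param samples Optional raw samples backing the histogram.
#' @return An object of class `empirical_pdf`.
#' @export
empirical_pdf <- function(x, density, err = NULL, samples = NULL) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("`x` must be finite numeric")
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  if (length(density) != length(x)) stop("`density` length must match `x`")
  if (any(!is.finite(density)) || any(density < 0))
    stop("`density` must be finite and non-negative")
  if (!is.null(err)) {
    if (length(err) != length(x) || any(!is.finite(err)) || any(err <= 0))
      stop("`err` must be positive, finite, and match `x` in length")
  }
  structure(list(x = x, density = density, err = err, samples = samples),
            class = "empirical_pdf")
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat(sprintf("<empirical_pdf> %d points on [%g, %g]%s%s\n",
              length(x$x), min(x$x), max(x$x),
              if (!is.null(x$err)) ", with uncertainties" else "",
              if (!is.null(x$samples))
                sprintf(", backed by %d raw samples", length(x$samples))
              else ""))
  invisible(x)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Histogram density estimate from raw samples
#'
#' Bins the samples on a uniform grid and renormalizes so the density
#' integrates to exactly 1 over the range under the trapezoid rule on bin
#' midpoints. Per-bin uncertainties are Poisson
#' (\eqn{\sqrt{\max(n_k, 1)}} scaled like the density).
#'
#' @param samples Numeric vector, at least 100 finite values.
#' @param n_bins Number of bins (\eqn{\ge 10}).
#' @param range Optional `c(lo, hi)` histogram range. The default spans the
#'   0.2% to 99.8% sample quantiles (padded by 5%) rather than the raw
#'   extremes: Voigt-like samples have Cauchy tails whose outliers would
#'   otherwise stretch the grid until all structure lands in a few bins.
#' @return An [empirical_pdf()] on bin midpoints, with `samples` attached.
#' @examples
#' p <- histogram_pdf(rnorm(10000), n_bins = 40)
#' @export
histogram_pdf <- function(samples, n_bins = 60, range = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("need at least 100 finite samples")
  stopifnot(length(n_bins) == 1L, n_bins >= 10)
  if (diff(base::range(samples)) <= 0)
    stop("degenerate samples: all values identical")
  if (is.null(range)) {
    qs <- stats::quantile(samples, c(0.002, 0.998), names = FALSE)
    range <- qs + c(-1, 1) * 0.05 * max(diff(qs), .Machine$double.eps)
  }
  if (diff(range) <= 0)
    stop("degenerate samples: histogram range has zero width")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  inside <- samples >= range[1] & samples <= range[2]
  counts <- tabulate(pmin(findInterval(samples[inside], breaks,
                                       rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  width <- diff(breaks)[1]
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  dens <- counts / (sum(counts) * width)
  scale <- .trapz(mids, dens)
  if (scale <= 0) stop("degenerate samples: empty histogram")
  dens <- dens / scale
  err <- sqrt(pmax(counts, 1)) / (sum(counts) * width) / scale
  empirical_pdf(mids, dens, err = err, samples = samples)
}

#' Detect density modes by peak prominence
#'
#' Finds local maxima of the density and keeps those whose topographic
#' prominence (height above the highest saddle separating them from higher
#' terrain; the tallest peak is measured from the grid minimum) exceeds
#' `prominence_fraction` of the global maximum. Deterministic.
#'
#' @param pdf An [empirical_pdf()].
#' @param prominence_fraction Fraction of the global maximum in (0, 1).
#' @return A data frame with columns `location`, `height`, `prominence`,
#'   ordered by location. Errors if no peak passes the threshold.
#' @export
detect_modes <- function(pdf, prominence_fraction = 0.1) {
  stopifnot(inherits(pdf, "empirical_pdf"),
            prominence_fraction > 0, prominence_fraction < 1)
  d <- pdf$density
  n <- length(d)
  if (n < 3) stop("density grid too short for mode detection")
  idx <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  if (length(idx) == 0) stop("no local maximum found: density has no mode")
  h <- d[idx]
  prom <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    higher <- idx[h > h[k]]
    saddles <- c()
    left <- higher[higher < i]
    if (length(left)) saddles <- c(saddles, min(d[max(left):i]))
    right <- higher[higher > i]
    if (length(right)) saddles <- c(saddles, min(d[i:min(right)]))
    if (length(saddles) == 0) return(h[k] - min(d))
    h[k] - max(saddles)
  }, numeric(1))
  keep <- prom >= prominence_fraction * max(d)
  if (!any(keep))
    stop("no mode with prominence above threshold: density too flat")
  out <- data.frame(location = pdf$x[idx[keep]], height = h[keep],
                    prominence = prom[keep])
  out[order(out$location), , drop = FALSE]
}

## half-width at half-maximum of the density around grid index i
.hwhm_at <- function(x, d, i) {
  half <- d[i] / 2
  right <- which(d[i:length(d)] < half)
  left <- which(rev(d[1:i]) < half)
  dr <- if (length(right)) x[i + right[1] - 1L] - x[i] else x[length(x)] - x[i]
  dl <- if (length(left)) x[i] - x[i - left[1] + 1L] else x[i] - x[1]
  max(min(dr, dl), diff(range(x)) / length(x))
}

.fit_model_eval <- function(x, par_mat) {
  ## par_mat: one row per component, columns center, gauss_width, xi, area
  out <- numeric(length(x))
  for (k in seq_len(nrow(par_mat))) {
    sh <- voigt_shape(par_mat[k, 1], par_mat[k, 2], par_mat[k, 3],
                      par_mat[k, 4])
    out <- out + voigt_pdf(x, sh)
  }
  out
}

.unpack_par <- function(p, m) {
  matrix(c(p[seq(1, 4 * m, 4)], exp(p[seq(2, 4 * m, 4)]),
           exp(p[seq(3, 4 * m, 4)]), exp(p[seq(4, 4 * m, 4)])),
         nrow = m)
}

#' Fit one or two Voigt components to an empirical density
#'
#' Weighted least squares on density values (weights \eqn{1/\sigma^2} where
#' uncertainties are present, else uniform) by bounded Levenberg-Marquardt,
#' with the component width, line-damping parameter and area fitted in log
#' space (\eqn{\xi} bounded to \eqn{[10^{-4}, 10^3]} to cover its large
#' dynamic range). Initial values are derived from [detect_modes()] (peak
#' location, half-width at half-maximum, \eqn{\xi_0 = 0.5}) unless
#' supplied; three deterministic starts (the detected peak, and the peak
#' jittered by a quarter half-width with scaled \eqn{\xi_0}) guard against
#' local minima, and the lowest-loss solution is kept. With
#' `method = "mle"` the parameters instead maximize the likelihood of the
#' raw samples backing the histogram -- more efficient when heavy
#' Lorentzian tails make histogram least squares wasteful.
#'
#' Both components of a bimodal density are fitted jointly (overlapping
#' tails bias mode-by-mode fits); pass `mask` to restrict the fit to an
#' abscissa window and mimic a per-mode treatment.
#'
#' @param pdf An [empirical_pdf()]; for `method = "mle"` it must carry raw
#'   samples (see [histogram_pdf()]).
#' @param n_components 1 or 2 Voigt components.
#' @param init Optional initial parameter data frame / matrix with columns
#'   (center, gauss_width, xi, area), one row per component.
#' @param xi_bounds Bounds for \eqn{\xi} (default `c(1e-4, 1e3)`).
#' @param mask Optional `c(lo, hi)` abscissa window restricting the fit.
#' @param method `"ls"` (weighted least squares on densities, the default)
#'   or `"mle"` (maximum likelihood on raw samples).
#' @param reweight For histogram-backed least-squares fits, re-derive the
#'   per-bin uncertainties from the expected (fitted) counts and refit:
#'   observed-count weights over-weight downward fluctuations in sparse
#'   tail bins and bias \eqn{\xi} low (default `TRUE`).
#' @param max_iter Maximum optimizer iterations.
#' @return An object of class `voigt_fit`: `components` (list of
#'   [voigt_shape()]), `xi`, `xi_se` (delta-method standard errors), `loss`
#'   (weighted residual sum of squares, or negative log-likelihood for
#'   MLE), `converged` (maximum-iteration exits are reported as
#'   `FALSE`), `iterations`, `cov` (covariance of the transformed
#'   parameters), `method`.
#' @examples
#' sh <- voigt_shape(0, 1, 0.5)
#' x <- seq(-6, 6, length.out = 300)
#' fit <- fit_voigt(empirical_pdf(x, voigt_pdf(x, sh)))
#' fit$xi
#' @export
fit_voigt <- function(pdf, n_components = 1, init = NULL,
                      xi_bounds = c(1e-4, 1e3), mask = NULL,
                      method = c("ls", "mle"), reweight = TRUE,
                      max_iter = 200) {
  stopifnot(inherits(pdf, "empirical_pdf"), n_components %in% c(1, 2))
  method <- match.arg(method)
  m <- as.integer(n_components)
  x <- pdf$x; d <- pdf$density
  err <- pdf$err
  if (!is.null(mask)) {
    stopifnot(length(mask) == 2L, mask[1] < mask[2])
    keep <- x >= mask[1] & x <= mask[2]
    if (sum(keep) < 8 * m) stop("mask leaves too few points to fit")
    x <- x[keep]; d <- d[keep]
    if (!is.null(err)) err <- err[keep]
  }

  ## --- initial values ---------------------------------------------------
  if (is.null(init)) {
    modes <- detect_modes(pdf, prominence_fraction = 0.05)
    if (!is.null(mask))
      modes <- modes[modes$location >= mask[1] & modes$location <= mask[2], ,
                     drop = FALSE]
    if (nrow(modes) < m)
      stop(sprintf("detected %d mode(s) but %d component(s) requested; supply `init`",
                   nrow(modes), m))
    modes <- modes[order(-modes$prominence), , drop = FALSE][seq_len(m), ,
                                                             drop = FALSE]
    modes <- modes[order(modes$location), , drop = FALSE]
    total <- .trapz(x, d)
    init <- t(vapply(seq_len(m), function(k) {
      i <- which.min(abs(pdf$x - modes$location[k]))
      hw <- .hwhm_at(pdf$x, pdf$density, i)
      area_k <- if (m == 1) total else {
        cutpt <- mean(modes$location)
        if (k == 1) .trapz(x[x <= cutpt], d[x <= cutpt]) else
          .trapz(x[x >= cutpt], d[x >= cutpt])
      }
      c(modes$location[k], hw / .SQRT_LN2, 0.5, max(area_k, 1e-6))
    }, numeric(4)))
  } else {
    init <- as.matrix(init)
    if (nrow(init) != m || ncol(init) != 4)
      stop("`init` must have one row per component and 4 columns")
  }

  if (method == "mle") {
    return(.fit_voigt_mle(pdf, init, xi_bounds, max_iter))
  }

  wts <- if (!is.null(err)) 1 / pmax(err, max(err) * 1e-3)^2 else
    rep(1, length(x))
  sw <- sqrt(wts)
  ## Histogram bins report the average density over each bin, not the value
  ## at the midpoint; evaluating the model the same way (Simpson over the
  ## bin) removes the curvature bias that otherwise makes wide-binned peaks
  ## look flatter, i.e. more Lorentzian, than they are.
  dx <- diff(x)
  bin_avg <- !is.null(pdf$samples) &&
    (max(dx) - min(dx)) < 1e-8 * mean(dx)
  model_at <- if (bin_avg) {
    wbin0 <- dx[1]
    function(p) {
      pm <- .unpack_par(p, m)
      (.fit_model_eval(x - wbin0 / 2, pm) + 4 * .fit_model_eval(x, pm) +
         .fit_model_eval(x + wbin0 / 2, pm)) / 6
    }
  } else {
    function(p) .fit_model_eval(x, .unpack_par(p, m))
  }
  make_resid <- function(sw) function(p) {
    r <- sw * (model_at(p) - d)
    if (any(!is.finite(r))) stop("non-finite residuals during fit")
    r
  }
  resid_fn <- make_resid(sw)
  span <- diff(range(x))
  lower <- rep(c(min(x), log(span * 1e-4), log(xi_bounds[1]), -25), m)
  upper <- rep(c(max(x), log(span * 2), log(xi_bounds[2]), 25), m)

  starts <- list(init)
  jit <- init; jit[, 1] <- jit[, 1] - 0.25 * jit[, 2]; jit[, 3] <- 0.15
  starts[[2]] <- jit
  jit <- init; jit[, 1] <- jit[, 1] + 0.25 * jit[, 2]; jit[, 3] <- 1.5
  starts[[3]] <- jit

  best <- NULL
  for (s in starts) {
    p0 <- as.numeric(t(cbind(s[, 1], log(s[, 2]), log(pmin(pmax(s[, 3],
      xi_bounds[1] * 1.01), xi_bounds[2] * 0.99)), log(s[, 4]))))
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all fit starts failed")

  ## For histogram-backed densities the stored per-bin errors come from the
  ## observed counts, which over-weights downward fluctuations (zero-count
  ## bins carry the largest weights) and biases the tails -- and hence xi --
  ## low. Re-deriving the errors from the expected counts under the current
  ## fit (Pearson-style weights) and refitting removes that bias.
  if (reweight && !is.null(pdf$samples) && !is.null(err)) {
    wbin <- stats::median(diff(x))
    n_in <- sum(pdf$samples >= min(x) - wbin / 2 &
                  pdf$samples <= max(x) + wbin / 2)
    for (pass in 1:2) {
      expected <- pmax(model_at(best$par) * n_in * wbin, 0.5)
      swp <- (n_in * wbin) / sqrt(expected)
      res <- tryCatch(
        minpack.lm::nls.lm(best$par, lower = lower, upper = upper,
                           fn = make_resid(swp),
                           control = minpack.lm::nls.lm.control(
                             maxiter = max_iter, ftol = 1e-12,
                             ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(res)) break
      best <- res
    }
  }

  pm <- .unpack_par(best$par, m)
  comps <- lapply(seq_len(m), function(k)
    voigt_shape(pm[k, 1], pm[k, 2], pm[k, 3], pm[k, 4]))
  np <- length(best$par)
  dof <- max(length(x) - np, 1)
  sigma2 <- best$deviance / dof
  cov_t <- tryCatch(sigma2 * solve(best$hessian / 2),
                    error = function(e)
                      tryCatch(sigma2 * MASS::ginv(best$hessian / 2),
                               error = function(e2) NULL))
  xi_se <- rep(NA_real_, m)
  if (!is.null(cov_t)) {
    ix <- seq(3, 4 * m, 4)
    xi_se <- pm[, 3] * sqrt(pmax(diag(cov_t)[ix], 0))  # delta method, log scale
  }
  at_bound <- any(abs(best$par[seq(3, 4 * m, 4)] - log(xi_bounds[1])) < 1e-8 |
                  abs(best$par[seq(3, 4 * m, 4)] - log(xi_bounds[2])) < 1e-8)
  converged <- best$info %in% 1:3 && !at_bound
  if (at_bound) warning("fitted xi at its bound; fit flagged as not converged")
  structure(list(components = comps, xi = pm[, 3], xi_se = xi_se,
                 loss = best$deviance, converged = converged,
                 iterations = best$niter, cov = cov_t, method = "ls",
                 n_points = length(x)),
            class = "voigt_fit")
}

.fit_voigt_mle <- function(pdf, init, xi_bounds, max_iter) {
  s <- pdf$samples
  if (is.null(s)) stop("method = 'mle' needs raw samples in the empirical_pdf")
  m <- nrow(init)
  ## parameters: per component (center, log w, log xi) + (m-1) share logits
  pack0 <- as.numeric(t(cbind(init[, 1], log(init[, 2]), log(init[, 3]))))
  if (m == 2) {
    w1 <- init[1, 4] / sum(init[, 4])
    pack0 <- c(pack0, log(w1 / (1 - w1)))
  }
  nll <- function(p) {
    pm <- matrix(p[seq_len(3 * m)], ncol = 3, byrow = TRUE)
    wgt <- if (m == 2) { q <- plogis(p[3 * m + 1]); c(q, 1 - q) } else 1
    dens <- numeric(length(s))
    for (k in seq_len(m)) {
      sh <- voigt_shape(pm[k, 1], exp(pm[k, 2]), exp(pm[k, 3]), 1)
      dens <- dens + wgt[k] * voigt_pdf(s, sh)
    }
    -sum(log(pmax(dens, 1e-300)))
  }
  span <- diff(range(s))
  lower <- rep(c(min(s), log(span * 1e-5), log(xi_bounds[1])), m)
  upper <- rep(c(max(s), log(span), log(xi_bounds[2])), m)
  if (m == 2) { lower <- c(lower, -10); upper <- c(upper, 10) }
  opt <- stats::optim(pack0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, hessian = TRUE,
                      control = list(maxit = max_iter))
  pm <- matrix(opt$par[seq_len(3 * m)], ncol = 3, byrow = TRUE)
  wgt <- if (m == 2) { q <- plogis(opt$par[3 * m + 1]); c(q, 1 - q) } else 1
  comps <- lapply(seq_len(m), function(k)
    voigt_shape(pm[k, 1], exp(pm[k, 2]), exp(pm[k, 3]),
                if (m == 2) wgt[k] else 1))
  cov_t <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  xi <- exp(pm[, 3])
  xi_se <- rep(NA_real_, m)
  if (!is.null(cov_t))
    xi_se <- xi * sqrt(pmax(diag(cov_t)[seq(3, 3 * m, 3)], 0))
  structure(list(components = comps, xi = xi, xi_se = xi_se,
                 loss = opt$value, converged = opt$convergence == 0,
                 iterations = opt$counts[["function"]], cov = cov_t,
                 method = "mle", n_points = length(s)),
            class = "voigt_fit")
}

#' @export
print.voigt_fit <- function(x, ...) {
  cat(sprintf("<voigt_fit> %d component(s), method %s, %sconverged, loss %.4g\n",
              length(x$components), x$method,
              if (x$converged) "" else "NOT ", x$loss))
  for (k in seq_along(x$components)) {
    sh <- x$components[[k]]
    cat(sprintf("  [%d] center %.5g  gauss_width %.5g  xi %.5g (se %.2g)  area %.4g\n",
                k, sh$center, sh$gauss_width, sh$xi, x$xi_se[k], sh$area))
  }
  invisible(x)
}

#' @export
predict.voigt_fit <- function(object, x, ...) {
  out <- numeric(length(x))
  for (sh in object$components) out <- out + voigt_pdf(x, sh)
  out
}

#' Tabulate the line-damping parameter along a covariate
#'
#' Collects the fitted \eqn{\xi} (and its uncertainty) from a series of
#' fits indexed by a covariate -- residence time, temperature, lag -- into
#' one ordered table, the form in which \eqn{\xi} trends are inspected.
#'
#' @param covariate Numeric vector, one value per fit.
#' @param fits List of [fit_voigt()] / [fit_qens()] results (anything with
#'   `xi` and `xi_se` fields).
#' @param component Which component's \eqn{\xi} to tabulate (default 1).
#' @return A data frame `(covariate, xi, xi_se)` ordered by covariate.
#' @export
xi_trend <- function(covariate, fits, component = 1) {
  stopifnot(length(fits) >= 2, length(covariate) == length(fits))
  xi <- vapply(fits, function(f) f$xi[[component]], numeric(1))
  se <- vapply(fits, function(f) {
    v <- f$xi_se[[component]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  out <- data.frame(covariate = covariate, xi = xi, xi_se = se)
  out[order(out$covariate), , drop = FALSE]
}
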