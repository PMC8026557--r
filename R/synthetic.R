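## Seeded synthetic generators emulating the statistical structure of the
## molecular-dynamics and neutron-scattering inputs the fitting pipelines
## are built for: Voigt-distributed order-parameter noise, two-state
## (folded/unfolded) switching trajectories, overdamped diffusion of a
## dihedral-like angle on a circle, and noisy QENS spectra.

#' Draw samples from a Voigt distribution
#'
#' Uses the defining convolution: \eqn{X = x_0 + N + C} with
#' \eqn{N \sim \mathrm{Normal}(0, \sigma = \omega_G'/\sqrt{2})} and
#' \eqn{C} Cauchy with HWHM \eqn{\omega_L = \xi\,\omega_G'} drawn by the
#' inverse-CDF (tangent) method, so the samples follow [voigt_pdf()]
#' exactly.
#'
#' @param n Number of draws.
#' @param shape A [voigt_shape()] (its `area` is irrelevant for sampling).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` draws.
#' @examples
#' x <- gen_voigt_samples(1000, voigt_shape(0, sqrt(2), 0), seed = 1)
#' var(x)   # ~ 1
#' @export
gen_voigt_samples <- function(n, shape, seed = NULL) {
  stopifnot(inherits(shape, "voigt_shape"), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  x <- shape$center + rnorm(n, 0, shape$gauss_width / sqrt(2))
  if (shape$xi > 0)
    x <- x + shape$lorentz_hwhm * tan(pi * (runif(n) - 0.5))
  x
}

#' Two-state switching trajectory with Voigt-shaped state noise
#'
#' Emulates the radius-of-gyration time series of a protein hopping
#' between a folded and an unfolded state: a two-state Markov chain with
#' per-step switching probabilities, observed as the state level plus
#' per-state Voigt noise (so a ground-truth \eqn{\xi} exists for each mode
#' of the resulting bimodal distribution). Residence (dwell) times are
#' geometric by construction and returned for residence-time analyses.
#'
#' @param n_steps Trajectory length (\eqn{\ge 1}).
#' @param mu_folded,mu_unfolded Distinct state levels (e.g. Rg in nm).
#' @param k_unfold Per-step probability of leaving the folded state, in
#'   \eqn{[0, 1)}.
#' @param k_fold Per-step probability of leaving the unfolded state, in
#'   \eqn{[0, 1)}.
#' @param noise_folded,noise_unfolded [voigt_shape()]s describing the
#'   centered per-state observation noise (their `center` is ignored; the
#'   state levels position the modes).
#' @param start `"folded"` or `"unfolded"`.
#' @param seed Optional integer seed.
#' @return A list of class `two_state_traj`: `observation` (the noisy
#'   trajectory), `state` (`"folded"`/`"unfolded"` per step), `residence`
#'   (data frame `state`, `length`, `censored`; the final, truncated dwell
#'   is marked censored), and the generating parameters.
#' @examples
#' tr <- gen_two_state(5000, 1.0, 1.8, k_unfold = 0.01, k_fold = 0.01,
#'                     seed = 7)
#' @export
gen_two_state <- function(n_steps, mu_folded, mu_unfolded,
                          k_unfold, k_fold,
                          noise_folded = voigt_shape(0, 0.08, 0.3),
                          noise_unfolded = voigt_shape(0, 0.12, 0.5),
                          start = "folded", seed = NULL) {
  stopifnot(n_steps >= 1, mu_folded != mu_unfolded,
            k_unfold >= 0, k_unfold < 1, k_fold >= 0, k_fold < 1,
            inherits(noise_folded, "voigt_shape"),
            inherits(noise_unfolded, "voigt_shape"))
  start <- match.arg(start, c("folded", "unfolded"))
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_steps)

  ## alternating geometric dwells (exact holding-time construction)
  st <- character(0); len <- integer(0)
  cur <- start; total <- 0L
  while (total < n_steps) {
    k_out <- if (cur == "folded") k_unfold else k_fold
    dwell <- if (k_out == 0) n_steps - total else
      min(rgeom(1L, k_out) + 1L, n_steps - total)
    st <- c(st, cur); len <- c(len, dwell); total <- total + dwell
    cur <- if (cur == "folded") "unfolded" else "folded"
  }
  censored <- c(rep(FALSE, length(len) - 1L), TRUE)
  state <- rep(st, len)

  obs <- numeric(n_steps)
  fold <- state == "folded"
  nf <- sum(fold)
  if (nf) obs[fold] <- mu_folded +
    gen_voigt_samples(nf, voigt_shape(0, noise_folded$gauss_width,
                                      noise_folded$xi))
  if (n_steps - nf) obs[!fold] <- mu_unfolded +
    gen_voigt_samples(n_steps - nf, voigt_shape(0, noise_unfolded$gauss_width,
                                                noise_unfolded$xi))
  structure(list(observation = obs, state = state,
                 residence = data.frame(state = st, length = len,
                                        censored = censored),
                 params = list(mu_folded = mu_folded,
                               mu_unfolded = mu_unfolded,
                               k_unfold = k_unfold, k_fold = k_fold,
                               noise_folded = noise_folded,
                               noise_unfolded = noise_unfolded,
                               start = start, n_steps = n_steps,
                               seed = seed)),
            class = "two_state_traj")
}

#' @export
print.two_state_traj <- function(x, ...) {
  cat(sprintf("<two_state_traj> %d steps, %d dwell(s), fraction folded %.3f\n",
              length(x$observation), nrow(x$residence),
              mean(x$state == "folded")))
  invisible(x)
}

.potential_force <- function(potential, stiffness, depth) {
  switch(potential,
    free = list(force = function(th) 0 * th, curvature = 0),
    harmonic = list(force = function(th) -stiffness * th,
                    curvature = stiffness),
    double_well = list(force = function(th) -depth * sin(2 * th),
                       curvature = 2 * depth))
}

#' Angular increments of overdamped diffusion on a circle
#'
#' Euler-Maruyama simulation of an overdamped Langevin angle
#' \eqn{d\theta = -(D/k_BT)\,U'(\theta)\,dt + \sqrt{2D\,dt}\,\eta}, wrapped
#' to \eqn{(-\pi, \pi]}, emulating a coarse-grained backbone dihedral
#' \eqn{\gamma} built on four consecutive C-alpha atoms. The returned
#' quantity is the set of wrapped increments \eqn{\Delta\gamma} at lag `lag`
#' -- the rotation-probability samples whose distribution is fitted by the
#' Voigt profile. Harmonic wells give nearly Gaussian increments; deep
#' multi-well potentials add rare barrier hops, i.e. heavy tails.
#'
#' @param n_steps Number of post-burn-in steps (must exceed `lag`).
#' @param lag Increment lag \eqn{t} in steps (\eqn{\ge 1}).
#' @param D Diffusion coefficient (rad\eqn{^2}/step, > 0).
#' @param kT Thermal energy in the units of the potential (default 1).
#' @param potential `"free"`, `"harmonic"` (\eqn{U = k\theta^2/2}), or
#'   `"double_well"` (\eqn{U = (\mathrm{depth}/2)(1 - \cos 2\theta)}, wells
#'   at 0 and \eqn{\pi}).
#' @param stiffness Harmonic stiffness \eqn{k} (energy/rad\eqn{^2}).
#' @param depth Double-well barrier scale (energy units).
#' @param burn_in Burn-in steps; defaults to ten times the estimated
#'   relaxation time \eqn{k_BT/(D\,U'')} (1000 steps for free diffusion).
#' @param seed Optional integer seed.
#' @return A list of class `dihedral_sim`: `increments` (wrapped
#'   \eqn{\Delta\gamma} at the requested lag), `angles` (the post-burn-in
#'   trajectory), and the parameters. Errors if the Euler step is unstable
#'   (\eqn{D\,U''/k_BT \ge 0.1} per step).
#' @examples
#' sim <- gen_dihedral(20000, lag = 10, D = 0.01, potential = "harmonic",
#'                     stiffness = 1, seed = 3)
#' @export
gen_dihedral <- function(n_steps, lag, D, kT = 1,
                         potential = c("free", "harmonic", "double_well"),
                         stiffness = 1, depth = 2, burn_in = NULL,
                         seed = NULL) {
  potential <- match.arg(potential)
  stopifnot(n_steps > lag, lag >= 1, D > 0, kT > 0, stiffness > 0, depth > 0)
  pf <- .potential_force(potential, stiffness, depth)
  if (pf$curvature > 0 && D * pf$curvature / kT >= 0.1)
    stop(sprintf("unstable Euler step: D * curvature / kT = %.3g >= 0.1; reduce D",
                 D * pf$curvature / kT))
  if (is.null(burn_in))
    burn_in <- if (pf$curvature > 0)
      ceiling(10 * kT / (D * pf$curvature)) else 1000L
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_steps); burn_in <- as.integer(burn_in)
  ntot <- n_steps + burn_in
  sd_step <- sqrt(2 * D)
  wrap <- function(a) a - 2 * pi * ceiling(a / (2 * pi) - 0.5)  # -> (-pi, pi]
  if (potential == "free") {
    th <- wrap(cumsum(rnorm(ntot, 0, sd_step)))
  } else {
    th <- numeric(ntot)
    eta <- rnorm(ntot, 0, sd_step)
    cur <- 0
    mob <- D / kT
    for (i in seq_len(ntot)) {
      cur <- wrap(cur + mob * pf$force(cur) + eta[i])
      th[i] <- cur
    }
  }
  th <- th[(burn_in + 1L):ntot]
  inc <- wrap(th[(lag + 1L):n_steps] - th[1:(n_steps - lag)])
  structure(list(increments = inc, angles = th,
                 params = list(n_steps = n_steps, lag = lag, D = D, kT = kT,
                               potential = potential, stiffness = stiffness,
                               depth = depth, burn_in = burn_in,
                               seed = seed)),
            class = "dihedral_sim")
}

#' @export
print.dihedral_sim <- function(x, ...) {
  cat(sprintf("<dihedral_sim> %s potential, %d increments at lag %d, D = %g\n",
              x$params$potential, length(x$increments), x$params$lag,
              x$params$D))
  invisible(x)
}

#' Synthetic QENS spectrum with counting noise
#'
#' Evaluates [qens_spectrum()] on the grid and adds noise: by default
#' heteroscedastic Gaussian noise of standard deviation
#' \eqn{\sigma = \mathrm{noise}\cdot I + \mathrm{floor}} (the common
#' relative-error model of spectrometer exports; the floor, 1% of
#' `noise` times the peak intensity, keeps least-squares weights finite in
#' the far tails), or Poisson counting noise at a given count scale.
#'
#' @param omega Energy-transfer grid (meV), covering the elastic peak.
#' @param model A [qens_model()].
#' @param noise Relative noise level (\eqn{\ge 0}) for the Gaussian model.
#' @param noise_type `"relative"` or `"poisson"`.
#' @param count_scale Counts per intensity unit for the Poisson model.
#' @param seed Optional integer seed.
#' @return A data frame `(omega, intensity, err)`; with `noise = 0` the
#'   intensity is exactly the noiseless model and `err` is 1.
#' @examples
#' m <- qens_model(0.5, data.frame(weight = 0.5, hwhm = 0.1),
#'                 resolution_width = 0.0721)
#' sp <- gen_qens(seq(-2, 2, 0.005), m, noise = 0.02, seed = 11)
#' @export
gen_qens <- function(omega, model, noise = 0.02,
                     noise_type = c("relative", "poisson"),
                     count_scale = 1e4, seed = NULL) {
  noise_type <- match.arg(noise_type)
  stopifnot(noise >= 0, count_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  ideal <- qens_spectrum(omega, model)
  if (noise_type == "relative") {
    if (noise == 0) {
      return(data.frame(omega = omega, intensity = ideal,
                        err = rep(1, length(omega))))
    }
    sigma <- noise * ideal + 0.01 * noise * max(ideal)
    data.frame(omega = omega, intensity = ideal + rnorm(length(omega), 0,
                                                        sigma),
               err = sigma)
  } else {
    counts <- rpois(length(omega), count_scale * ideal)
    data.frame(omega = omega, intensity = counts / count_scale,
               err = sqrt(pmax(counts, 1)) / count_scale)
  }
}
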