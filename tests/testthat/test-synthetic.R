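test_that("Voigt sampling matches its construction and is reproducible", {
  ## pure Gaussian case: variance w^2/2
  x <- gen_voigt_samples(5e4, voigt_shape(0, sqrt(2), 0), seed = 11)
  se <- sqrt(2 / (length(x) - 1))          # sd of a normal variance estimate
  expect_lt(abs(var(x) - 1), 3 * se)
  expect_identical(x, gen_voigt_samples(5e4, voigt_shape(0, sqrt(2), 0),
                                        seed = 11))
  ## Voigt case: KS distance against the quadrature CDF of voigt_pdf
  sh <- voigt_shape(0, 1, 0.5)
  y <- gen_voigt_samples(1e5, sh, seed = 12)
  cdf <- ref_cdf_fun(sh, -60, 60)
  grid <- seq(-10, 10, length.out = 1001)
  ks <- max(abs(ecdf(y)(grid) - cdf(grid)))
  expect_lt(ks, 1.63 / sqrt(length(y)))    # 1% critical value
})

test_that("round-trip: sampling then fitting recovers the generating shape", {
  sh <- voigt_shape(1.3, 0.8, 0.9)
  s <- gen_voigt_samples(1e5, sh, seed = 21)
  fit <- fit_voigt(histogram_pdf(s, n_bins = 220, range = c(-8, 11)))
  expect_equal(fit$components[[1]]$center, 1.3, tolerance = 0.02)
  expect_equal(fit$components[[1]]$gauss_width, 0.8, tolerance = 0.05)
  expect_equal(fit$xi, 0.9, tolerance = 0.05)
})

test_that("two-state trajectories have the right stationary masses and dwells", {
  ## absorbing folded state: unimodal at mu_folded
  tr0 <- gen_two_state(5000, 1.0, 1.8, k_unfold = 0, k_fold = 0.1,
                       start = "folded", seed = 5)
  expect_true(all(tr0$state == "folded"))
  m <- detect_modes(histogram_pdf(tr0$observation, n_bins = 60,
                                  range = c(0, 2.6)),
                    prominence_fraction = 0.3)
  expect_equal(nrow(m), 1)
  expect_equal(m$location, 1.0, tolerance = 0.05)
  ## symmetric rates: equal masses within Monte-Carlo error; with dwell
  ## times ~100 steps the fraction has sd ~ sqrt(2 p q tau / n), so n = 1e6
  ## makes the 5% band a > 3 sigma check
  tr <- gen_two_state(1e6, 1.0, 1.8, k_unfold = 0.01, k_fold = 0.01,
                      seed = 6)
  expect_equal(mean(tr$state == "folded"), 0.5, tolerance = 0.05)
  ## geometric dwell times: mean ~ 1/k and chi-square GOF not rejected at 1%
  tr2 <- gen_two_state(1e6, 1.0, 1.8, k_unfold = 0.01, k_fold = 0.05,
                       seed = 8)
  dw <- tr2$residence
  fold_dw <- dw$length[dw$state == "folded" & !dw$censored]
  expect_equal(mean(fold_dw), 100, tolerance = 0.05)
  brk <- c(seq(0, 400, by = 50), Inf)
  obs <- table(cut(fold_dw, brk))
  p_geom <- diff(pgeom(brk - 1, 0.01))   # dwell = 1 + geometric
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = p_geom,
                                     rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
  ## reproducibility
  expect_identical(tr$observation,
                   gen_two_state(1e6, 1.0, 1.8, k_unfold = 0.01,
                                 k_fold = 0.01, seed = 6)$observation)
})

test_that("free circular diffusion has increment variance 2 D t", {
  sim <- gen_dihedral(2e4, lag = 5, D = 0.01, potential = "free", seed = 3)
  expect_lt(abs(var(sim$increments) - 2 * 0.01 * 5) / (2 * 0.01 * 5), 0.05)
  expect_true(all(sim$increments > -pi & sim$increments <= pi))
  expect_identical(sim$increments,
                   gen_dihedral(2e4, lag = 5, D = 0.01, potential = "free",
                                seed = 3)$increments)
})

test_that("harmonic-well diffusion equilibrates to the Boltzmann angle law", {
  sim <- gen_dihedral(2e5, lag = 10, D = 0.02, potential = "harmonic",
                      stiffness = 1, kT = 0.25, seed = 9)
  ## stationary sd = sqrt(kT/k) = 0.5; subsample beyond the relaxation time
  th <- sim$angles[seq(1, length(sim$angles), by = 150)]
  ks <- suppressWarnings(ks.test(th, "pnorm", 0, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("deep double wells give heavy-tailed increments", {
  sim <- gen_dihedral(2e5, lag = 40, D = 0.02, potential = "double_well",
                      depth = 2, kT = 1, seed = 13)
  z <- sim$increments
  kurt <- mean((z - mean(z))^4) / var(z)^2 - 3
  expect_gt(kurt, 0)
  ## and an unstable Euler step errors out
  expect_error(gen_dihedral(1000, 5, D = 0.1, potential = "double_well",
                            depth = 2, kT = 1), "unstable")
})

test_that("more frequent long jumps raise the fitted xi of the unfolded mode", {
  ## end-to-end trend: two-state trajectories whose unfolded-state noise
  ## carries a growing Lorentzian (long-jump) contribution yield a growing
  ## fitted xi for that mode
  xi_unf <- c(0.15, 0.45, 0.9)
  fitted_xi <- vapply(seq_along(xi_unf), function(i) {
    tr <- gen_two_state(6e4, 1.0, 1.8, k_unfold = 0.01, k_fold = 0.01,
                        noise_folded = voigt_shape(0, 0.08, 0.2),
                        noise_unfolded = voigt_shape(0, 0.12, xi_unf[i]),
                        seed = 60 + i)
    fit <- fit_voigt(histogram_pdf(tr$observation, n_bins = 200),
                     n_components = 2)
    fit$components[[2]]$xi
  }, numeric(1))
  expect_true(all(diff(fitted_xi) > 0))
  expect_equal(fitted_xi, xi_unf, tolerance = 0.2)
})

test_that("synthetic spectra carry the stated noise model", {
  w <- gauss_width_from_fwhm(0.12)
  m <- qens_model(0.5, data.frame(weight = 0.5, hwhm = 0.1),
                  resolution_width = w)
  om <- seq(-2, 2, length.out = 801)
  sp0 <- gen_qens(om, m, noise = 0)
  expect_identical(sp0$intensity, qens_spectrum(om, m))
  sp <- gen_qens(om, m, noise = 0.02, seed = 4)
  expect_identical(sp, gen_qens(om, m, noise = 0.02, seed = 4))
  ideal <- qens_spectrum(om, m)
  z <- (sp$intensity - ideal) / sp$err
  expect_lt(abs(sd(z) - 1), 0.1)           # residuals standardized by err
  spp <- gen_qens(om, m, noise_type = "poisson", count_scale = 2e4, seed = 5)
  expect_true(all(spp$intensity >= 0))
  zp <- (spp$intensity - ideal) / spp$err
  expect_lt(abs(sd(zp) - 1), 0.1)
})
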