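test_that("histogram densities integrate to one and estimate known peaks", {
  set.seed(101)
  s <- rnorm(1e5)
  p <- histogram_pdf(s, n_bins = 50)
  expect_s3_class(p, "empirical_pdf")
  expect_equal(trapz(p$x, p$density), 1, tolerance = 1e-9)
  expect_equal(max(p$density), dnorm(0), tolerance = 0.05)
  ## unit area holds for arbitrary input
  p2 <- histogram_pdf(rexp(500), n_bins = 12)
  expect_equal(trapz(p2$x, p2$density), 1, tolerance = 1e-9)
  expect_error(histogram_pdf(rnorm(50)), "at least 100")
  expect_error(histogram_pdf(rep(1, 500)), "degenerate")
})

test_that("empirical_pdf validates its grid and densities", {
  expect_error(empirical_pdf(c(1, 1, 2), c(0, 1, 0)), "strictly increasing")
  expect_error(empirical_pdf(1:3, c(-1, 0, 1)), "non-negative")
  expect_error(empirical_pdf(1:3, c(0, 1, 0), err = c(1, 0, 1)), "err")
})

test_that("mode detection separates unimodal from bimodal densities", {
  x <- seq(-6, 6, length.out = 400)
  one <- empirical_pdf(x, voigt_pdf(x, voigt_shape(0.5, 1, 0.4)))
  m1 <- detect_modes(one)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$location, 0.5, tolerance = 0.05)
  ## two well-separated components (|x01 - x02| > 4 w)
  x2 <- seq(-10, 10, length.out = 600)
  d2 <- voigt_pdf(x2, voigt_shape(-3, 1, 0.3, area = 0.5)) +
    voigt_pdf(x2, voigt_shape(3, 1, 0.3, area = 0.5))
  m2 <- detect_modes(empirical_pdf(x2, d2))
  expect_equal(nrow(m2), 2)
  expect_equal(m2$location, c(-3, 3), tolerance = 0.05)
  flat <- empirical_pdf(x, rep(0.1, length(x)))
  expect_error(detect_modes(flat), "mode")
})

test_that("a noiseless single Voigt curve is recovered to optimizer precision", {
  sh <- voigt_shape(0, 1, 0.5)
  x <- seq(-8, 8, length.out = 400)
  fit <- fit_voigt(empirical_pdf(x, voigt_pdf(x, sh)))
  expect_true(fit$converged)
  est <- fit$components[[1]]
  expect_equal(est$center, 0, tolerance = 1e-4)
  expect_equal(est$gauss_width, 1, tolerance = 1e-4)
  expect_equal(est$xi, 0.5, tolerance = 1e-4)
  expect_equal(est$area, 1, tolerance = 1e-4)
  expect_lt(fit$loss, 1e-10)
  ## predictions reproduce the curve
  expect_lt(max(abs(predict(fit, x) - voigt_pdf(x, sh))), 1e-6)
})

test_that("xi is recovered from sampled Normal-plus-Cauchy data", {
  ## X = Normal(sd sigma) + Cauchy(HWHM gL) is Voigt with w = sigma sqrt(2),
  ## xi = gL / (sigma sqrt(2))
  sigma <- 1; gL <- 0.5
  set.seed(2024)
  s <- rnorm(1e5, 0, sigma) + gL * tan(pi * (runif(1e5) - 0.5))
  p <- histogram_pdf(s, n_bins = 200, range = c(-15, 15))
  fit <- fit_voigt(p)
  xi_true <- gL / (sigma * sqrt(2))
  expect_equal(fit$xi, xi_true, tolerance = 0.05)
  expect_true(fit$converged)
  expect_true(is.finite(fit$xi_se) && fit$xi_se > 0)
  ## the likelihood route agrees on the same draws
  fit_ml <- fit_voigt(p, method = "mle")
  expect_equal(fit_ml$xi, xi_true, tolerance = 0.05)
})

test_that("joint two-component fits recover both modes of a bimodal density", {
  sh1 <- voigt_shape(1.0, 0.35, 0.3, area = 0.55)
  sh2 <- voigt_shape(3.0, 0.5, 0.8, area = 0.45)
  set.seed(77)
  n <- 1e5
  pick <- runif(n) < 0.55
  s <- ifelse(pick, gen_voigt_samples(n, sh1), gen_voigt_samples(n, sh2))
  p <- histogram_pdf(s, n_bins = 250, range = c(-3, 8))
  fit <- fit_voigt(p, n_components = 2)
  expect_true(fit$converged)
  expect_equal(fit$components[[1]]$xi, 0.3, tolerance = 0.1)
  expect_equal(fit$components[[2]]$xi, 0.8, tolerance = 0.1)
  expect_equal(fit$components[[1]]$center, 1.0, tolerance = 0.05)
  expect_equal(fit$components[[2]]$center, 3.0, tolerance = 0.05)
  ## masked single-mode fit around the first mode finds it, but the second
  ## mode's tail leaking into the window biases xi upward -- the reason the
  ## joint fit is the default
  fitm <- fit_voigt(p, n_components = 1, mask = c(-1, 2))
  expect_equal(fitm$components[[1]]$center, 1.0, tolerance = 0.05)
  expect_gt(fitm$xi, 0.15)
  expect_lt(fitm$xi, 0.7)
})

test_that("fits are invariant under a change of abscissa units", {
  sh <- voigt_shape(2, 0.5, 0.7)
  x <- seq(-3, 7, length.out = 350)
  p1 <- empirical_pdf(x, voigt_pdf(x, sh))
  scale <- 1000   # e.g. nm -> pm
  p2 <- empirical_pdf(x * scale, voigt_pdf(x, sh) / scale)
  f1 <- fit_voigt(p1); f2 <- fit_voigt(p2)
  expect_equal(f2$xi, f1$xi, tolerance = 1e-6)
  expect_equal(f2$components[[1]]$center,
               f1$components[[1]]$center * scale, tolerance = 1e-4)
  expect_equal(f2$components[[1]]$gauss_width,
               f1$components[[1]]$gauss_width * scale, tolerance = 1e-3)
})

test_that("xi_trend tabulates and orders fitted parameters", {
  sh <- voigt_shape(0, 1, 0.5)
  x <- seq(-8, 8, length.out = 200)
  f <- fit_voigt(empirical_pdf(x, voigt_pdf(x, sh)))
  tab <- xi_trend(c(330, 300), list(f, f))
  expect_equal(tab$covariate, c(300, 330))
  expect_equal(tab$xi[1], tab$xi[2])
  expect_error(xi_trend(1, list(f)), "fits")
})
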