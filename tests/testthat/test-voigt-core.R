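test_that("reduced coordinates center, scale and reject bad input", {
  sh <- voigt_shape(center = 2, gauss_width = 0.5, xi = 0.3)
  expect_equal(reduce_abscissa(2, sh), 0)
  expect_equal(reduce_abscissa(2.5, sh), 1)
  expect_equal(reduce_abscissa(1, sh), -2)
  expect_error(reduce_abscissa(NaN, sh), "finite")
  expect_error(voigt_shape(gauss_width = -1), "gauss_width")
  expect_error(voigt_shape(xi = -0.1), "xi")
  expect_error(voigt_shape(area = 0), "area")
  expect_equal(voigt_shape(0, 2, 0.5)$lorentz_hwhm, 1)
  expect_equal(voigt_shape(0, 1, 0)$gauss_hwhm, sqrt(log(2)))
})

test_that("oracle quadrature reproduces closed-form anchors in all three forms", {
  expect_equal(voigt_oracle(0, 0), 1 / sqrt(pi), tolerance = 1e-10)
  expect_equal(voigt_oracle(0, 1), ref_peak(1), tolerance = 1e-10)
  expect_equal(voigt_oracle(2, 0), exp(-4) / sqrt(pi), tolerance = 1e-10)
  ## the Gaussian-Lorentzian convolution form and the scaled cosine form
  ## agree with the default cosine form
  for (xi in c(0.1, 1, 3)) {
    v <- c(0, 0.7, 2.5)
    base <- voigt_oracle(v, xi)
    expect_equal(voigt_oracle(v, xi, form = "lorentzian"), base,
                 tolerance = 1e-8)
    expect_equal(voigt_oracle(v, xi, form = "scaled"), base,
                 tolerance = 1e-8)
  }
  expect_error(voigt_oracle(0, 0, form = "lorentzian"), "xi > 0")
  expect_error(voigt_oracle(0, 1, rel_tol = 1), "rel_tol")
})

test_that("series evaluator matches the quadrature oracle and peak law", {
  for (xi in c(0.001, 0.05, 0.4, 1, 3, 7)) {
    v <- seq(-5, 5, by = 1.25)
    expect_lt(max(abs(voigt_series(v, xi) - voigt_oracle(v, xi))), 1e-9)
  }
  ## peak law V(0, xi) = e^{xi^2} erfc(xi)/sqrt(pi) across the series domain
  for (xi in c(0, 1e-8, 1e-4, 0.02, 0.7, 2, 5, 9, 10))
    expect_lt(abs(voigt_series(0, xi) - ref_peak(xi)), 1e-10)
  ## peaks strictly decrease with xi
  pk <- sapply(c(0, 0.01, 0.1, 0.5, 1, 2, 5, 10), function(x) voigt_series(0, x))
  expect_true(all(diff(pk) < 0))
  expect_error(voigt_series(Inf, 1), "finite")
  expect_error(voigt_series(0, -1), "xi")
  expect_error(voigt_series(0, 1, tol = 1e-3), "tol")
})

test_that("all evaluators are structurally symmetric and unimodal in |v|", {
  v <- seq(0.1, 6, by = 0.37)
  for (xi in c(0, 0.3, 1, 4)) {
    expect_identical(voigt_series(v, xi), voigt_series(-v, xi))
    expect_identical(voigt(v, 12, "faddeeva"), voigt(-v, 12, "faddeeva"))
    expect_identical(as.numeric(voigt_gauss_dominant(v, xi)),
                     as.numeric(voigt_gauss_dominant(-v, xi)))
    vv <- seq(0, 8, by = 0.1)
    expect_true(all(diff(voigt_series(vv, xi)) <= 0))
  }
})

test_that("profiles integrate to one with explicit tail treatment", {
  for (xi in c(0, 0.01, 0.1, 1, 10)) {
    area <- even_density_area(function(v) voigt(v, xi))
    expect_equal(area, 1, tolerance = 1e-6)
  }
})

test_that("Gaussian and Lorentzian limits are reached", {
  v <- seq(-4, 4, by = 0.25)
  expect_lt(max(abs(voigt_series(v, 1e-9) - exp(-v^2) / sqrt(pi))), 1e-8)
  expect_identical(voigt_series(v, 0), exp(-v^2) / sqrt(pi))
  ## rescaled large-xi shape: xi * V(xi*u, xi) -> (1/pi)/(1+u^2)
  u <- seq(-3, 3, by = 0.2)
  for (xi in c(20, 50)) {
    resc <- xi * voigt(xi * u, xi)
    expect_lt(max(abs(resc - (1 / pi) / (1 + u^2))), 0.01 / pi)
  }
  sup50 <- max(abs(50 * voigt(50 * u, 50) - (1 / pi) / (1 + u^2)) /
                 ((1 / pi) / (1 + u^2)))
  expect_lt(sup50, 0.01)
})

test_that("profile equals the numerical Gaussian-Lorentzian convolution", {
  ## defining property: unit-area Gaussian (1/e half-width w) convolved
  ## with unit-area Lorentzian (HWHM xi*w)
  w <- 1; xi <- 0.5
  dx <- 0.005
  x <- seq(-60, 60, by = dx)
  g <- exp(-(x / w)^2) / (w * sqrt(pi))
  l <- (xi * w / pi) / (x^2 + (xi * w)^2)
  conv <- convolve(g, rev(l), type = "open") * dx
  xc <- seq(-120, 120, by = dx)[seq_along(conv)]
  keep <- abs(xc) <= 3
  expect_lt(max(abs(conv[keep] -
                      voigt_pdf(xc[keep], voigt_shape(0, w, xi)))), 2e-4)
})

test_that("Faddeeva function satisfies its defining identities", {
  expect_equal(faddeeva_w(0 + 0i), 1 + 0i, tolerance = 1e-13)
  ## on the imaginary axis W(i xi) = erfcx(xi), real
  for (xi in c(0.5, 1, 5, 20))
    expect_equal(Re(faddeeva_w(complex(imaginary = xi))),
                 pracma::erfcx(xi), tolerance = 1e-12)
  ## on the real axis W(t) = e^{-t^2} + 2i F(t)/sqrt(pi)
  t <- c(0.3, 1, 2.5)
  wt <- faddeeva_w(complex(real = t))
  expect_equal(Re(wt), exp(-t^2), tolerance = 1e-12)
  expect_equal(Im(wt), 2 * dawson(t) / sqrt(pi), tolerance = 1e-12)
  ## Re W(v + i xi) = sqrt(pi) V(v, xi) against the independent oracle
  for (xi in c(0.2, 1, 12)) {
    v <- c(0, 1, 3.5)
    expect_equal(Re(faddeeva_w(complex(real = v, imaginary = rep(xi, 3)))) /
                   sqrt(pi),
                 voigt_oracle(v, xi), tolerance = 1e-9)
  }
  expect_error(faddeeva_w(1 - 1i), "upper half-plane")
})

test_that("Dawson function is odd with the known maximum and values", {
  expect_identical(dawson(0), 0)
  t <- c(0.2, 0.924, 1, 3, 8)
  expect_identical(dawson(-t), -dawson(t))
  expect_equal(dawson(1), 0.538079506912768, tolerance = 1e-12)
  ## maximum near t = 0.924
  tt <- seq(0.5, 1.5, by = 0.001)
  expect_equal(tt[which.max(dawson(tt))], 0.924, tolerance = 1e-2)
})

test_that("limiting approximations hit their closed-form anchors", {
  expect_equal(as.numeric(voigt_gauss_dominant(0, 0)), 1 / sqrt(pi))
  expect_equal(as.numeric(voigt_gauss_dominant_small(0, 0)), 1 / sqrt(pi))
  ## peak of the near-maximum form equals erfcx(xi)/sqrt(pi) exactly
  expect_equal(as.numeric(voigt_gauss_dominant(0, 0.2)), ref_peak(0.2),
               tolerance = 1e-12)
  expect_equal(as.numeric(voigt_gauss_dominant(0, 0.2)), 0.4564404,
               tolerance = 1e-7)
  ## the two Gaussian-dominance forms agree at v = 0 by construction
  expect_equal(as.numeric(voigt_gauss_dominant_small(0.2, 0.05)),
               as.numeric(voigt_gauss_dominant(0.2, 0.05)), tolerance = 1e-4)
  ## Lorentzian-dominance tail form at the peak
  expect_equal(as.numeric(voigt_lorentz_tail(0, 50)), 1 / (50 * pi),
               tolerance = 1e-10)
  expect_equal(as.numeric(voigt_lorentz_tail(0, 50)), 0.0063662,
               tolerance = 1e-5)
  ## intermediate form within 1% of the oracle at its regime edge
  expect_rel_error(as.numeric(voigt_lorentz_dominant_sum(0, 10)),
                   voigt_oracle(0, 10), 0.01)
  expect_error(voigt_lorentz_dominant_sum(0, 0), "undefined")
  expect_error(voigt_lorentz_tail(0, 0), "undefined")
  ## out-of-regime use is flagged, not blocked
  expect_false(attr(voigt_gauss_dominant(3, 0.1), "in_regime")[1])
  expect_true(attr(voigt_lorentz_tail(0, 50), "in_regime")[1])
})

test_that("approximation errors stay below the committed bound table", {
  tab <- read.csv(system.file("extdata", "approx_error_bounds.csv",
                              package = "voigtline"), comment.char = "#")
  fns <- list(gauss = voigt_gauss_dominant, gauss_small = voigt_gauss_dominant_small,
              lorentz_sum = voigt_lorentz_dominant_sum, lorentz_tail = voigt_lorentz_tail)
  for (i in seq_len(nrow(tab))) {
    form <- as.character(tab$form[i])
    v <- if (form %in% c("gauss", "gauss_small")) seq(0, tab$v_max[i], by = 0.025)
         else if (form == "lorentz_sum") seq(0, tab$v_max[i], by = 0.5)
         else seq(0, tab$v_max[i], length.out = 26)
    err <- max(abs(as.numeric(fns[[form]](v, tab$xi[i])) -
                     voigt_oracle(v, tab$xi[i])) / voigt_oracle(v, tab$xi[i]))
    expect_lt(err, tab$max_rel_err[i])
  }
})

test_that("physical-units wrapper scales, shifts and normalizes correctly", {
  sh <- voigt_shape(0, 2, 0, area = 1)
  expect_equal(voigt_pdf(0, sh), 1 / (2 * sqrt(pi)))
  sh2 <- voigt_shape(1.5, 0.7, 0.8, area = 2.5)
  area <- even_density_area(function(v) voigt_pdf(v + 1.5, sh2))
  expect_equal(area, 2.5, tolerance = 1e-6)
  x <- seq(-2, 5, by = 0.3)
  shifted <- voigt_shape(1.5 + 3, 0.7, 0.8, area = 2.5)
  expect_equal(voigt_pdf(x, sh2), voigt_pdf(x + 3, shifted),
               tolerance = 1e-13)
})

test_that("front-end dispatch honors method aliases and regime router", {
  v <- seq(-2, 2, by = 0.5)
  expect_identical(voigt(v, 0.5, "gauss"), voigt_gauss_dominant(v, 0.5))
  expect_identical(voigt(v, 2, "lorentz_tail"), voigt_lorentz_tail(v, 2))
  expect_equal(voigt(v, 15), voigt_oracle(v, 15), tolerance = 1e-10)
  out <- voigt_regime(seq(-8, 8, by = 0.5), 2)
  expect_true(all(attr(out, "method") %in% c("lorentz_sum", "lorentz_tail")))
  expect_lt(max(abs(out - voigt_oracle(seq(-8, 8, by = 0.5), 2)) /
                  voigt_oracle(seq(-8, 8, by = 0.5), 2)), 0.05)
  out2 <- voigt_regime(c(0, 5), 0.1)
  expect_identical(attr(out2, "method"), c("gauss", "series"))
})
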