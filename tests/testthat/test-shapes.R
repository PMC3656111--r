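test_that("circles have the textbook area and circumference", {
  sh <- make_circle(2.5)
  expect_identical(nrow(sh$harmonics), 0L)
  expect_equal(shape_area(sh), pi * 2.5^2)
  expect_equal(shape_circumference(make_circle(1)), 2 * pi, tolerance = 1e-8)
  expect_error(make_circle(0), "positive")
  expect_error(make_circle(-1), "positive")
})

test_that("clover-leaf construction covers the stated special cases", {
  expect_equal(make_cloverleaf(5, 0, R0 = 1.7), make_circle(1.7))
  sh <- make_cloverleaf(5, 0.2, R0 = 2)
  th <- seq(0, 2 * pi, length.out = 100001L)
  expect_equal(min(radius_profile(sh, th)), 0.8 * 2, tolerance = 1e-7)
  expect_equal(radius_profile(sh, pi / 5), 0.8 * 2)
  # closed-form area pi R0^2 (1 + eps^2/2) against quadrature
  sh6 <- make_cloverleaf(6, 0.2, R0 = 1.3)
  expect_equal(shape_area(sh6), pi * 1.3^2 * 1.02, tolerance = 1e-12)
  expect_equal(shape_area(sh6), area_quadrature(sh6), tolerance = 1e-8)
  expect_error(make_cloverleaf(5, 1.0), "eps")
  expect_error(make_cloverleaf(1, 0.1), "symmetry order")
})

test_that("polygon harmonics live at multiples of P and match a dense DFT", {
  g <- make_ngon(4, 2)
  expect_identical(g$harmonics$n, c(4L, 8L))
  expect_identical(g$symmetry_order, 4L)
  # dense-DFT oracle on the exact polygon radius function (the kinked
  # radius makes DFT aliasing decay like N^-2, so sample densely)
  N <- 65536L
  th <- 2 * pi * (0:(N - 1L)) / N
  rg <- cos(pi / 4) / cos((th %% (pi / 2)) - pi / 4)
  a0 <- mean(rg)
  for (k in 1:2) {
    ak <- 2 * mean(rg * cos(4 * k * th))
    expect_equal(g$harmonics$c[k], ak / a0, tolerance = 1e-6)
  }
  expect_equal(g$R0, a0, tolerance = 1e-6)
  # higher symmetry lies closer to the circle
  emax <- function(P) max(abs(eps_profile(make_ngon(P, 1),
                                          seq(0, 2 * pi, length.out = 4096))))
  expect_lt(emax(12), emax(4))
  expect_error(make_ngon(2), "P >= 3")
})

test_that("polygon truncation error decreases monotonically with retained multiples", {
  th <- seq(0, 2 * pi, length.out = 8192)
  exact <- cos(pi / 5) / cos((th %% (2 * pi / 5)) - pi / 5)
  dev <- vapply(1:4, function(mm) {
    g <- make_ngon(5, mm)
    max(abs(radius_profile(g, th) - exact))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("the closed-form area matches quadrature for randomized shapes", {
  set.seed(11)
  for (i in 1:8) {
    ns <- sample(1:9, sample(1:4, 1))
    h <- data.frame(n = ns, c = runif(length(ns), -0.08, 0.08),
                    s = runif(length(ns), -0.08, 0.08))
    sh <- boundary_shape(runif(1, 1, 4), h)
    expect_equal(shape_area(sh), area_quadrature(sh), tolerance = 1e-8)
  }
})

test_that("area examples with one and two harmonics match the Parseval form", {
  sh1 <- boundary_shape(1, data.frame(n = 5, c = 0.3, s = 0))
  expect_equal(shape_area(sh1), pi * 1.045, tolerance = 1e-12)
  expect_equal(shape_area(sh1), area_quadrature(sh1), tolerance = 1e-8)
  sh2 <- boundary_shape(1, data.frame(n = c(4, 8), c = c(0.1, 0.05), s = c(0, 0)))
  expect_equal(shape_area(sh2), pi * 1.00625, tolerance = 1e-12)
})

test_that("circumference obeys the isoperimetric bound and a brute-force sum", {
  sh <- boundary_shape(1, data.frame(n = 5, c = 0.2, s = 0))
  c_eq <- 2 * pi * sqrt(shape_area(sh) / pi)
  expect_gt(shape_circumference(sh), c_eq)
  sh4 <- boundary_shape(1, data.frame(n = 4, c = 0.1, s = 0))
  n <- 1e6
  th <- 2 * pi * (0:(n - 1)) / n
  r <- radius_profile(sh4, th)
  dr <- 0.1 * 4 * (-sin(4 * th))
  brute <- sum(sqrt(r^2 + dr^2)) * 2 * pi / n
  expect_equal(shape_circumference(sh4), brute, tolerance = 1e-7)
})

test_that("size normalization is exact, idempotent, and harmonic-preserving", {
  expect_equal(scale_to_area(make_circle(3), pi)$R0, 1, tolerance = 1e-14)
  sh <- boundary_shape(1, data.frame(n = 5, c = 0.3, s = 0))
  sc <- scale_to_area(sh, pi)
  expect_equal(sc$R0, 1.045^-0.5, tolerance = 1e-12)
  expect_equal(shape_area(sc), pi, tolerance = 1e-12)
  expect_equal(scale_to_area(sc, pi), sc)
  expect_identical(sc$harmonics, sh$harmonics)
  # circumference analogue
  cs <- scale_to_circumference(sh, 5)
  expect_equal(shape_circumference(cs), 5, tolerance = 1e-8)
  expect_equal(scale_to_circumference(cs, 5)$R0, cs$R0, tolerance = 1e-10)
  expect_equal(scale_to_circumference(make_circle(2), 2 * pi)$R0, 1,
               tolerance = 1e-10)
})

test_that("rotating the harmonics leaves area and circumference unchanged", {
  sh <- boundary_shape(2, data.frame(n = c(3, 7), c = c(0.1, -0.04), s = c(0.05, 0.02)))
  rot <- rotate_shape(sh, 1.234)
  expect_equal(shape_area(rot), shape_area(sh), tolerance = 1e-13)
  expect_equal(shape_circumference(rot), shape_circumference(sh), tolerance = 1e-9)
  # rotation really moves the profile
  expect_gt(max(abs(radius_profile(rot, 0:6) - radius_profile(sh, 0:6))), 1e-3)
})

test_that("invalid shapes are rejected and large deviations are flagged", {
  expect_error(boundary_shape(1, data.frame(n = 2, c = 1.2, s = 0)), "positive")
  expect_error(boundary_shape(1, data.frame(n = c(2, 2), c = c(0.1, 0.1), s = 0)),
               "distinct")
  expect_error(boundary_shape(1, data.frame(n = 0, c = 0.1, s = 0)), ">= 1")
  expect_warning(boundary_shape(1, data.frame(n = 3, c = 0.4, s = 0)), "validity")
})

test_that("fit_fourier recovers band-limited shapes exactly", {
  sh <- make_cloverleaf(5, 0.23, R0 = 2)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  fit <- fit_fourier(th, radius_profile(sh, th), n_max = 8)
  expect_equal(fit$R0, 2, tolerance = 1e-10)
  c5 <- fit$harmonics$c[fit$harmonics$n == 5]
  expect_equal(c5, 0.23, tolerance = 1e-10)
  others <- abs(c(fit$harmonics$c[fit$harmonics$n != 5], fit$harmonics$s))
  expect_lt(max(others), 1e-10)
  expect_lt(fit$meta$fit_rms_nm, 1e-10)
})

test_that("fit_fourier noise behavior follows least-squares theory", {
  # sd of each recovered Fourier amplitude is sigma * sqrt(2/N); check the
  # Monte-Carlo RMS against theory and the bias against its standard error
  sh <- make_cloverleaf(5, 0.23, R0 = 2)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r0 <- radius_profile(sh, th)
  sigma <- 0.01 * 2
  set.seed(99)
  cs <- vapply(1:100, function(i) {
    fit <- fit_fourier(th, r0 + rnorm(length(th), 0, sigma), n_max = 8)
    fit$harmonics$c[fit$harmonics$n == 5] * fit$R0
  }, numeric(1))
  theo_sd <- sigma * sqrt(2 / length(th))
  expect_lt(abs(mean(cs) - 0.23 * 2), 4 * theo_sd / sqrt(100))
  expect_lt(sd(cs), 1.6 * theo_sd)
  expect_gt(sd(cs), 0.6 * theo_sd)
})

test_that("fit_fourier rejects degenerate sampling", {
  expect_error(fit_fourier(rep(1, 50), rep(2, 50), n_max = 3), "span")
  expect_error(fit_fourier(c(0, 1), c(1, 1), n_max = 3), "samples")
  expect_error(fit_fourier(seq(0, 6, length.out = 20), rep(-1, 20), n_max = 3),
               "positive")
})
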