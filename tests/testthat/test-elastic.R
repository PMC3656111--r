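test_that("Helmholtz roots satisfy their quadratic in every tension regime", {
  for (tau in c(0, 0.5, 2, 60)) {
    p <- std_params(tau)
    rt <- helmholtz_roots(p)
    for (nu in c(rt$nu_plus, rt$nu_minus)) {
      resid <- p$Kb * nu^2 - p$tau * nu + p$Kt / p$leaflet_l^2
      expect_lt(Mod(resid), 1e-12 * (p$Kt / p$leaflet_l^2))
    }
    # Vieta: sum and product reproduce the quadratic's coefficients
    expect_equal(rt$nu_plus + rt$nu_minus, as.complex(tau / p$Kb), tolerance = 1e-12)
    expect_equal(rt$nu_plus * rt$nu_minus,
                 as.complex(p$Kt / (p$Kb * p$leaflet_l^2)), tolerance = 1e-12)
    # decay: sqrt(nu) in the right half plane
    expect_gt(Re(rt$k_plus), 0)
    expect_gt(Re(rt$k_minus), 0)
  }
})

test_that("roots are a conjugate pair at zero tension and real at extreme tension", {
  rt0 <- helmholtz_roots(std_params(0))
  expect_equal(rt0$nu_plus, Conj(rt0$nu_minus), tolerance = 1e-14)
  expect_equal(Re(rt0$nu_plus + rt0$nu_minus), 0, tolerance = 1e-14)
  # discriminant turns positive above tau = 2 sqrt(Kb Kt)/l ~ 46.6 kBT/nm^2
  rt_hi <- helmholtz_roots(std_params(60))
  expect_equal(Im(rt_hi$nu_plus), 0, tolerance = 1e-14)
  expect_gt(Re(rt_hi$nu_plus), 0)
  expect_gt(Re(rt_hi$nu_minus), 0)
})

test_that("an unperturbed tension-free bilayer stays flat", {
  sol <- solve_cylinder(2.5, boundary_data(0, 0), std_params(0))
  expect_lt(max(Mod(c(sol$coeffs$Ap, sol$coeffs$Am))), 1e-14)
  f <- evaluate_field(sol, c(2.5, 4, 9), c(0, 1))
  expect_equal(max(abs(f$u)), 0, tolerance = 1e-14)
})

test_that("cylinder solutions honor their boundary conditions", {
  for (case in list(c(-0.3, 0), c(0.22, 0.1), c(-0.5, -0.15))) {
    p <- std_params(0.6)
    sol <- solve_cylinder(2.5, boundary_data(case[1], case[2]), p)
    f <- evaluate_field(sol, 2.5, 0)
    expect_equal(f$u[1, 1], case[1], tolerance = 1e-10)
    h <- 1e-6
    slope <- (evaluate_field(sol, 2.5 + h, 0)$u - f$u) / h
    expect_equal(as.numeric(slope), case[2], tolerance = 1e-4)
  }
})

test_that("the field decays to the tension-set far-field thickness", {
  p <- std_params(1.2)
  sol <- solve_cylinder(2.5, std_bd(), p)
  f <- evaluate_field(sol, 2.5 + 20, 0)
  expect_lt(abs(f$u[1, 1] - u_far_field(p)), 1e-6 * abs(-0.525))
  # the zero-tension kernel is an exponentially damped oscillation, so
  # pointwise |u| crosses zero; the windowed envelope decays monotonically
  p0 <- std_params(0)
  s0 <- solve_cylinder(2.5, std_bd(), p0)
  r <- seq(2.5 + 2, 2.5 + 18, by = 0.05)
  u <- abs(as.numeric(evaluate_field(s0, r, 0)$u))
  win <- split(u, findInterval(r, seq(2.5 + 2, 2.5 + 18, by = 4)))
  env <- vapply(win, max, numeric(1))
  expect_true(all(diff(env) < 0))
})

test_that("solution coefficients are jointly linear in the boundary data", {
  p <- std_params(0.4)
  sol <- function(U, Up) solve_cylinder(2.5, boundary_data(U, Up), p)$coeffs
  a <- sol(0.3, 0); b <- sol(0, 0.2); ab <- sol(0.3, 0.2); z <- sol(0, 0)
  expect_equal(ab$Ap, a$Ap + b$Ap - z$Ap, tolerance = 1e-10)
  expect_equal(ab$Am, a$Am + b$Am - z$Am, tolerance = 1e-10)
  # doubling both data doubles the deviation from the homogeneous solution
  d2 <- sol(0.6, 0.4)
  expect_equal(d2$Ap - z$Ap, 2 * (ab$Ap - z$Ap), tolerance = 1e-10)
})

test_that("equivalent-cylinder boundary data has the stated structure", {
  p <- std_params(0)
  circ <- make_circle(2.5)
  eff0 <- effective_boundary_data(circ, std_bd(), p)
  expect_identical(nrow(eff0$U_harmonics), 0L)
  expect_identical(nrow(eff0$Up_harmonics), 0L)
  sh <- make_cloverleaf(5, 0.1, R0 = 2.5)
  eff <- effective_boundary_data(sh, std_bd(), p)
  expect_identical(eff$U_harmonics$n, 5L)
  expect_identical(eff$Up_harmonics$n, 5L)
  expect_equal(eff$U, std_bd()$U)
  # linearity: doubling eps doubles every effective correction
  eff2 <- effective_boundary_data(make_cloverleaf(5, 0.2, R0 = 2.5), std_bd(), p)
  expect_equal(eff2$U_harmonics$c, 2 * eff$U_harmonics$c, tolerance = 1e-12)
  expect_equal(eff2$Up_harmonics$c, 2 * eff$Up_harmonics$c, tolerance = 1e-12)
  # the mapped value channel carries -R0 eps u0'(R0)
  sol0 <- solve_cylinder(2.5, std_bd(), p)
  h <- 1e-6
  d1 <- (evaluate_field(sol0, 2.5 + h, 0)$u - evaluate_field(sol0, 2.5, 0)$u) / h
  expect_equal(eff$U_harmonics$c, -2.5 * 0.1 * as.numeric(d1), tolerance = 1e-4)
})

test_that("the perturbed solver reduces to the cylinder for circular shapes", {
  p <- std_params(0.8)
  sol_c <- solve_cylinder(2.5, std_bd(), p)
  sol_p <- solve_perturbed(make_circle(2.5), std_bd(), p)
  expect_equal(sol_p$coeffs$Ap, sol_c$coeffs$Ap, tolerance = 1e-14)
  expect_equal(sol_p$coeffs$Am, sol_c$coeffs$Am, tolerance = 1e-14)
})

test_that("perturbed fields inherit the boundary symmetry", {
  sol <- solve_perturbed(make_cloverleaf(5, 0.1, R0 = 2.5), std_bd(), std_params())
  th <- c(0.37, 1.1, 2.9)
  u1 <- evaluate_field(sol, c(2.7, 3.5, 6), th)$u
  u2 <- evaluate_field(sol, c(2.7, 3.5, 6), th + 2 * pi / 5)$u
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("a tetragonal difference field has exact 4-fold periodicity", {
  p <- std_params()
  sh <- scale_to_area(make_ngon(4, 2), pi * 2.5^2)
  sol <- solve_perturbed(sh, std_bd(), p)
  sol_c <- solve_cylinder(2.5, std_bd(), p)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  r <- c(2.8, 4, 7)
  du <- evaluate_field(sol, r, th)$u - evaluate_field(sol_c, r, th)$u
  du_shift <- evaluate_field(sol, r, (th + pi / 2) %% (2 * pi))$u -
    evaluate_field(sol_c, r, (th + pi / 2) %% (2 * pi))$u
  expect_equal(du, du_shift, tolerance = 1e-12)
  expect_gt(max(abs(du)), 1e-3)  # the difference pattern is non-trivial
})

test_that("evaluate_field validates its domain and grid shape", {
  sol <- solve_cylinder(2.5, std_bd(), std_params())
  expect_error(evaluate_field(sol, 2.0, 0), "exterior")
  f <- evaluate_field(sol, c(2.5, 3, 4.5), c(0, 1, 2, 3))
  expect_identical(dim(f$u), c(3L, 4L))
  expect_true(is.numeric(f$u))
})

test_that("solver guards reject inconsistent requests", {
  expect_error(solve_perturbed(make_cloverleaf(5, 0.1), std_bd(), std_params(),
                               N_max = 3), "top harmonic")
  expect_error(solve_cylinder(-1, std_bd(), std_params()), "positive")
})
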