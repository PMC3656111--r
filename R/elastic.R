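#' Material parameters of the bilayer membrane
#'
#' Collects the elastic constants of the thickness-deformation energy
#' functional
#' \deqn{G = \frac12 \int dx\,dy\, \Big[ K_b (\nabla^2 u)^2
#'   + K_t \Big(\frac{u}{\ell}\Big)^2
#'   + \tau \Big( \frac{2u}{\ell} + (\nabla u)^2 \Big) \Big],}
#' where `u` is the thickness deformation field (deviation of the leaflet
#' hydrophobic thickness from its unperturbed value, nm), `Kb` the bending
#' rigidity (kBT), `Kt` the thickness-deformation stiffness (kBT/nm^2,
#' normalized by the relative strain u/l), `tau` the membrane tension
#' (kBT/nm^2) with its two couplings (to lipid area via 2u/l and to surface
#' undulations via (grad u)^2), and `leaflet_l` one-half the equilibrium
#' bilayer hydrophobic thickness (nm). All energies are expressed in units
#' of the thermal energy kBT.
#'
#' @param Kb bending rigidity (kBT), > 0.
#' @param Kt thickness-deformation stiffness (kBT/nm^2), > 0.
#' @param tau membrane tension (kBT/nm^2), >= 0.
#' @param leaflet_l one-half equilibrium bilayer hydrophobic thickness (nm), > 0.
#' @return an object of class `material_params`.
#' @export
material_params <- function(Kb = 20, Kt = 60, tau = 0, leaflet_l = 1.4) {
  vals <- c(Kb = Kb, Kt = Kt, tau = tau, leaflet_l = leaflet_l)
  if (any(!is.finite(vals))) stop("material parameters must be finite")
  if (Kb <= 0) stop("Kb must be > 0")
  if (Kt <= 0) stop("Kt must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  if (leaflet_l <= 0) stop("leaflet_l must be > 0")
  structure(list(Kb = Kb, Kt = Kt, tau = tau, leaflet_l = leaflet_l, kT = 1),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(paste0("<material_params> Kb = %g kBT, Kt = %g kBT/nm^2, ",
                     "tau = %g kBT/nm^2, leaflet l = %g nm\n"),
              x$Kb, x$Kt, x$tau, x$leaflet_l))
  invisible(x)
}

#' Boundary data at the bilayer-inclusion interface
#'
#' `U` is one-half the hydrophobic mismatch (nm): the value the thickness
#' deformation field takes at the inclusion boundary, `U = (W - 2l)/2` for
#' a protein of hydrophobic thickness `W` in a bilayer of hydrophobic
#' thickness `2l`. `Uprime` is the prescribed slope of the field along the
#' boundary normal (dimensionless); it is zero in all standard
#' calculations. Both may carry angular Fourier content through
#' `U_harmonics` / `Up_harmonics` (data.frames with columns `n`, `c`, `s`).
#'
#' @param U constant part of the half-mismatch (nm).
#' @param Uprime constant part of the contact slope (default 0).
#' @param U_harmonics optional data.frame of angular harmonics of U.
#' @param Up_harmonics optional data.frame of angular harmonics of Uprime.
#' @return an object of class `boundary_data`.
#' @export
boundary_data <- function(U, Uprime = 0, U_harmonics = NULL, Up_harmonics = NULL) {
  if (!is.finite(U) || !is.finite(Uprime))
    stop("boundary data must be finite")
  norm_h <- function(h) {
    if (is.null(h) || nrow(h) == 0L)
      return(data.frame(n = integer(0), c = numeric(0), s = numeric(0)))
    data.frame(n = as.integer(h$n), c = as.numeric(h$c), s = as.numeric(h$s))
  }
  structure(list(U = U, Uprime = Uprime,
                 U_harmonics = norm_h(U_harmonics),
                 Up_harmonics = norm_h(Up_harmonics)),
            class = "boundary_data")
}

#' Roots of the factorized Euler-Lagrange operator
#'
#' Minimizing the elastic energy gives the fourth-order equation
#' \deqn{K_b \nabla^4 u - \tau \nabla^2 u + \frac{K_t}{\ell^2} u +
#'   \frac{\tau}{\ell} = 0.}
#' After absorbing the constant tension-induced thickness shift
#' (see [u_far_field()]), the homogeneous operator factorizes into two
#' Helmholtz operators \eqn{(\nabla^2 - \nu_+)(\nabla^2 - \nu_-)} whose
#' inverse-length-squared roots solve
#' \deqn{K_b \nu^2 - \tau \nu + K_t/\ell^2 = 0.}
#' The roots form a complex-conjugate pair at low tension (discriminant
#' \eqn{\tau^2 < 4 K_b K_t/\ell^2}) and become real and positive at very
#' large tension; in either case `sqrt(nu)` has positive real part, so the
#' exterior solutions built from \eqn{K_n(\sqrt{\nu} r)} decay.
#'
#' @param params a [material_params()].
#' @return an object of class `helmholtz_roots`: list with complex
#'   `nu_plus`, `nu_minus` and their principal square roots `k_plus`,
#'   `k_minus`.
#' @export
helmholtz_roots <- function(params) {
  stopifnot(inherits(params, "material_params"))
  a <- params$Kb
  b <- -params$tau
  cc <- params$Kt / params$leaflet_l^2
  disc <- as.complex(b^2 - 4 * a * cc)
  sq <- sqrt(disc)
  nu_p <- (-b + sq) / (2 * a)
  nu_m <- (-b - sq) / (2 * a)
  structure(list(nu_plus = nu_p, nu_minus = nu_m,
                 k_plus = sqrt(nu_p), k_minus = sqrt(nu_m)),
            class = "helmholtz_roots")
}

#' @export
print.helmholtz_roots <- function(x, ...) {
  cat(sprintf("<helmholtz_roots> nu+ = %s, nu- = %s (nm^-2)\n",
              format(x$nu_plus, digits = 6), format(x$nu_minus, digits = 6)))
  invisible(x)
}

#' Far-field thickness shift
#'
#' The tension couples linearly to the thickness strain, so far from the
#' inclusion the bilayer settles at \eqn{u_\infty = -\tau \ell / K_t}
#' rather than at zero: tension thins the membrane. The series solution is
#' computed for the shifted, decaying field and this constant is added back
#' on evaluation.
#'
#' @param params a [material_params()].
#' @return the far-field value of u (nm).
#' @export
u_far_field <- function(params) {
  -params$tau * params$leaflet_l / params$Kt
}

# Solve the per-harmonic 2x2 system fixing the amplitudes (Ap, Am) of
# K_n(k+ r), K_n(k- r) from a boundary value and a boundary radial slope
# of the shifted field at r = R.
channel_solve <- function(n, R, value, slope, roots) {
  zp <- roots$k_plus * R
  zm <- roots$k_minus * R
  M <- matrix(c(cbesselK(n, zp), cbesselK(n, zm),
                roots$k_plus * cbesselK_d1(n, zp),
                roots$k_minus * cbesselK_d1(n, zm)),
              2, 2, byrow = TRUE)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  scale <- max(Mod(M))
  if (!is.finite(Mod(det)) || Mod(det) < 1e-14 * scale^2)
    stop("degenerate boundary-matching system: the per-harmonic 2x2 solve ",
         "is numerically singular (|det| = ", format(Mod(det)),
         ", coefficient scale ", format(scale), ")")
  rhs <- c(value, slope)
  Ap <- (rhs[1] * M[2, 2] - rhs[2] * M[1, 2]) / det
  Am <- (M[1, 1] * rhs[2] - M[2, 1] * rhs[1]) / det
  c(Ap, Am)
}

new_series_solution <- function(R0, roots, coeffs, params, bdata, shape = NULL) {
  structure(list(R0 = R0, roots = roots, coeffs = coeffs,
                 u_offset = u_far_field(params),
                 params = params, bdata = bdata, shape = shape),
            class = "series_solution")
}

#' @export
print.series_solution <- function(x, ...) {
  cat(sprintf("<series_solution> R0 = %.4f nm, %d channel(s), u_offset = %g nm\n",
              x$R0, nrow(x$coeffs), x$u_offset))
  invisible(x)
}

#' Thickness deformation around a cylindrical inclusion
#'
#' Closed-form Fourier-Bessel solution for a circular boundary of radius
#' `R`: the rotationally symmetric channel is fixed by requiring
#' `u(R) = U` and radial slope `Uprime`, and any angular harmonics carried
#' by the boundary data are matched channel by channel.
#'
#' @param R inclusion radius (nm), > 0.
#' @param bdata a [boundary_data()].
#' @param params a [material_params()].
#' @return a `series_solution`.
#' @export
solve_cylinder <- function(R, bdata, params) {
  stopifnot(inherits(bdata, "boundary_data"), inherits(params, "material_params"))
  if (!is.finite(R) || R <= 0) stop("R must be a positive radius (nm)")
  roots <- helmholtz_roots(params)
  shift <- -u_far_field(params)   # boundary value of the shifted field
  ab <- channel_solve(0L, R, bdata$U + shift, bdata$Uprime, roots)
  coeffs <- data.frame(n = 0L, trig = "cos",
                       Ap = ab[1], Am = ab[2])
  hu <- bdata$U_harmonics
  hp <- bdata$Up_harmonics
  ns <- sort(unique(c(hu$n, hp$n)))
  for (n in ns) {
    uc <- if (n %in% hu$n) hu$c[hu$n == n] else 0
    us <- if (n %in% hu$n) hu$s[hu$n == n] else 0
    pc <- if (n %in% hp$n) hp$c[hp$n == n] else 0
    ps <- if (n %in% hp$n) hp$s[hp$n == n] else 0
    if (uc != 0 || pc != 0) {
      ab <- channel_solve(n, R, as.complex(uc), as.complex(pc), roots)
      coeffs <- rbind(coeffs, data.frame(n = n, trig = "cos", Ap = ab[1], Am = ab[2]))
    }
    if (us != 0 || ps != 0) {
      ab <- channel_solve(n, R, as.complex(us), as.complex(ps), roots)
      coeffs <- rbind(coeffs, data.frame(n = n, trig = "sin", Ap = ab[1], Am = ab[2]))
    }
  }
  new_series_solution(R, roots, coeffs, params, bdata)
}

# Radial profile of a single channel and its derivatives at radii r.
# what: "u" (value), "dr", "d2r", "lap", "dlap".
channel_radial <- function(sol, n, Ap, Am, r, what = "u") {
  kp <- sol$roots$k_plus; km <- sol$roots$k_minus
  np <- sol$roots$nu_plus; nm <- sol$roots$nu_minus
  switch(what,
    u    = Ap * cbesselK(n, kp * r) + Am * cbesselK(n, km * r),
    dr   = Ap * kp * cbesselK_d1(n, kp * r) + Am * km * cbesselK_d1(n, km * r),
    d2r  = Ap * kp^2 * cbesselK_d2(n, kp * r) + Am * km^2 * cbesselK_d2(n, km * r),
    lap  = Ap * np * cbesselK(n, kp * r) + Am * nm * cbesselK(n, km * r),
    dlap = Ap * np * kp * cbesselK_d1(n, kp * r) +
           Am * nm * km * cbesselK_d1(n, km * r),
    stop("unknown radial quantity"))
}

#' Effective boundary data of the equivalent cylinder
#'
#' Maps the boundary conditions on a non-circular curve
#' \eqn{r = R_0(1+\epsilon(\theta))} onto per-harmonic boundary conditions
#' on the reference circle `R0`, to leading order in eps: Taylor expansion
#' of the zeroth-order (cylinder) profile about `R0` gives, for each
#' harmonic `n` of eps with amplitude `eps_n`,
#' \deqn{U_n = -R_0\, \epsilon_n\, u_0'(R_0), \qquad
#'   U_n' = -R_0\, \epsilon_n\, u_0''(R_0),}
#' while the n = 0 channel keeps the original constant data (the
#' zeroth-order terms of the expansion). Angular harmonics already present
#' in the supplied boundary data are added to the mapped corrections.
#'
#' @param shape a [boundary_shape()].
#' @param bdata a [boundary_data()].
#' @param params a [material_params()].
#' @param sol0 the n = 0 cylinder solution at `R0 = shape$R0`, as returned
#'   by [solve_cylinder()]; computed internally when NULL.
#' @return a [boundary_data()] whose harmonics hold the effective
#'   first-order data of the equivalent variable-thickness cylinder.
#' @export
effective_boundary_data <- function(shape, bdata, params, sol0 = NULL) {
  stopifnot(inherits(shape, "boundary_shape"))
  if (is.null(sol0)) sol0 <- solve_cylinder(shape$R0, bdata, params)
  if (abs(sol0$R0 - shape$R0) > 1e-12 * shape$R0)
    stop("sol0 must be the cylinder solution at the shape's reference radius")
  i0 <- which(sol0$coeffs$n == 0L)
  Ap <- sol0$coeffs$Ap[i0]; Am <- sol0$coeffs$Am[i0]
  d1 <- channel_radial(sol0, 0L, Ap, Am, shape$R0, "dr")
  d2 <- channel_radial(sol0, 0L, Ap, Am, shape$R0, "d2r")
  reality_check(c(d1, d2), "zeroth-order radial derivatives")
  d1 <- Re(d1); d2 <- Re(d2)
  h <- shape$harmonics
  Uh <- data.frame(n = h$n,
                   c = -shape$R0 * h$c * d1,
                   s = -shape$R0 * h$s * d1)
  Uph <- data.frame(n = h$n,
                    c = -shape$R0 * h$c * d2,
                    s = -shape$R0 * h$s * d2)
  merge_h <- function(a, b) {
    if (nrow(b) == 0L) return(a)
    for (i in seq_len(nrow(b))) {
      j <- match(b$n[i], a$n)
      if (is.na(j)) a <- rbind(a, b[i, ]) else {
        a$c[j] <- a$c[j] + b$c[i]; a$s[j] <- a$s[j] + b$s[i]
      }
    }
    a[order(a$n), , drop = FALSE]
  }
  boundary_data(bdata$U, bdata$Uprime,
                U_harmonics = merge_h(Uh, bdata$U_harmonics),
                Up_harmonics = merge_h(Uph, bdata$Up_harmonics))
}

#' Thickness deformation around a non-circular inclusion
#'
#' Leading-order perturbative solution: the non-circular boundary
#' conditions are mapped with [effective_boundary_data()] onto an
#' equivalent cylinder of radius `R0`, and every angular channel is then
#' fixed by its own 2x2 Fourier-Bessel match. For a circular shape the
#' result coincides with [solve_cylinder()].
#'
#' @param shape a [boundary_shape()].
#' @param bdata a [boundary_data()].
#' @param params a [material_params()].
#' @param N_max highest harmonic channel retained; defaults to the
#'   shape's top harmonic (higher channels vanish at leading order).
#' @return a `series_solution` with the shape recorded.
#' @export
solve_perturbed <- function(shape, bdata, params, N_max = NULL) {
  stopifnot(inherits(shape, "boundary_shape"))
  top <- if (nrow(shape$harmonics)) max(shape$harmonics$n) else 0L
  if (is.null(N_max)) N_max <- top
  if (N_max < top)
    stop("N_max (", N_max, ") is below the shape's top harmonic (", top, ")")
  sol0 <- solve_cylinder(shape$R0, bdata, params)
  eff <- effective_boundary_data(shape, bdata, params, sol0)
  keep <- eff$U_harmonics$n <= N_max
  eff$U_harmonics <- eff$U_harmonics[keep, , drop = FALSE]
  eff$Up_harmonics <- eff$Up_harmonics[eff$Up_harmonics$n <= N_max, , drop = FALSE]
  sol <- solve_cylinder(shape$R0, eff, params)
  sol$shape <- shape
  sol
}

reality_check <- function(z, what, tol = 1e-10) {
  scale <- max(abs(Re(z)), 1e-300)
  if (max(abs(Im(z))) > tol * max(scale, 1e-10))
    stop("reality violation in ", what, ": |Im| = ", format(max(abs(Im(z)))),
         " vs |Re| scale ", format(scale))
  invisible(z)
}

#' Evaluate a series solution on a polar grid
#'
#' Sums the Fourier-Bessel channels and restores the tension-induced
#' far-field shift, returning the physical thickness deformation field
#' (zero = unperturbed bilayer).
#'
#' @param sol a `series_solution`.
#' @param r_values radii (nm), all >= the matching radius `R0`.
#' @param theta_values polar angles (rad).
#' @return a `deformation_field`: list with `r`, `theta`, matrix `u`
#'   (length(r) x length(theta), nm) and metadata.
#' @export
evaluate_field <- function(sol, r_values, theta_values) {
  stopifnot(inherits(sol, "series_solution"))
  r_values <- as.numeric(r_values); theta_values <- as.numeric(theta_values)
  if (any(r_values < sol$R0 * (1 - 1e-12)))
    stop("the series solution is defined on the exterior r >= R0 = ",
         format(sol$R0), " nm")
  acc <- matrix(0 + 0i, length(r_values), length(theta_values))
  for (i in seq_len(nrow(sol$coeffs))) {
    n <- sol$coeffs$n[i]
    rad <- channel_radial(sol, n, sol$coeffs$Ap[i], sol$coeffs$Am[i], r_values, "u")
    ang <- if (sol$coeffs$trig[i] == "cos") cos(n * theta_values) else sin(n * theta_values)
    acc <- acc + outer(rad, ang)
  }
  reality_check(acc, "evaluated deformation field")
  structure(list(r = r_values, theta = theta_values,
                 u = Re(acc) + sol$u_offset,
                 R0 = sol$R0, params = sol$params,
                 note = "u = thickness deformation (nm); zero = unperturbed bilayer"),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %d x %d polar grid, r in [%.3f, %.3f] nm, u in [%.4g, %.4g] nm\n",
              length(x$r), length(x$theta), min(x$r), max(x$r),
              min(x$u), max(x$u)))
  invisible(x)
}
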