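#' Elastic thickness-deformation energy (closed form)
#'
#' Evaluates the deformation energy of a series solution exactly, by the
#' boundary line integral obtained from Gauss's theorem in the plane. In
#' terms of the decaying shifted field `v` (which absorbs the uniform
#' tension-induced thickness change), the energy density is a positive
#' quadratic form and, on the Euler-Lagrange solution,
#' \deqn{G = -\frac{R_0}{2} \int_0^{2\pi} \Big[
#'   K_b\big( \nabla^2 v\, \partial_r v - v\, \partial_r \nabla^2 v \big)
#'   + \tau\, v\, \partial_r v \Big]_{r=R_0} d\theta .}
#' Angular orthogonality reduces this to independent per-harmonic terms.
#' The zero of energy is the uniformly stretched flat membrane (at zero
#' tension: the flat unperturbed membrane), so an undeformed bilayer has
#' zero energy and `G >= 0` whenever `tau = 0`.
#'
#' @param sol a `series_solution` from [solve_cylinder()] or
#'   [solve_perturbed()].
#' @param params a [material_params()]; defaults to the parameters stored
#'   in the solution.
#' @return an `energy_breakdown`: list with `g_total`, `g_cyl` (n = 0
#'   channel), `dg_shape` (sum of n >= 1 channels), `per_harmonic`
#'   (data.frame n, g), and `zero_convention`. Energies in kBT.
#' @export
deformation_energy <- function(sol, params = sol$params) {
  stopifnot(inherits(sol, "series_solution"))
  R0 <- sol$R0
  g <- numeric(nrow(sol$coeffs))
  for (i in seq_len(nrow(sol$coeffs))) {
    n <- sol$coeffs$n[i]
    Ap <- sol$coeffs$Ap[i]; Am <- sol$coeffs$Am[i]
    v    <- channel_radial(sol, n, Ap, Am, R0, "u")
    dv   <- channel_radial(sol, n, Ap, Am, R0, "dr")
    lap  <- channel_radial(sol, n, Ap, Am, R0, "lap")
    dlap <- channel_radial(sol, n, Ap, Am, R0, "dlap")
    w <- if (n == 0L) 2 * pi else pi
    gi <- -(R0 * w / 2) * (params$Kb * (lap * dv - v * dlap) + params$tau * v * dv)
    reality_check(gi, sprintf("energy contribution of channel n = %d", n))
    g[i] <- Re(gi)
  }
  per <- stats::aggregate(list(g = g), by = list(n = sol$coeffs$n), FUN = sum)
  g_cyl <- sum(per$g[per$n == 0L])
  structure(list(g_total = sum(g), g_cyl = g_cyl,
                 dg_shape = sum(g) - g_cyl, per_harmonic = per,
                 zero_convention = "zero energy = flat membrane at the uniform tension-set thickness"),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> G_total = %.6f kBT  (G_cyl = %.6f, dG_shape = %.6f)\n",
              x$g_total, x$g_cyl, x$dg_shape))
  if (nrow(x$per_harmonic) > 1L) {
    for (i in seq_len(nrow(x$per_harmonic)))
      cat(sprintf("   n = %2d : %.6f kBT\n", x$per_harmonic$n[i], x$per_harmonic$g[i]))
  }
  invisible(x)
}

#' Deformation energy by area quadrature (verification route)
#'
#' Integrates the energy density of the shifted field
#' \eqn{\frac12 [ K_b(\nabla^2 v)^2 + (K_t/\ell^2) v^2 + \tau |\nabla v|^2 ]}
#' over the exterior annulus `R0 <= r <= R0 + r_extent` on a product grid:
#' trapezoid in r, uniform (spectrally exact for the truncated series) in
#' theta. Independent of the line-integral route in
#' [deformation_energy()]; the truncated tail is below 1e-6 of the total
#' for the default extent because the Bessel K envelope decays
#' exponentially.
#'
#' @param sol a `series_solution`.
#' @param params a [material_params()].
#' @param r_extent radial extent of the quadrature domain beyond R0 (nm).
#' @param nr number of radial nodes.
#' @param ntheta number of angular nodes (default resolves the top
#'   harmonic generously).
#' @return energy in kBT.
#' @export
deformation_energy_quadrature <- function(sol, params = sol$params,
                                          r_extent = 30, nr = 3000,
                                          ntheta = NULL) {
  stopifnot(inherits(sol, "series_solution"))
  R0 <- sol$R0
  nmax <- max(sol$coeffs$n)
  if (is.null(ntheta)) ntheta <- max(16L, 8L * (nmax + 1L))
  r <- seq(R0, R0 + r_extent, length.out = nr)
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  val <- lap <- dr <- dth <- matrix(0 + 0i, nr, ntheta)
  for (i in seq_len(nrow(sol$coeffs))) {
    n <- sol$coeffs$n[i]
    Ap <- sol$coeffs$Ap[i]; Am <- sol$coeffs$Am[i]
    fu <- channel_radial(sol, n, Ap, Am, r, "u")
    fl <- channel_radial(sol, n, Ap, Am, r, "lap")
    fd <- channel_radial(sol, n, Ap, Am, r, "dr")
    ang <- if (sol$coeffs$trig[i] == "cos") cos(n * th) else sin(n * th)
    dang <- if (sol$coeffs$trig[i] == "cos") -n * sin(n * th) else n * cos(n * th)
    val <- val + outer(fu, ang)
    lap <- lap + outer(fl, ang)
    dr  <- dr + outer(fd, ang)
    dth <- dth + outer(fu, dang)
  }
  reality_check(val, "quadrature field")
  v <- Re(val); L <- Re(lap); Dr <- Re(dr); Dt <- Re(dth)
  dens <- 0.5 * (params$Kb * L^2 + (params$Kt / params$leaflet_l^2) * v^2 +
                 params$tau * (Dr^2 + (Dt / r)^2))
  wr <- rep(r[2] - r[1], nr); wr[c(1, nr)] <- wr[1] / 2
  sum((dens * r) * wr) * (2 * pi / ntheta)
}

#' Cylinder / shape decomposition of the deformation energy
#'
#' Splits the membrane deformation energy of a non-circular inclusion into
#' the energy of a circular reference inclusion of equal area (or equal
#' circumference) and the shape excess `dG_shape = G_total - G_cyl`.
#'
#' @param shape a [boundary_shape()] (already normalized to the size of
#'   interest).
#' @param bdata a [boundary_data()].
#' @param params a [material_params()].
#' @param reference `"area"` (default) or `"circumference"`: the matching
#'   convention fixing the reference cylinder radius.
#' @return an `energy_breakdown` whose `g_cyl` is the reference-cylinder
#'   energy; `per_harmonic` is that of the shape solution.
#' @export
shape_decomposition <- function(shape, bdata, params,
                                reference = c("area", "circumference")) {
  reference <- match.arg(reference)
  r_ref <- if (reference == "area") sqrt(shape_area(shape) / pi)
           else shape_circumference(shape) / (2 * pi)
  g_shape <- deformation_energy(solve_perturbed(shape, bdata, params), params)
  g_ref <- deformation_energy(solve_cylinder(r_ref, bdata, params), params)
  structure(list(g_total = g_shape$g_total, g_cyl = g_ref$g_total,
                 dg_shape = g_shape$g_total - g_ref$g_total,
                 per_harmonic = g_shape$per_harmonic,
                 reference = reference, r_ref = r_ref,
                 zero_convention = g_shape$zero_convention),
            class = "energy_breakdown")
}
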