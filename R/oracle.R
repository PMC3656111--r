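# Independent finite-difference solvers used to verify the Fourier-Bessel
# machinery. Both work in real arithmetic on the shifted (decaying) field
# and never touch the series path: the radial solver discretizes the
# per-harmonic fourth-order ODE, the 2D solver discretizes the full
# Euler-Lagrange equation on a boundary-fitted annulus honoring the true
# non-circular boundary.

# first/second derivative matrices on a uniform 1D grid, second order,
# one-sided closures at the ends
fd_d1 <- function(N, h) {
  # third-order one-sided end rows keep the boundary closure error one
  # order below the interior scheme, so Richardson extrapolation of the
  # composed operators stays clean
  i <- c(rep(1, 4), rep(N, 4), rep(2:(N - 1), 2))
  j <- c(1:4, N:(N - 3), 2:(N - 1) - 1, 2:(N - 1) + 1)
  x <- c(c(-11, 18, -9, 2) / 6, c(11, -18, 9, -2) / 6,
         rep(-0.5, N - 2), rep(0.5, N - 2)) / h
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N))
}

fd_d2 <- function(N, h) {
  i <- c(rep(1, 5), rep(N, 5), rep(2:(N - 1), 3))
  j <- c(1:5, N:(N - 4), 2:(N - 1) - 1, 2:(N - 1), 2:(N - 1) + 1)
  x <- c(c(35, -104, 114, -56, 11) / 12, c(35, -104, 114, -56, 11) / 12,
         rep(1, N - 2), rep(-2, N - 2), rep(1, N - 2)) / h^2
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N))
}

# periodic central first derivative
fd_d1_periodic <- function(N, h) {
  ip <- c(seq_len(N), seq_len(N))
  jp <- c(ifelse(seq_len(N) == N, 1, seq_len(N) + 1),
          ifelse(seq_len(N) == 1, N, seq_len(N) - 1))
  Matrix::sparseMatrix(i = ip, j = jp, x = rep(c(1, -1) / (2 * h), each = N),
                       dims = c(N, N))
}

#' Per-harmonic radial finite-difference oracle
#'
#' Solves the fourth-order radial equation of angular channel `n` of the
#' shifted thickness field,
#' \deqn{K_b \Delta_n^2 v - \tau \Delta_n v + (K_t/\ell^2) v = 0, \quad
#'   \Delta_n = \frac{d^2}{dr^2} + \frac1r \frac{d}{dr} - \frac{n^2}{r^2},}
#' on `[R0, Rmax]` with clamped value and slope at `R0` and decay
#' (value and slope zero) at `Rmax`, by a second-order banded
#' finite-difference scheme. Entirely independent of the Bessel-series
#' path; used for verification only.
#'
#' @param n harmonic index (>= 0).
#' @param R0 inner radius (nm).
#' @param value boundary value of the shifted field at R0 (nm). For the
#'   n = 0 channel of a physical problem this is `U - u_far_field(params)`.
#' @param slope boundary radial slope at R0.
#' @param params a [material_params()].
#' @param Rmax outer truncation radius (nm); place it many decay lengths
#'   out so the clamped far end is exponentially irrelevant.
#' @param N number of grid points (>= 1000 recommended).
#' @return list with `r`, `v` (shifted field) and the grid step `h`.
#' @export
radial_ode_solve <- function(n, R0, value, slope, params, Rmax, N = 4000L) {
  stopifnot(inherits(params, "material_params"), Rmax > R0, N >= 16L)
  n <- as.integer(n)
  h <- (Rmax - R0) / (N - 1L)
  r <- R0 + h * (0:(N - 1L))
  D1 <- fd_d1(N, h); D2 <- fd_d2(N, h)
  Ln <- D2 + Matrix::Diagonal(N, 1 / r) %*% D1 - Matrix::Diagonal(N, n^2 / r^2)
  A <- params$Kb * (Ln %*% Ln) - params$tau * Ln +
    Matrix::Diagonal(N, params$Kt / params$leaflet_l^2)
  A <- as(A, "CsparseMatrix")
  b <- numeric(N)
  # boundary closures replace the PDE rows adjacent to each end
  bc_rows <- c(1L, 2L, N - 1L, N)
  A[bc_rows, ] <- 0
  A[1L, 1L] <- 1; b[1L] <- value
  A[2L, 1:4] <- c(-11, 18, -9, 2) / (6 * h); b[2L] <- slope
  A[N, N] <- 1; b[N] <- 0
  A[N - 1L, N:(N - 3L)] <- c(11, -18, 9, -2) / (6 * h); b[N - 1L] <- 0
  v <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("radial oracle linear solve failed: ",
                                         conditionMessage(e)))
  list(r = r, v = v, h = h, n = n)
}

#' Full 2D finite-difference oracle on a boundary-fitted annulus
#'
#' Solves the thickness-deformation Euler-Lagrange equation on the physical
#' exterior domain \eqn{\{(\rho,\theta): C(\theta) \le \rho \le R_{max}\}}
#' via the boundary-fitted map \eqn{\rho = C(\theta) + (R_{max} -
#' C(\theta))\xi}, imposing the value and the true normal-slope condition
#' exactly on the non-circular boundary. Verifies the equivalent-cylinder
#' mapping of [solve_perturbed()], including its O(eps^2) truncation.
#'
#' @param shape a [boundary_shape()].
#' @param bdata a [boundary_data()] (constant U, Uprime).
#' @param params a [material_params()].
#' @param Nxi radial nodes (>= 9).
#' @param Ntheta angular nodes; should resolve the top harmonic with at
#'   least 16 points per angular period (a warning is given otherwise).
#' @param Rmax outer truncation radius (nm).
#' @return list with `xi`, `theta`, matrices `rho` and `v`
#'   (`Nxi x Ntheta`, shifted field), and metadata. The physical field is
#'   `v + u_far_field(params)`.
#' @export
fd2d_solve <- function(shape, bdata, params, Nxi = 81L, Ntheta = 96L,
                       Rmax = NULL) {
  stopifnot(inherits(shape, "boundary_shape"), inherits(bdata, "boundary_data"),
            inherits(params, "material_params"))
  Nxi <- as.integer(Nxi); Ntheta <- as.integer(Ntheta)
  if (Nxi < 9L || Ntheta < 16L) stop("grid too coarse for the 2D oracle")
  top <- if (nrow(shape$harmonics)) max(shape$harmonics$n) else 0L
  if (top > 0L && Ntheta < 16L * top)
    warning("fewer than 16 angular points per period of the top harmonic")
  if (is.null(Rmax)) Rmax <- shape$R0 + 14
  hxi <- 1 / (Nxi - 1L)
  xi <- hxi * (0:(Nxi - 1L))
  hth <- 2 * pi / Ntheta
  theta <- hth * (0:(Ntheta - 1L))
  Cth <- radius_profile(shape, theta)
  Cp <- radius_dtheta(shape, theta)
  if (any(Cth >= Rmax)) stop("Rmax must exceed the boundary radius everywhere")
  N <- Nxi * Ntheta
  rho <- outer(xi, Rmax - Cth) + matrix(Cth, Nxi, Ntheta, byrow = TRUE)
  rho_xi <- matrix(Rmax - Cth, Nxi, Ntheta, byrow = TRUE)
  rho_th <- outer(1 - xi, Cp)
  Dxi <- Matrix::kronecker(Matrix::Diagonal(Ntheta), fd_d1(Nxi, hxi))
  Dth <- Matrix::kronecker(fd_d1_periodic(Ntheta, hth), Matrix::Diagonal(Nxi))
  dg <- function(m) Matrix::Diagonal(N, as.vector(m))
  P1 <- dg(1 / rho_xi) %*% Dxi                 # d/drho at fixed polar angle
  Tt <- Dth - dg(rho_th / rho_xi) %*% Dxi      # d/dtheta at fixed rho
  L <- P1 %*% P1 + dg(1 / rho) %*% P1 + dg(1 / rho^2) %*% (Tt %*% Tt)
  A <- params$Kb * (L %*% L) - params$tau * L +
    Matrix::Diagonal(N, params$Kt / params$leaflet_l^2)
  b <- numeric(N)
  idx <- function(i, j) i + (j - 1L) * Nxi
  jall <- seq_len(Ntheta)
  # normal-slope operator rows, evaluated on the inner boundary nodes
  S <- P1 - dg(Cp[col(rho)] / rho^2) %*% Tt
  normfac <- sqrt(1 + (Cp / Cth)^2)
  shift <- -u_far_field(params)
  bval <- bdata$U + shift + eval_bdata_harmonics(bdata$U_harmonics, theta)
  bslope <- bdata$Uprime + eval_bdata_harmonics(bdata$Up_harmonics, theta)
  rows_value_in <- idx(1L, jall)
  rows_slope_in <- idx(2L, jall)
  rows_value_out <- idx(Nxi, jall)
  rows_slope_out <- idx(Nxi - 1L, jall)
  bc_rows <- c(rows_value_in, rows_slope_in, rows_value_out, rows_slope_out)
  # replace the PDE rows adjacent to each boundary with the boundary
  # equations; done by sparse masking + selector products (row
  # subassignment on large sparse matrices is prohibitively slow)
  mask <- rep(1, N); mask[bc_rows] <- 0
  sel <- function(to, from, x = 1) Matrix::sparseMatrix(i = to, j = from, x = x,
                                                        dims = c(N, N))
  Abc <- sel(rows_value_in, rows_value_in) +
    sel(rows_slope_in, rows_value_in, 1 / normfac[jall]) %*% S +
    sel(rows_value_out, rows_value_out) +
    sel(rows_slope_out, rows_value_out) %*% P1
  A <- Matrix::Diagonal(N, mask) %*% A + Abc
  A <- as(A, "CsparseMatrix")
  b[rows_value_in] <- bval
  b[rows_slope_in] <- bslope
  v <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("2D oracle linear solve failed: ",
                                         conditionMessage(e)))
  list(xi = xi, theta = theta, rho = rho,
       v = matrix(v, Nxi, Ntheta), Nxi = Nxi, Ntheta = Ntheta,
       Rmax = Rmax, shape = shape, params = params, bdata = bdata)
}

eval_bdata_harmonics <- function(h, theta) {
  out <- numeric(length(theta))
  for (i in seq_len(nrow(h)))
    out <- out + h$c[i] * cos(h$n[i] * theta) + h$s[i] * sin(h$n[i] * theta)
  out
}

# dr/dtheta of the boundary curve
radius_dtheta <- function(shape, theta) {
  h <- shape$harmonics
  out <- numeric(length(theta))
  for (i in seq_len(nrow(h)))
    out <- out + h$n[i] * (-h$c[i] * sin(h$n[i] * theta) + h$s[i] * cos(h$n[i] * theta))
  shape$R0 * out
}

#' Richardson-extrapolated 2D oracle solution
#'
#' Runs [fd2d_solve()] on a grid and on its factor-two refinement,
#' extrapolates the (second-order) solution on the shared nodes and
#' estimates the discretization error from the grid difference.
#'
#' @inheritParams fd2d_solve
#' @return list with the coarse grid (`theta`, `rho`), the extrapolated
#'   shifted field `v_ext`, the fine-on-coarse field `v_fine`, the coarse
#'   field `v_coarse`, and `est_disc_error` (max |fine - coarse|, about
#'   three times the fine-grid error).
#' @export
fd2d_richardson <- function(shape, bdata, params, Nxi = 81L, Ntheta = 96L,
                            Rmax = NULL) {
  sc <- fd2d_solve(shape, bdata, params, Nxi, Ntheta, Rmax)
  sf <- fd2d_solve(shape, bdata, params, 2L * Nxi - 1L, 2L * Ntheta, sc$Rmax)
  vf <- sf$v[seq(1L, 2L * Nxi - 1L, by = 2L), seq(1L, 2L * Ntheta, by = 2L)]
  list(theta = sc$theta, rho = sc$rho, xi = sc$xi,
       v_coarse = sc$v, v_fine = vf, v_ext = (4 * vf - sc$v) / 3,
       est_disc_error = max(abs(vf - sc$v)),
       Rmax = sc$Rmax, shape = shape, params = params, bdata = bdata)
}

# Evaluate a series solution (shifted field) at scattered polar points.
eval_series_points <- function(sol, r, theta) {
  stopifnot(length(r) == length(theta))
  acc <- complex(length(r))
  for (i in seq_len(nrow(sol$coeffs))) {
    n <- sol$coeffs$n[i]
    rad <- channel_radial(sol, n, sol$coeffs$Ap[i], sol$coeffs$Am[i], r, "u")
    ang <- if (sol$coeffs$trig[i] == "cos") cos(n * theta) else sin(n * theta)
    acc <- acc + rad * ang
  }
  reality_check(acc, "series evaluation at oracle points")
  Re(acc)
}

#' Series-versus-oracle validity report
#'
#' Compares the leading-order Fourier-Bessel solution of a shape with the
#' Richardson-extrapolated 2D finite-difference solution on the common
#' region outside the perturbation band, and budgets the observed
#' difference into an estimated discretization part (from the grid pair)
#' and the leading-order truncation part (the remainder, expected to
#' scale as eps^2).
#'
#' @inheritParams fd2d_solve
#' @param margin extra radial clearance (nm) beyond the maximum boundary
#'   radius for the comparison region.
#' @return list with `max_field_error` (series vs extrapolated oracle, nm),
#'   `estimated_h2_term`, `estimated_eps2_term`, `max_eps`, and `pass`
#'   (TRUE when the observed error is covered by the budget).
#' @export
oracle_check <- function(shape, bdata, params, Nxi = 81L, Ntheta = 96L,
                         Rmax = NULL, margin = 0.25) {
  rich <- fd2d_richardson(shape, bdata, params, Nxi, Ntheta, Rmax)
  sol <- solve_perturbed(shape, bdata, params)
  eps_max <- if (nrow(shape$harmonics))
    max(abs(eps_profile(shape, seq(0, 2 * pi, length.out = 1024L)))) else 0
  r_min <- shape$R0 * (1 + eps_max) + margin
  pts <- which(rich$rho >= r_min & rich$rho <= rich$Rmax - 2, arr.ind = TRUE)
  rr <- rich$rho[pts]
  tt <- rich$theta[pts[, 2]]
  us <- eval_series_points(sol, rr, tt)
  diff_ext <- max(abs(us - rich$v_ext[pts]))
  h2 <- max(abs(rich$v_fine[pts] - rich$v_coarse[pts])) / 3
  list(max_field_error = max(abs(us - rich$v_fine[pts])),
       estimated_h2_term = h2,
       estimated_eps2_term = diff_ext,
       max_eps = eps_max,
       n_points = nrow(pts),
       pass = max(abs(us - rich$v_fine[pts])) <= 1.5 * (h2 + diff_ext) + 1e-12)
}
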