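#' Analytic Hagen-Poiseuille references for inclined cylinders
#'
#' Closed-form flow rate, velocity profile and deviatoric shear-stress tensor
#' of steady laminar flow in a circular pipe, together with the rotation
#' machinery needed to express them for a cylinder whose axis is not aligned
#' with the lattice, and the relative error norms used to score simulations
#' against them.
#'
#' @name poiseuille
NULL

#' Sample a non-lattice-aligned cylinder axis
#'
#' Draws a direction uniformly from the unit sphere and rejection-resamples
#' until every Cartesian component satisfies `|n_i| >= sin(min_angle)`, so
#' that the axis is at least `min_angle` away from every lattice plane.
#' Deterministic for a given seed; the global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param min_angle_deg minimum inclination from each lattice axis plane,
#'   degrees (default 15).
#' @return unit 3-vector.
#' @export
sample_inclined_axis <- function(seed = 1L, min_angle_deg = 15) {
  s <- sin(min_angle_deg * pi / 180)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  repeat {
    v <- stats::rnorm(3)
    n <- v / sqrt(sum(v^2))
    if (all(abs(n) >= s)) return(n)
  }
}

#' Poiseuille volumetric flow rate
#'
#' \eqn{Q = v_{max} \pi R^2 / 2} for a parabolic profile of peak velocity
#' `v_max` in a pipe of radius `R`.
#'
#' @param R pipe radius (m, or lattice units if consistent).
#' @param v_max peak (centreline) velocity.
#' @return flow rate `Q` in consistent units.
#' @export
poiseuille_flow_rate <- function(R, v_max) {
  stopifnot(R > 0, v_max >= 0)
  v_max * pi * R^2 / 2
}

#' Parabolic inlet velocity profile
#'
#' \eqn{v(r) = v_{max}(1 - r^2/R^2)\,\hat n}, where `r` is the distance of
#' `point` from the cylinder axis.
#'
#' @param point 3-vector position (same units as `p0`, `R`).
#' @param p0 a point on the axis (the inlet-cap centre).
#' @param axis unit axis vector.
#' @param R radius.
#' @param v_max peak velocity.
#' @return 3-vector velocity.
#' @export
parabolic_inlet_profile <- function(point, p0, axis, R, v_max) {
  d <- point - p0
  r2 <- sum((d - sum(d * axis) * axis)^2)
  if (r2 > R^2 * (1 + 1e-9)) stop("point lies outside the inlet disc")
  v_max * (1 - r2 / R^2) * axis
}

#' Deviatoric stress tensor of axial Poiseuille flow
#'
#' For a cylinder with axis along \eqn{e_3} and flow in the positive axial
#' direction, the only nonzero components are
#' \eqn{T'_{13} = T'_{31} = -2\eta v_{max} x_1 / R^2} and
#' \eqn{T'_{23} = T'_{32} = -2\eta v_{max} x_2 / R^2}; the Frobenius norm is
#' \eqn{2\sqrt2\,\eta v_{max} r/R^2}, linear in the radial coordinate.
#'
#' @param x1,x2 in-plane coordinates relative to the axis (`x1^2 + x2^2 <= R^2`).
#' @param R radius.
#' @param eta dynamic viscosity.
#' @param v_max peak velocity.
#' @return 3x3 symmetric traceless matrix.
#' @export
poiseuille_stress_axial <- function(x1, x2, R, eta, v_max) {
  if (x1^2 + x2^2 > R^2 * (1 + 1e-9)) stop("point lies outside the cylinder")
  g <- -2 * eta * v_max / R^2
  matrix(c(0, 0, g * x1,
           0, 0, g * x2,
           g * x1, g * x2, 0), 3, 3)
}

#' Rotation taking the lattice z-axis onto a given cylinder axis
#'
#' Builds an orthonormal right-handed frame whose third column is `axis`;
#' the first two columns come from Gram-Schmidt against the lattice axis
#' least aligned with `axis`, which keeps the construction well conditioned
#' for any admissible inclination.
#'
#' @param axis unit 3-vector.
#' @return 3x3 rotation matrix `Rot` with `det(Rot) = +1` and
#'   `Rot %*% c(0,0,1) == axis`.
#' @export
rotation_from_axis <- function(axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be a nonzero vector")
  n <- axis / nrm
  if (isTRUE(all.equal(n, c(0, 0, 1), tolerance = 1e-12))) return(diag(3))
  seed_axis <- diag(3)[, which.min(abs(n))]
  e1 <- seed_axis - sum(seed_axis * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],   # n x e1, so (e1, e2, n) is right handed
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2, n, deparse.level = 0)
}

#' Rotate a stress tensor between frames
#'
#' Similarity transform \eqn{T = Rot\,T'\,Rot^\top}; preserves symmetry,
#' trace and Frobenius norm.
#'
#' @param T_prime 3x3 tensor in the cylinder frame.
#' @param Rot rotation matrix from [rotation_from_axis()].
#' @return 3x3 tensor in the lattice frame.
#' @export
rotate_tensor <- function(T_prime, Rot) {
  Rot %*% T_prime %*% t(Rot)
}

#' Rotated Poiseuille stress tensor at a lattice point
#'
#' Convenience wrapper: expresses the analytic deviatoric stress at point `x`
#' (lattice frame) for a cylinder through `p0` along `axis`.
#'
#' @param x 3-vector point, lattice frame.
#' @inheritParams parabolic_inlet_profile
#' @param eta dynamic viscosity.
#' @return 3x3 tensor in the lattice frame.
#' @export
poiseuille_stress_rotated <- function(x, p0, axis, R, eta, v_max) {
  Rot <- rotation_from_axis(axis)
  d <- x - p0
  xp <- drop(t(Rot) %*% d)           # coordinates in the cylinder frame
  Tp <- poiseuille_stress_axial(xp[1], xp[2], R, eta, v_max)
  rotate_tensor(Tp, Rot)
}

#' Relative flow-rate error
#'
#' \eqn{\varepsilon_Q = |Q_{sim} - Q_{ref}| / |Q_{ref}|}.
#'
#' @param Q_sim simulated flow rate.
#' @param Q_analytic analytic reference (nonzero).
#' @return dimensionless error.
#' @export
flow_rate_error <- function(Q_sim, Q_analytic) {
  if (Q_analytic == 0) stop("reference flow rate must be nonzero")
  abs(Q_sim - Q_analytic) / abs(Q_analytic)
}

#' Relative Frobenius tensor error
#'
#' \eqn{\|T_{sim} - T_{ref}\|_F / \|T_{ref}\|_F}. The component-wise norm
#' prevents cancellation between components, so rotation errors register.
#' A zero-norm reference (e.g. on the cylinder axis) yields `NA` rather
#' than `Inf` so such sites can be excluded from shell statistics.
#'
#' @param T_sim,T_analytic 3x3 tensors.
#' @return dimensionless error, or `NA` if the reference has zero norm.
#' @export
tensor_error_frobenius <- function(T_sim, T_analytic) {
  ref <- sqrt(sum(T_analytic^2))
  if (ref < .Machine$double.eps) return(NA_real_)
  sqrt(sum((T_sim - T_analytic)^2)) / ref
}
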