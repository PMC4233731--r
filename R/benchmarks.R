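# Inclined-cylinder validation drivers: flow-rate accuracy over a grid of
# diameters and relaxation times, and near-wall shear-stress accuracy of the
# interpolated no-slip boundary, both scored against the analytic
# Hagen-Poiseuille solution.

# one benchmark cell: build, run, return field + setup
run_cylinder_case <- function(D_lat, tau, Re = 1, seed = 1L, L_factor = 4,
                              tol = 1e-6, max_steps = 60000L,
                              plain_bb = FALSE) {
  nu <- (tau - 0.5) / 3
  v_max <- 2 * Re * nu / D_lat          # Re defined with mean velocity v_max/2
  dom <- make_inclined_cylinder(D_lat, seed = seed, L_factor = L_factor,
                                v_max = v_max)
  mon <- convergence_monitor(v_ref = v_max, tol = tol, history_every = 200L)
  field <- suppressWarnings(
    run_to_convergence(dom, tau = tau, monitor = mon, max_steps = max_steps,
                       plain_bb = plain_bb))
  list(field = field, dom = dom, v_max = v_max, nu = nu, tau = tau,
       D_lat = D_lat, Re = Re)
}

#' Flow-rate accuracy benchmark
#'
#' For every combination of diameter and relaxation time, runs steady
#' Newtonian Hagen-Poiseuille flow at `Re = 1` in an inclined cylinder
#' (parabolic velocity inlet, pressure outlet, interpolated no-slip walls),
#' measures the flow rate on a lattice-aligned mid-cylinder plane and
#' reports the relative error against \eqn{Q = v_{max}\pi R^2/2}.
#'
#' @param diameters vector of diameters in lattice sites.
#' @param taus vector of relaxation times.
#' @param Re Reynolds number (mean-velocity based; default 1).
#' @param seed axis seed shared by all cells (one common inclined axis).
#' @param ... passed to the solver (`tol`, `max_steps`).
#' @return data frame with columns `D_lat`, `tau`, `eps_Q`, `converged`,
#'   `steps`.
#' @export
run_flow_rate_benchmark <- function(diameters = c(3, 5, 7, 9, 15),
                                    taus = 0.8, Re = 1, seed = 1L, ...) {
  grid <- expand.grid(D_lat = diameters, tau = taus)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cs <- run_cylinder_case(grid$D_lat[i], grid$tau[i], Re = Re, seed = seed, ...)
    Q_sim <- plane_flow_rate(cs$field)
    Q_ref <- poiseuille_flow_rate(cs$D_lat / 2, cs$v_max)
    data.frame(D_lat = cs$D_lat, tau = cs$tau,
               eps_Q = flow_rate_error(Q_sim, Q_ref),
               converged = cs$field$converged, steps = cs$field$steps)
  })
  do.call(rbind, rows)
}

#' Near-wall shear-stress accuracy benchmark
#'
#' Runs the inclined-cylinder benchmark for each diameter and compares the
#' computed deviatoric stress tensor, site by site, against the rotated
#' analytic Hagen-Poiseuille tensor using the relative Frobenius norm. The
#' statistics are collected over the near-wall shell `r/R` in
#' `shell` (default `[0.8, 1]`), on the middle half of the cylinder length
#' (away from inlet/outlet development), with azimuthal positions pooled and
#' radial structure kept via `n_bins` radial bins.
#'
#' @param diameters vector of diameters in lattice sites.
#' @param tau relaxation time (default 0.8, the accuracy optimum).
#' @param Re Reynolds number.
#' @param seed axis seed.
#' @param shell near-wall shell as fractions of the radius.
#' @param n_bins number of radial bins across the shell.
#' @param plain_bb use plain bounce-back instead of the interpolated wall
#'   (for comparison against the interpolated scheme).
#' @param ... passed to the solver.
#' @return list with one element per diameter: `sites` (per-site r/R,
#'   Frobenius error `eps_T`, signed norm error), `bins` (radial-bin means
#'   and maxima), `max_eps_T` (the maximum shell error, a fraction), and
#'   `max_bin` (index of the radial bin containing the maximum).
#' @export
run_wss_benchmark <- function(diameters = c(7, 15), tau = 0.8, Re = 1,
                              seed = 1L, shell = c(0.8, 1), n_bins = 4,
                              plain_bb = FALSE, ...) {
  out <- lapply(diameters, function(D_lat) {
    cs <- run_cylinder_case(D_lat, tau, Re = Re, seed = seed,
                            plain_bb = plain_bb, ...)
    dom <- cs$dom
    meta <- dom$meta
    R <- meta$R; L <- meta$L; n <- meta$axis; p0 <- meta$p0
    eta <- cs$nu * 1                        # lattice dynamic viscosity, rho0 = 1
    ijk <- active_coords(dom)
    d <- sweep(ijk, 2, p0)
    s_ax <- drop(d %*% n)
    r <- sqrt(pmax(rowSums(d^2) - s_ax^2, 0))
    sel <- which(dom$kind == 1L & r / R >= shell[1] & r / R <= shell[2] &
                 s_ax >= L / 4 & s_ax <= 3 * L / 4)
    Ts <- compute_deviatoric_stress(cs$field)
    Rot <- rotation_from_axis(n)
    eps <- signed <- numeric(length(sel))
    for (i in seq_along(sel)) {
      sidx <- sel[i]
      xp <- drop(t(Rot) %*% d[sidx, ])
      Ta <- rotate_tensor(poiseuille_stress_axial(xp[1], xp[2], R, eta, cs$v_max), Rot)
      Tsim <- Ts[sidx, , ]
      eps[i] <- tensor_error_frobenius(Tsim, Ta)
      signed[i] <- sqrt(sum(Tsim^2)) - sqrt(sum(Ta^2))
    }
    keep <- !is.na(eps)
    sites <- data.frame(r_over_R = (r[sel] / R)[keep], eps_T = eps[keep],
                        signed_norm_err = signed[keep] /
                          (2 * sqrt(2) * eta * cs$v_max * r[sel][keep] / R^2))
    edges <- seq(shell[1], shell[2], length.out = n_bins + 1)
    bin <- cut(sites$r_over_R, edges, include.lowest = TRUE, labels = FALSE)
    bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
      sb <- sites[bin == b, , drop = FALSE]
      data.frame(bin = b, r_lo = edges[b], r_hi = edges[b + 1], n = nrow(sb),
                 mean_eps = mean(sb$eps_T), max_eps = suppressWarnings(max(sb$eps_T)),
                 mean_signed = mean(sb$signed_norm_err))
    }))
    i_max <- which.max(sites$eps_T)
    list(D_lat = D_lat, sites = sites, bins = bins,
         max_eps_T = sites$eps_T[i_max],
         max_bin = bin[i_max],
         converged = cs$field$converged)
  })
  names(out) <- paste0("D", diameters)
  out
}
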