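# Lattice-Boltzmann solver driver: unit bridge, boundary conditions and the
# convergence loop around the compiled D3Q19 BGK kernel.

MMHG_TO_PA <- 133.322

#' Lattice specification: the bridge between physical and lattice units
#'
#' Fixes the voxel size \eqn{\Delta x}, time step \eqn{\Delta t} and blood
#' density, from which viscosities map to lattice relaxation times via
#' \eqn{\tilde\nu = (\eta/\rho)\,\Delta t/\Delta x^2},
#' \eqn{\tilde\tau = \tilde\nu/c_s^2 + 1/2} with \eqn{c_s^2 = 1/3}.
#' If `dt` is omitted it is calibrated so that the high-shear viscosity
#' `eta_ref` lands exactly on the accuracy optimum `tau_ref` (default 0.8).
#'
#' @param dx voxel size, metres.
#' @param dt time step, seconds, or `NULL` to calibrate from `eta_ref`.
#' @param rho blood density, kg/m^3 (default 1050).
#' @param eta_ref reference dynamic viscosity used for the calibration, Pa s.
#' @param tau_ref target relaxation time at `eta_ref` (default 0.8).
#' @return object of class `lattice_spec` with fields `dx`, `dt`, `rho`,
#'   `cs2`.
#' @examples
#' sp <- lattice_spec(dx = 0.5e-6, eta_ref = 3.265e-3)
#' sp$dt                    # ~8.04e-9 s
#' tau_from_viscosity(3.265e-3, sp)   # 0.8
#' @export
lattice_spec <- function(dx, dt = NULL, rho = 1050,
                         eta_ref = 3.265e-3, tau_ref = 0.8) {
  stopifnot(dx > 0, rho > 0)
  cs2 <- 1 / 3
  if (is.null(dt)) dt <- (tau_ref - 0.5) * cs2 * dx^2 * rho / eta_ref
  stopifnot(dt > 0)
  structure(list(dx = dx, dt = dt, rho = rho, cs2 = cs2), class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("lattice spec: dx = %.4g m, dt = %.4g s, rho = %g kg/m^3\n",
              x$dx, x$dt, x$rho))
  invisible(x)
}

#' Relaxation time for a given dynamic viscosity
#'
#' @param eta dynamic viscosity, Pa s.
#' @param spec a [lattice_spec()].
#' @return lattice relaxation time \eqn{\tilde\tau > 0.5}.
#' @export
tau_from_viscosity <- function(eta, spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (any(eta <= 0)) stop("viscosity must be positive")
  tau <- (eta / spec$rho) * (spec$dt / spec$dx^2) / spec$cs2 + 0.5
  if (any(tau <= 0.5))
    stop("unstable relaxation time for eta = ", paste(eta[tau <= 0.5], collapse = ", "))
  tau
}

#' Inlet/outlet pressure boundary condition
#'
#' @param p_inlet,p_outlet pressures in mmHg. The defaults are the mean
#'   murine central retinal artery pressure (MAP, 68.2 mmHg) and the
#'   intraocular pressure standing in for the venous side (IOP, 11.6 mmHg).
#' @return object of class `pressure_bc`.
#' @export
pressure_bc <- function(p_inlet = 68.2, p_outlet = 11.6) {
  if (p_inlet <= p_outlet) stop("need p_inlet > p_outlet for forward flow")
  structure(list(p_inlet = p_inlet, p_outlet = p_outlet), class = "pressure_bc")
}

# lattice density offset corresponding to a physical pressure difference
rho_for_pressure <- function(dp_pa, spec) {
  p_lat <- dp_pa / (spec$rho * (spec$dx / spec$dt)^2)
  1 + p_lat / spec$cs2
}

#' Convergence monitor settings
#'
#' The run is declared steady when the maximum per-site velocity change over
#' one time step, scaled by the reference velocity `v_ref`, drops below
#' `tol`.
#'
#' @param v_ref reference velocity, m/s (default 50 mm/s, a typical peak
#'   retinal velocity).
#' @param tol dimensionless tolerance (default 1e-5).
#' @param history_every record the criterion every this many steps.
#' @return object of class `convergence_monitor`.
#' @export
convergence_monitor <- function(v_ref = 50e-3, tol = 1e-5, history_every = 50L) {
  stopifnot(v_ref > 0, tol >= 0)   # tol = 0 runs the full step budget
  structure(list(v_ref = v_ref, tol = tol, history_every = as.integer(history_every)),
            class = "convergence_monitor")
}

#' Run the lattice-Boltzmann solver to steady state
#'
#' Advances a D3Q19 BGK solver from a quiescent uniform-density start until
#' the convergence criterion is met or `max_steps` is exhausted. Walls use
#' the Bouzidi interpolated bounce-back with the per-link sub-grid distances
#' stored in the domain; inlet/outlet caps use equilibrium plus
#' non-equilibrium extrapolation, holding either a prescribed velocity
#' profile or a target density (pressure).
#'
#' @param domain a `voxel_domain` from [make_inclined_cylinder()] or
#'   [voxelize_network()].
#' @param tau Newtonian relaxation time (ignored in Carreau-Yasuda mode,
#'   where it is recomputed per site from the local shear rate).
#' @param spec a [lattice_spec()]; required for physical-unit domains and
#'   for Carreau-Yasuda mode. Lattice-unit benchmark domains may pass `NULL`.
#' @param bc a [pressure_bc()] applied to pressure caps, or `NULL` to hold
#'   all pressure caps at the reference density.
#' @param rheology either `"newtonian"` or a [cy_params()] object (in mPa s)
#'   to enable the shear-thinning Carreau-Yasuda mode.
#' @param monitor a [convergence_monitor()]; for lattice-unit domains
#'   `v_ref` is interpreted in lattice units.
#' @param max_steps step budget.
#' @param tau_bounds admissible relaxation-time range in Carreau-Yasuda mode;
#'   updates outside it are clamped and counted.
#' @param plain_bb replace the interpolated boundary by plain bounce-back
#'   (diagnostic use).
#' @param min_steps minimum number of steps before convergence may be
#'   declared.
#' @return a `flow_field`: per-active-site `rho` (lattice), `u` (n x 3),
#'   `pressure`, `stress` (n x 6 deviatoric components xx,yy,zz,xy,xz,yz),
#'   convergence diagnostics, and the conversion spec. Units are physical
#'   (m/s, Pa) when `spec` is given and the domain is physical; lattice
#'   otherwise.
#' @export
run_to_convergence <- function(domain, tau = 0.8, spec = NULL, bc = NULL,
                               rheology = "newtonian",
                               monitor = convergence_monitor(),
                               max_steps = 50000L,
                               tau_bounds = c(0.505, 3), plain_bb = FALSE,
                               min_steps = 10L) {
  stopifnot(inherits(domain, "voxel_domain"))
  lattice_units <- isTRUE(domain$meta$lattice_units)
  cy_mode <- inherits(rheology, "cy_params") ||
    (is.list(rheology) && !is.character(rheology))
  if (cy_mode && is.null(spec))
    stop("Carreau-Yasuda mode needs a lattice_spec for the unit bridge")
  if (!lattice_units && is.null(spec))
    stop("physical-unit domains need a lattice_spec")

  cap_rho <- domain$cap_rho
  kernel_kind <- as.integer(domain$kind)
  if (!is.null(bc)) {
    # pressure-drop mode: inlet caps become pressure caps at the target density
    stopifnot(inherits(bc, "pressure_bc"))
    dp <- (bc$p_inlet - bc$p_outlet) * MMHG_TO_PA
    rho_in <- rho_for_pressure(dp, spec)
    cap_rho[domain$kind == 2L] <- rho_in
    cap_rho[domain$kind == 3L] <- 1
    kernel_kind[kernel_kind == 2L] <- 3L
  }

  u_cap_max <- if (nrow(domain$cap_u)) max(sqrt(rowSums(domain$cap_u^2))) else 0
  if (u_cap_max > 0.3)
    stop("prescribed cap velocity ", signif(u_cap_max, 3),
         " lattice units exceeds the compressibility limit (0.3)")
  if (u_cap_max > 0.1)
    warning("prescribed cap velocity ", signif(u_cap_max, 3),
            " lattice units; compressibility errors may be noticeable")

  cy_par <- rep(0, 5); conv_nu <- 0; conv_gamma <- 0
  if (cy_mode) {
    p <- as_cy_params(rheology)
    cy_par <- c(p$eta0, p$eta_inf, p$lam, p$a, p$n) * c(1e-3, 1e-3, 1, 1, 1)
    conv_nu <- spec$dt / (spec$rho * spec$dx^2)
    conv_gamma <- 1 / spec$dt
  }

  v_ref_lat <- if (lattice_units) monitor$v_ref else
    monitor$v_ref * spec$dt / spec$dx

  res <- .lbm_run_cpp(
    nbr = domain$nbr, kind = kernel_kind,
    wl_site = as.integer(domain$wall_links$site),
    wl_dir = as.integer(domain$wall_links$dir),
    wl_q = as.numeric(domain$wall_links$q),
    wl_vt = if (is.null(domain$wall_links$vt)) numeric(nrow(domain$wall_links))
            else as.numeric(domain$wall_links$vt),
    cap_u = domain$cap_u, cap_rho = cap_rho,
    cap_nbr = as.integer(domain$cap_nbr),
    tau0 = tau, cy_mode = cy_mode, cy_par = cy_par,
    conv_nu = conv_nu, conv_gamma = conv_gamma,
    tau_min = tau_bounds[1], tau_max = tau_bounds[2],
    max_steps = as.integer(max_steps), tol = monitor$tol, v_ref = v_ref_lat,
    history_every = monitor$history_every, plain_bb = plain_bb,
    min_steps = as.integer(min_steps),
    group_id = if (is.null(domain$group_id))
      ifelse(domain$kind == 1L, 0L, -1L) else as.integer(domain$group_id),
    cap_id = if (is.null(domain$cap_id)) rep(-1L, length(domain$active))
             else as.integer(domain$cap_id))

  if (res$diverged)
    stop("simulation diverged at step ", res$steps,
         " (criterion ", signif(res$criterion, 3), ")")
  if (!res$converged)
    warning("maximum step count reached before convergence (criterion ",
            signif(res$criterion, 3), "); returning partial result")

  c_u <- if (lattice_units) 1 else spec$dx / spec$dt
  c_p <- if (lattice_units) 1 else spec$rho * (spec$dx / spec$dt)^2
  c_q <- if (lattice_units) 1 else spec$dx^3 / spec$dt
  structure(list(
    cap_flux = res$cap_flux * c_q,
    rho = res$rho,
    u = res$u * c_u,
    pressure = (res$rho - 1) / 3 * c_p,
    stress = res$stress * c_p,
    tau = res$tau,
    steps = res$steps, converged = res$converged,
    criterion = res$criterion, history = res$history,
    clamp_count = res$clamp_count,
    domain = domain, spec = spec,
    lattice_units = lattice_units),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  vmag <- sqrt(rowSums(x$u^2))
  cat(sprintf(
    "flow field: %d sites, %s after %d steps (criterion %.3g)\n  peak |v| = %.4g %s, clamped tau updates: %g\n",
    length(x$rho), if (x$converged) "converged" else "NOT converged",
    x$steps, x$criterion, max(vmag),
    if (x$lattice_units) "lattice" else "m/s", x$clamp_count))
  invisible(x)
}

#' Flow rate through lattice-aligned planes
#'
#' Sums the plane-normal velocity component over all fluid sites of a
#' lattice plane (a Riemann estimate of the flux integral). At steady state
#' the flux is the same through every plane cutting the tube, so for a
#' cylinder benchmark the default estimate averages the per-plane sums over
#' all lattice planes intersecting the middle half of the cylinder (normal
#' to the lattice axis best aligned with the cylinder); at coarse diameters
#' this suppresses the Riemann noise of any single staircase cut.
#'
#' @param field a `flow_field`.
#' @param axis_dim 1, 2 or 3: lattice axis normal to the plane.
#' @param index plane index (or indices) along that axis (grid units).
#' @return flow rate (lattice units^3/step, or m^3/s for physical domains).
#' @export
plane_flow_rate <- function(field, axis_dim = NULL, index = NULL) {
  dom <- field$domain
  ijk <- active_coords(dom)
  if (is.null(axis_dim)) {
    if (is.null(dom$meta$axis)) stop("axis_dim required for non-benchmark domains")
    axis_dim <- which.max(abs(dom$meta$axis))
  }
  if (is.null(index)) {
    lo <- (dom$meta$p0 + dom$meta$L / 4 * dom$meta$axis)[axis_dim]
    hi <- (dom$meta$p0 + 3 * dom$meta$L / 4 * dom$meta$axis)[axis_dim]
    index <- seq(round(lo), round(hi))
  }
  dx <- if (field$lattice_units) 1 else dom$dx * 1e-6
  per_plane <- vapply(index, function(i) {
    sel <- ijk[, axis_dim] == i & dom$kind == 1L
    sum(field$u[sel, axis_dim]) * dx^2
  }, numeric(1))
  mean(per_plane)
}
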