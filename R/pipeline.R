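# End-to-end drivers: network simulation from a skeleton, run summaries,
# report tables mirroring the validation figures, config files, and VTK
# export for inspection.

#' Simulate steady blood flow through a vessel network
#'
#' The full pipeline on a skeleton graph: choose the voxel size from the
#' 95% length-coverage rule, voxelize, calibrate the time step so the
#' high-shear viscosity sits on the relaxation-time accuracy optimum, run
#' the shear-thinning (or Newtonian) solver under a physiological pressure
#' drop, and post-process wall tractions.
#'
#' @param skeleton a [skeleton_graph()] with designated inlet/outlet nodes.
#' @param bc a [pressure_bc()] (defaults: arterial 68.2 mmHg, venous
#'   11.6 mmHg).
#' @param rheology `"newtonian"` (at the high-shear viscosity) or a
#'   [cy_params()] object; default is the packaged murine Carreau-Yasuda fit.
#' @param dx voxel size in um, or `NULL` to use [choose_voxel_size()].
#' @param rho blood density, kg/m^3.
#' @param monitor a [convergence_monitor()].
#' @param max_steps solver step budget.
#' @param min_diameter_sites minimum resolved diameter, lattice sites.
#' @return list with `field` (a `flow_field`), `traction`, `summary`
#'   (inflow/outflow balance, peak velocity, WSS statistics, validity and
#'   plausibility fractions, voxel counts, clamped segments), `domain`,
#'   `spec`, `dx`.
#' @export
simulate_network <- function(skeleton, bc = pressure_bc(),
                             rheology = NULL, dx = NULL, rho = 1050,
                             monitor = convergence_monitor(),
                             max_steps = 50000L, min_diameter_sites = 3) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  if (is.null(rheology)) {
    fit <- fit_cy(mouse_blood_viscosity())
    rheology <- fit$params
  }
  if (is.null(dx)) dx <- choose_voxel_size(skeleton,
                                           min_diameter_sites = min_diameter_sites)
  dom <- voxelize_network(skeleton, dx, min_diameter_sites = min_diameter_sites)

  eta_ref <- if (inherits(rheology, "cy_params")) rheology$eta_inf * 1e-3 else 3.265e-3
  spec <- lattice_spec(dx = dx * 1e-6, rho = rho, eta_ref = eta_ref)

  field <- run_to_convergence(
    dom, spec = spec, bc = bc,
    rheology = if (inherits(rheology, "cy_params")) rheology else "newtonian",
    tau = if (inherits(rheology, "cy_params")) 0.8 else
      tau_from_viscosity(eta_ref, spec),
    monitor = monitor, max_steps = max_steps)

  traction <- compute_traction(field)
  flux <- cap_fluxes(field)
  inflow <- sum(flux$flux[flux$role == "inlet"])
  outflow <- -sum(flux$flux[flux$role == "outlet"])
  vmag <- sqrt(rowSums(field$u^2))
  summary <- list(
    dx_um = dx,
    n_fluid = sum(dom$kind == 1L),
    n_clamped_segments = length(dom$meta$clamped_segments),
    steps = field$steps, converged = field$converged,
    criterion = field$criterion,
    clamp_count = field$clamp_count,
    inflow_m3s = inflow, outflow_m3s = outflow,
    mass_balance_error = abs(inflow - outflow) / max(abs(inflow), 1e-300),
    peak_velocity_mms = max(vmag) * 1e3,
    wss = summarize_wss(traction))
  list(field = field, traction = traction, summary = summary,
       domain = dom, spec = spec, dx = dx)
}

#' Volumetric flux through each boundary cap
#'
#' The net discrete mass flux each cap exchanges with the fluid region,
#' accounted link-by-link inside the solver at the final state (exact up to
#' the convergence residual), signed positive into the domain.
#'
#' @param field a `flow_field` on a network domain.
#' @return data frame: cap node, role, flux (m^3/s; positive = into the
#'   domain, so outlets carry negative values).
#' @export
cap_fluxes <- function(field) {
  dom <- field$domain
  sl <- dom$meta$cap_slices
  if (is.null(sl)) stop("domain has no cap slices (benchmark domain?)")
  rows <- lapply(seq_along(sl), function(i) {
    cp <- sl[[i]]
    data.frame(node = cp$node, role = cp$role, flux = field$cap_flux[i])
  })
  do.call(rbind, rows)
}

#' Write run reports
#'
#' Emits the standard result tables of a completed run directory:
#' flow-rate benchmark tables (diameter, relaxation time, relative error),
#' WSS benchmark shell statistics, the network diameter histogram, and the
#' WSS distribution with the 20 Pa plausibility cap marked.
#'
#' @param results a list as returned by [simulate_network()],
#'   [run_flow_rate_benchmark()] or [run_wss_benchmark()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (is.data.frame(results) && all(c("D_lat", "tau", "eps_Q") %in% names(results))) {
    w(results, "flow_rate_benchmark.csv")
  } else if (is.list(results) && length(results) &&
             is.list(results[[1]]) && !is.null(results[[1]]$bins)) {
    for (nm in names(results)) {
      w(results[[nm]]$bins, paste0("wss_shell_", nm, ".csv"))
      w(results[[nm]]$sites, paste0("wss_sites_", nm, ".csv"))
    }
  } else if (is.list(results) && !is.null(results$summary)) {
    s <- results$summary
    w(data.frame(quantity = names(unlist(s[c("dx_um", "n_fluid", "steps",
                                             "inflow_m3s", "outflow_m3s",
                                             "mass_balance_error",
                                             "peak_velocity_mms")])),
                 value = unlist(s[c("dx_um", "n_fluid", "steps", "inflow_m3s",
                                    "outflow_m3s", "mass_balance_error",
                                    "peak_velocity_mms")])),
      "run_summary.csv")
    tr <- results$traction
    if (nrow(tr)) {
      w(tr, "wall_traction.csv")
      br <- seq(0, max(tr$wss) + 1, length.out = 41)
      w(data.frame(wss_lo = br[-length(br)], wss_hi = br[-1],
                   n = as.integer(table(cut(tr$wss, br, include.lowest = TRUE))),
                   above_cap = br[-length(br)] >= 20),
        "wss_histogram.csv")
    }
  } else {
    stop("unrecognized results object")
  }
  invisible(paths)
}

#' Read a run configuration file
#'
#' YAML (or JSON) with the knobs of a run: `mode`, geometry paths or
#' synthetic-plexus parameters, pressures in mmHg, rheology mode, voxel
#' size, tolerance, step budget and seed. Unknown keys are preserved.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$mode)) stop("config must name a mode")
  cfg
}

#' Export a flow field as legacy VTK structured points
#'
#' ASCII legacy VTK with point data (velocity magnitude, pressure, site
#' type) on the full regular grid, for inspection in ParaView and kin.
#'
#' @param field a `flow_field`.
#' @param path output `.vtk` path.
#' @return invisibly, `path`.
#' @export
write_vtk <- function(field, path) {
  dom <- field$domain
  sh <- dom$shape
  vmag <- pres <- array(0, dim = sh)
  vmag[dom$active] <- sqrt(rowSums(field$u^2))
  pres[dom$active] <- field$pressure
  con <- file(path, "w")
  on.exit(close(con))
  dx <- if (field$lattice_units) 1 else dom$dx
  writeLines(c("# vtk DataFile Version 3.0",
               "plexusflow flow field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", sh[1], sh[2], sh[3]),
               sprintf("ORIGIN %g %g %g", dom$origin[1], dom$origin[2], dom$origin[3]),
               sprintf("SPACING %g %g %g", dx, dx, dx),
               sprintf("POINT_DATA %d", prod(sh)),
               "SCALARS velocity_magnitude float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(vmag), trim = TRUE, scientific = TRUE, digits = 7), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(pres), trim = TRUE, scientific = TRUE, digits = 7), con)
  writeLines(c("SCALARS site_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(dom$site_type), trim = TRUE), con)
  invisible(path)
}
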