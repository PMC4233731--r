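# Wall-traction post-processing: stress tensors at wall-adjacent sites,
# traction vectors on the analytic tube normals, WSS magnitudes and the
# validity / plausibility flags attached to them.

#' Deviatoric stress tensors of a flow field
#'
#' Returns the per-site deviatoric stress (computed inside the solver from
#' the non-equilibrium populations, \eqn{T = 2\eta S}) as an `n x 3 x 3`
#' array, symmetric and traceless by construction.
#'
#' @param field a `flow_field` from [run_to_convergence()].
#' @return array `n x 3 x 3` (Pa, or lattice units for benchmark domains).
#' @export
compute_deviatoric_stress <- function(field) {
  s <- field$stress
  n <- nrow(s)
  out <- array(0, c(n, 3, 3))
  out[, 1, 1] <- s[, 1]; out[, 2, 2] <- s[, 2]; out[, 3, 3] <- s[, 3]
  out[, 1, 2] <- out[, 2, 1] <- s[, 4]
  out[, 1, 3] <- out[, 3, 1] <- s[, 5]
  out[, 2, 3] <- out[, 3, 2] <- s[, 6]
  if (!field$converged)
    attr(out, "warning") <- "stress computed from an unconverged state"
  out
}

#' Wall traction vectors and WSS magnitudes
#'
#' For every wall-adjacent cut link, evaluates the traction
#' \eqn{t = T\,\hat n} at the adjacent fluid site using the analytic tube
#' normal stored with the link, and reports its magnitude (the wall shear
#' stress, since the deviatoric tensor excludes the pressure part).
#' Each link carries two flags: `valid` requires the local vessel to be at
#' least `min_valid_sites` lattice sites across (stress accuracy degrades in
#' thinner vessels), and `unphysiological` marks magnitudes above `wss_cap`
#' (20 Pa, the upper bound of microvascular WSS reported in vivo).
#'
#' @param field a `flow_field`.
#' @param min_valid_sites validity threshold on the local diameter in lattice
#'   sites (default 7).
#' @param wss_cap plausibility cap, Pa (default 20). For lattice-unit
#'   benchmark fields the cap is applied to lattice-unit magnitudes and is
#'   only meaningful if scaled by the caller.
#' @return data frame: one row per wall link with the wall-point position,
#'   normal, traction components, `wss`, `valid` and `unphysiological`.
#' @export
compute_traction <- function(field, min_valid_sites = 7, wss_cap = 20) {
  dom <- field$domain
  wl <- dom$wall_links
  if (!nrow(wl)) return(data.frame())
  if (is.null(wl$nx)) stop("domain wall links carry no surface normals")
  s <- field$stress[wl$site + 1L, , drop = FALSE]
  nx <- wl$nx; ny <- wl$ny; nz <- wl$nz
  tx <- s[, 1] * nx + s[, 4] * ny + s[, 5] * nz
  ty <- s[, 4] * nx + s[, 2] * ny + s[, 6] * nz
  tz <- s[, 5] * nx + s[, 6] * ny + s[, 3] * nz
  wss <- sqrt(tx^2 + ty^2 + tz^2)
  data.frame(site = wl$site, dir = wl$dir, q = wl$q,
             nx = nx, ny = ny, nz = nz,
             tx = tx, ty = ty, tz = tz, wss = wss,
             D_local = wl$D_local,
             valid = wl$D_local >= min_valid_sites,
             unphysiological = wss > wss_cap)
}

#' Summarize a traction table
#'
#' @param traction output of [compute_traction()].
#' @return list with WSS quantiles, the fraction of links flagged valid and
#'   the fraction flagged unphysiological.
#' @export
summarize_wss <- function(traction) {
  if (!nrow(traction)) return(list(n = 0L))
  list(n = nrow(traction),
       wss_quantiles = stats::quantile(traction$wss, c(0, 0.25, 0.5, 0.75, 0.95, 1)),
       frac_valid = mean(traction$valid),
       frac_unphysiological = mean(traction$unphysiological))
}
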