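#' Carreau-Yasuda generalized-Newtonian viscosity
#'
#' Evaluates the five-parameter Carreau-Yasuda law
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
#'       \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' which joins a low-shear Newtonian plateau \eqn{\eta_0} and a high-shear
#' plateau \eqn{\eta_\infty} through a shear-thinning transition of sharpness
#' \eqn{a} and power-law index \eqn{n}. Blood is shear thinning
#' (\eqn{\eta_0 > \eta_\infty}, \eqn{0 < n < 1}).
#'
#' @param gamma_dot shear rate(s), 1/s; must be non-negative.
#' @param params a [cy_params()] object (viscosities in mPa s, `lam` in s).
#' @return viscosity in the same units as `params$eta0` (mPa s by convention).
#' @examples
#' cy_viscosity(c(0, 100, 1e6), cy_params(14.49, 3.265, 0.1839, 2.707, 0.4136))
#' @export
cy_viscosity <- function(gamma_dot, params) {
  params <- as_cy_params(params)
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("shear rate must be finite and non-negative")
  params$eta_inf + (params$eta0 - params$eta_inf) *
    (1 + (params$lam * gamma_dot)^params$a)^((params$n - 1) / params$a)
}

#' Construct a Carreau-Yasuda parameter set
#'
#' @param eta0 low-shear plateau viscosity, mPa s.
#' @param eta_inf high-shear plateau viscosity, mPa s; `eta_inf <= eta0`.
#' @param lam relaxation time \eqn{\lambda}, s.
#' @param a transition-sharpness exponent (dimensionless, > 0).
#' @param n power-law index (dimensionless; < 1 for shear thinning).
#' @return object of class `cy_params`.
#' @export
cy_params <- function(eta0, eta_inf, lam, a, n) {
  stopifnot(is.finite(eta0), is.finite(eta_inf), is.finite(lam),
            is.finite(a), is.finite(n))
  if (eta_inf <= 0 || eta0 < eta_inf)
    stop("need eta0 >= eta_inf > 0")
  if (lam <= 0 || a <= 0) stop("need lam > 0 and a > 0")
  structure(list(eta0 = eta0, eta_inf = eta_inf, lam = lam, a = a, n = n),
            class = "cy_params")
}

as_cy_params <- function(x) {
  if (inherits(x, "cy_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(cy_params(x$eta0, x$eta_inf, x$lam, x$a, x$n))
  }
  stop("cannot interpret object as Carreau-Yasuda parameters")
}

#' @export
print.cy_params <- function(x, ...) {
  cat(sprintf(
    "Carreau-Yasuda parameters:\n  eta0 = %.4g mPa s, eta_inf = %.4g mPa s\n  lambda = %.4g s, a = %.4g, n = %.4g\n",
    x$eta0, x$eta_inf, x$lam, x$a, x$n))
  invisible(x)
}

#' Fit the Carreau-Yasuda model to viscometry data
#'
#' Unweighted nonlinear least squares on viscosity (not log-viscosity) via
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]), restarted from multiple
#' seeded log-uniform initial guesses to escape local minima. The best
#' converged start (smallest residual sum of squares) is returned.
#'
#' The transition exponent is constrained to `a <= 10`: on noisy viscometry
#' tables the unconstrained least-squares surface develops a competing
#' near-degenerate minimum with an effectively discontinuous transition
#' (`a` diverging) and a sub-plasma high-shear plateau, which is not a
#' haemorheologically meaningful solution.
#'
#' @param data data frame with columns `shear_rate` (1/s) and `viscosity`
#'   (mPa s), e.g. from [mouse_blood_viscosity()].
#' @param starts number of multi-start draws.
#' @param seed RNG seed for the start draws (local, does not touch the
#'   global RNG state).
#' @return a `cy_fit` object: the fitted [cy_params()] plus `residual_norm`
#'   (root of the residual sum of squares, mPa s), `n_converged`, and the
#'   input data.
#' @examples
#' fit <- fit_cy(mouse_blood_viscosity())
#' fit$params
#' @export
fit_cy <- function(data, starts = 32L, seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("shear_rate", "viscosity") %in% names(data)))
  g <- as.numeric(data$shear_rate)
  eta <- as.numeric(data$viscosity)
  if (any(g < 0) || any(eta <= 0)) stop("invalid viscometry data")
  if (length(g) < 6) stop("need at least 6 data points to fit 5 parameters")
  if (diff(range(log10(pmax(g, 1e-6)))) < 1)
    stop("shear rates must span at least one decade")

  resid_fn <- function(p) {
    eta_inf <- p[2]; eta0 <- eta_inf + p[1]   # p[1] = eta0 - eta_inf >= 0
    eta_inf + (eta0 - eta_inf) * (1 + (p[3] * g)^p[4])^((p[5] - 1) / p[4]) - eta
  }
  lower <- c(1e-8, 1e-8, 1e-8, 1e-3, 1e-4)
  upper <- c(1e4, 1e4, 1e4, 10, 0.9999)   # a <= 10: see Details

  rng <- local({ set.seed(seed); function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi))) })
  best <- NULL
  n_conv <- 0L
  e_hi <- stats::median(eta[g >= stats::median(g)])
  e_lo <- max(eta)
  for (i in seq_len(starts)) {
    p0 <- c(rng(1, 0.2 * e_lo, 4 * e_lo), rng(1, 0.2 * e_hi, 3 * e_hi),
            rng(1, 1e-3, 10), rng(1, 0.3, 5), stats::runif(1, 0.05, 0.95))
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.finite(rss)) {
      n_conv <- n_conv + 1L
      if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
    }
  }
  if (is.null(best))
    stop("Carreau-Yasuda fit failed: no start converged (", starts, " attempted)")
  p <- best$par
  structure(list(
    params = cy_params(eta0 = p[1] + p[2], eta_inf = p[2], lam = p[3],
                       a = p[4], n = p[5]),
    residual_norm = sqrt(best$rss),
    n_converged = n_conv,
    data = data.frame(shear_rate = g, viscosity = eta)),
    class = "cy_fit")
}

#' @export
print.cy_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  residual norm %.4g mPa s over %d points (%d starts converged)\n",
              x$residual_norm, nrow(x$data), x$n_converged))
  invisible(x)
}

#' Murine blood viscosity versus shear rate
#'
#' The packaged viscometry table for adult mouse blood: 8 points measured in
#' C57Bl/6 mice and 3 in BALB/c mice, mixed as a single unweighted data set.
#' Units: shear rate 1/s, viscosity mPa s.
#'
#' @return data frame with columns `shear_rate`, `viscosity`, `source`.
#' @export
mouse_blood_viscosity <- function() {
  read_viscosity_csv(system.file("extdata", "mouse_blood_viscosity.csv",
                                 package = "plexusflow", mustWork = TRUE))
}

#' Read / write viscometry tables
#'
#' CSV with columns `shear_rate_s-1`, `viscosity_mPa_s` and optionally
#' `source`.
#'
#' @param path file path.
#' @rdname viscosity_io
#' @export
read_viscosity_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  cn <- names(d)
  sr <- grep("^shear", cn, ignore.case = TRUE)[1]
  vi <- grep("^visc", cn, ignore.case = TRUE)[1]
  if (is.na(sr) || is.na(vi)) stop("viscosity CSV needs shear_rate and viscosity columns")
  out <- data.frame(shear_rate = as.numeric(d[[sr]]),
                    viscosity = as.numeric(d[[vi]]))
  src <- grep("^source", cn, ignore.case = TRUE)[1]
  out$source <- if (!is.na(src)) as.character(d[[src]]) else ""
  out
}

#' @param data data frame as returned by [read_viscosity_csv()].
#' @rdname viscosity_io
#' @export
write_viscosity_csv <- function(data, path) {
  out <- data.frame(`shear_rate_s-1` = data$shear_rate,
                    viscosity_mPa_s = data$viscosity,
                    source = if (is.null(data$source)) "" else data$source,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
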