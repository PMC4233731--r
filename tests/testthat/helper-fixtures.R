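# Shared fixtures, built in code at test time.

# printed Carreau-Yasuda constants for murine blood (reference values the
# rheology tests compare against)
cy_reference <- function() {
  cy_params(eta0 = 14.49, eta_inf = 3.265, lam = 0.1839, a = 2.707, n = 0.4136)
}

# straight two-node tube skeleton
tube_skeleton <- function(length_um = 120, radius_um = 8) {
  skeleton_graph(
    nodes = data.frame(x = c(0, length_um), y = 0, z = 0, radius = radius_um),
    edges = data.frame(from = 1, to = 2),
    inlet = 1, outlet = 2)
}

# fully periodic box domain for conservation tests (all sites fluid)
periodic_box_nbr <- function(nx = 6, ny = 5, nz = 4) {
  shape <- c(nx, ny, nz)
  st <- array(1L, dim = shape)
  plexusflow:::build_nbr(st, shape, seq_len(prod(shape)), periodic = TRUE)
}

# run the kernel directly on a caps-free, wall-free periodic box
run_periodic <- function(nbr, tau = 0.8, steps = 50, tol = 0) {
  n <- nrow(nbr)
  plexusflow:::.lbm_run_cpp(
    nbr = nbr, kind = rep(1L, n),
    wl_site = integer(), wl_dir = integer(), wl_q = numeric(), wl_vt = numeric(),
    cap_u = matrix(0, n, 3), cap_rho = rep(1, n), cap_nbr = rep(-1L, n),
    tau0 = tau, cy_mode = FALSE, cy_par = rep(0, 5),
    conv_nu = 0, conv_gamma = 0, tau_min = 0.505, tau_max = 3,
    max_steps = as.integer(steps), tol = tol, v_ref = 1,
    history_every = 0L, plain_bb = FALSE, min_steps = as.integer(steps),
    group_id = rep(-1L, n), cap_id = rep(-1L, n))
}

# deterministic random symmetric 3x3 tensors
random_symmetric <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- matrix(stats::rnorm(9), 3, 3)
    (a + t(a)) / 2
  })
}
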