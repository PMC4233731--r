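test_that("inclined axis sampling is seeded, inclined and symmetric", {
  a1 <- sample_inclined_axis(11)
  expect_identical(a1, sample_inclined_axis(11))
  expect_equal(sum(a1^2), 1, tolerance = 1e-12)

  # every accepted vector keeps >= 15 degrees from each lattice axis plane:
  # direct angle computation against the three coordinate axes
  for (sd in 1:25) {
    a <- sample_inclined_axis(sd)
    ang_to_planes <- asin(abs(a)) * 180 / pi
    expect_true(all(ang_to_planes >= 15 - 1e-9))
  }

  # Monte-Carlo symmetry: component means vanish
  draws <- t(vapply(1:2000, sample_inclined_axis, numeric(3)))
  expect_true(all(abs(colMeans(draws)) < 0.05))
})

test_that("Poiseuille flow rate matches closed form and disc quadrature", {
  expect_equal(poiseuille_flow_rate(3, 0), 0)
  expect_equal(poiseuille_flow_rate(1, 2), pi)

  # oracle: 2D midpoint quadrature of v(r) over the disc
  R <- 10e-6; nu <- 3.1e-6; Re <- 1
  v_max <- 2 * Re * nu / (2 * R)
  h <- R / 400
  xs <- seq(-R + h / 2, R - h / 2, by = h)
  grid <- expand.grid(x = xs, y = xs)
  r2 <- grid$x^2 + grid$y^2
  Q_quad <- sum(v_max * pmax(0, 1 - r2 / R^2)[r2 <= R^2]) * h^2
  expect_equal(poiseuille_flow_rate(R, v_max), Q_quad, tolerance = 1e-4)
})

test_that("parabolic inlet profile has the right peak, rim and midpoint", {
  p0 <- c(0, 0, 0); ax <- c(0, 0, 1); R <- 2; vm <- 3
  expect_equal(parabolic_inlet_profile(p0, p0, ax, R, vm), vm * ax)
  expect_equal(parabolic_inlet_profile(c(R, 0, 0), p0, ax, R, vm), c(0, 0, 0))
  expect_equal(parabolic_inlet_profile(c(R / 2, 0, 0), p0, ax, R, vm),
               0.75 * vm * ax)
  expect_error(parabolic_inlet_profile(c(2 * R, 0, 0), p0, ax, R, vm), "outside")
})

test_that("axial Poiseuille stress tensor has the closed-form structure", {
  R <- 2; eta <- 0.1; vm <- 0.5
  expect_equal(poiseuille_stress_axial(0, 0, R, eta, vm), matrix(0, 3, 3))
  Tw <- poiseuille_stress_axial(R, 0, R, eta, vm)
  expect_equal(sqrt(sum(Tw^2)), 2 * sqrt(2) * eta * vm / R)
  expect_equal(Tw[1, 3], -2 * eta * vm / R)
  Th <- poiseuille_stress_axial(R / 2, 0, R, eta, vm)
  expect_equal(sqrt(sum(Th^2)), sqrt(sum(Tw^2)) / 2)  # linear in r
  expect_equal(Tw, t(Tw))
  expect_equal(sum(diag(Tw)), 0)
  expect_error(poiseuille_stress_axial(3, 0, R, eta, vm), "outside")
})

test_that("rotation construction is orthonormal, proper and norm preserving", {
  expect_equal(rotation_from_axis(c(0, 0, 1)), diag(3))
  tensors <- random_symmetric(8, seed = 7)
  set.seed(8)
  for (i in 1:8) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    Rot <- rotation_from_axis(ax)
    expect_equal(t(Rot) %*% Rot, diag(3), tolerance = 1e-12)
    expect_equal(det(Rot), 1, tolerance = 1e-12)
    expect_equal(drop(Rot %*% c(0, 0, 1)), ax, tolerance = 1e-12)
    Tp <- tensors[[i]]
    expect_equal(sqrt(sum(rotate_tensor(Tp, Rot)^2)), sqrt(sum(Tp^2)),
                 tolerance = 1e-12)
    expect_equal(sum(diag(rotate_tensor(Tp, Rot))), sum(diag(Tp)),
                 tolerance = 1e-12)
  }
  expect_equal(rotate_tensor(tensors[[1]], diag(3)), tensors[[1]])
  expect_error(rotation_from_axis(c(0, 0, 0)), "nonzero")
})

test_that("rotated stress matches direct differentiation of the rotated field", {
  # oracle: numerically differentiate v(x) = v_max (1 - r'^2/R^2) n_hat and
  # assemble T = eta (grad v + grad v^T)
  ax <- sample_inclined_axis(5); R <- 3; eta <- 0.2; vm <- 0.7
  p0 <- c(0, 0, 0)
  vel <- function(x) {
    d <- x - p0; r2 <- sum(d^2) - sum(d * ax)^2
    vm * (1 - r2 / R^2) * ax
  }
  x0 <- p0 + 0.6 * R * { e <- c(ax[2], -ax[1], 0); e / sqrt(sum(e^2)) }
  h <- 1e-6
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    dv <- (vel(x0 + h * diag(3)[, j]) - vel(x0 - h * diag(3)[, j])) / (2 * h)
    J[, j] <- dv
  }
  T_fd <- eta * (J + t(J))
  T_an <- poiseuille_stress_rotated(x0, p0, ax, R, eta, vm)
  expect_equal(T_an, T_fd, tolerance = 1e-6)
})

test_that("error norms behave and are scale invariant", {
  expect_equal(flow_rate_error(5, 5), 0)
  expect_equal(flow_rate_error(0.97 * 5, 5), 0.03)
  expect_error(flow_rate_error(1, 0), "nonzero")

  Ts <- random_symmetric(5, seed = 3)
  for (Tp in Ts) {
    expect_equal(tensor_error_frobenius(Tp, Tp), 0)
    # scale invariance
    expect_equal(tensor_error_frobenius(1.1 * Tp, Tp),
                 tensor_error_frobenius(1.1 * 7 * Tp, 7 * Tp))
    # component permutation with matched norm still registers as error
    Tperm <- Tp[c(2, 3, 1), c(2, 3, 1)]
    if (sqrt(sum((Tperm - Tp)^2)) > 1e-12)
      expect_gt(tensor_error_frobenius(Tperm, Tp), 0)
    # invariant under simultaneous rotation
    Rot <- rotation_from_axis(sample_inclined_axis(9))
    expect_equal(tensor_error_frobenius(1.2 * Tp, Tp),
                 tensor_error_frobenius(rotate_tensor(1.2 * Tp, Rot),
                                        rotate_tensor(Tp, Rot)),
                 tolerance = 1e-12)
  }
  expect_true(is.na(tensor_error_frobenius(diag(3), matrix(0, 3, 3))))
})
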