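test_that("skeletonization recovers strip, disc and Y-junction geometry", {
  # straight strip, width 10 px: midline centreline, radius ~5 px
  strip <- matrix(FALSE, 30, 220); strip[11:20, 11:210] <- TRUE
  sk <- skeletonize_mask(strip, pixel_size = 1)
  expect_true(all(abs(sk$nodes$radius - 5) <= 1))
  expect_true(all(abs(sk$nodes$y - 15.5) <= 1.5))

  # filled disc of radius 20 px: medial axis collapses to the centre,
  # radius ~20 px
  disc <- matrix(FALSE, 60, 60)
  xy <- as.matrix(expand.grid(1:60, 1:60))
  disc[xy[(xy[, 1] - 30)^2 + (xy[, 2] - 30)^2 <= 400, ]] <- TRUE
  skd <- skeletonize_mask(disc)
  expect_lte(nrow(skd$nodes), 5)
  expect_equal(max(skd$nodes$radius), 20, tolerance = 0.1)
  expect_true(all(abs(skd$nodes$x - 30) <= 3 & abs(skd$nodes$y - 30) <= 3))

  # Y junction built as a union of constant-width bands around three
  # segments (stem half-width 6 px, arms 4 px): exactly one degree-3 node
  # and arm radii near the half-widths
  seg_dist <- function(px, py, a, b) {
    v <- b - a; t <- pmin(pmax(((px - a[1]) * v[1] + (py - a[2]) * v[2]) /
                               sum(v^2), 0), 1)
    sqrt((px - (a[1] + t * v[1]))^2 + (py - (a[2] + t * v[2]))^2)
  }
  gr <- expand.grid(r = 1:140, c = 1:140)
  dstem <- seg_dist(gr$r, gr$c, c(70, 70), c(130, 70))
  darm1 <- seg_dist(gr$r, gr$c, c(70, 70), c(25, 25))
  darm2 <- seg_dist(gr$r, gr$c, c(70, 70), c(25, 115))
  Y <- matrix(dstem <= 6 | darm1 <= 4 | darm2 <= 4, 140, 140)
  sky <- skeletonize_mask(Y)
  g <- igraph::graph_from_edgelist(as.matrix(sky$edges[, 1:2]), directed = FALSE)
  expect_equal(sum(igraph::degree(g) >= 3), 1)
  far <- sky$nodes[sky$nodes$y < 45, ]        # arm pixels far from the junction
  expect_true(all(abs(far$radius - 4) <= 1.5))
  stem <- sky$nodes[sky$nodes$y > 100, ]
  expect_true(all(abs(stem$radius - 6) <= 1.5))

  expect_error(skeletonize_mask(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 40, 40); two[5:10, 5:30] <- TRUE; two[25:28, 5:15] <- TRUE
  expect_warning(skeletonize_mask(two), "largest")
})

test_that("voxelized cylinder volume matches the analytic value", {
  # single axis-aligned cylinder R = 6dx, L = 40dx; oracle: exact volume
  sk <- skeleton_graph(
    nodes = data.frame(x = c(0, 40), y = 0, z = 0, radius = 6),
    edges = data.frame(from = 1, to = 2), inlet = 1, outlet = 2)
  dom <- voxelize_network(sk, dx = 1)
  n_fluid <- sum(dom$kind >= 1)
  # junction spheres at the two end nodes are cut by the cap planes, leaving
  # exactly the node-to-node cylinder volume
  expect_equal(n_fluid, pi * 6^2 * 40, tolerance = 0.03)
  # every cut link carries a usable q
  expect_true(all(dom$wall_links$q > 0 & dom$wall_links$q <= 1))
})

test_that("thin segments are clamped to the minimum resolved diameter", {
  sk <- skeleton_graph(
    nodes = data.frame(x = c(0, 20, 40), y = 0, z = 0,
                       radius = c(4, 0.4, 4)),
    edges = data.frame(from = c(1, 2), to = c(2, 3), radius = c(4, 0.4)),
    inlet = 1, outlet = 3)
  dom <- voxelize_network(sk, dx = 1, min_diameter_sites = 3)
  expect_equal(dom$meta$clamped_segments, 2L)
  expect_equal(dom$meta$segments$radius[2], 1.5)  # 3 sites * dx / 2
})

test_that("voxelization requires boundary designations", {
  sk <- skeleton_graph(
    nodes = data.frame(x = c(0, 40), y = 0, z = 0, radius = 6),
    edges = data.frame(from = 1, to = 2))
  expect_error(voxelize_network(sk, 1), "inlet")
})

test_that("inclined-cylinder q values match bisection on the implicit surface", {
  dom <- make_inclined_cylinder(7, seed = 1, v_max = 0.01)
  m <- dom$meta
  dirs <- plexusflow:::lbm_dirs()
  ijk <- plexusflow:::active_coords(dom)
  wl <- dom$wall_links[!dom$wall_links$on_inlet, ]
  phi <- function(x) {
    d <- x - m$p0; s <- sum(d * m$axis)
    max(sqrt(sum(d^2) - s^2) - m$R, s - m$L)
  }
  set.seed(1)
  for (i in sample(nrow(wl), 25)) {
    x0 <- ijk[wl$site[i] + 1, ]; ck <- dirs[wl$dir[i], ]
    lo <- 0; hi <- 1
    for (it in 1:45) {
      mid <- (lo + hi) / 2
      if (phi(x0 + mid * ck) < 0) lo <- mid else hi <- mid
    }
    expect_equal(wl$q[i], (lo + hi) / 2, tolerance = 1e-6)
  }
})

test_that("narrow inclined cylinders keep at least the nominal cross-section", {
  dom <- make_inclined_cylinder(3, seed = 1, v_max = 0.01)
  ijk <- plexusflow:::active_coords(dom)
  m <- dom$meta
  e <- which.max(abs(m$axis))
  # every lattice plane fully inside the tube (away from both end planes)
  lo <- ceiling((m$p0 + 2 * m$axis)[e]); hi <- floor((m$p0 + (m$L - 2) * m$axis)[e])
  per_plane <- table(factor(ijk[ijk[, e] >= lo & ijk[, e] <= hi, e],
                            levels = lo:hi))
  expect_true(all(per_plane >= 3))   # never fewer than 3 sites per cut
})

test_that("axis-aligned cylinder q is ring-like: invariant along the axis", {
  dom <- make_inclined_cylinder(9, axis = c(0, 0, 1), v_max = 0.01)
  ijk <- plexusflow:::active_coords(dom)
  m <- dom$meta
  wl <- dom$wall_links[!dom$wall_links$on_inlet, ]
  x <- ijk[wl$site + 1, 1] - m$p0[1]
  y <- ijk[wl$site + 1, 2] - m$p0[2]
  z <- ijk[wl$site + 1, 3] - m$p0[3]
  mid <- z > 9 & z < m$L - 9          # away from the end planes
  # for each (in-plane position, direction) the wall distance must not
  # depend on the axial coordinate: the 3D tube reduces to the 2D disc
  spread <- tapply(wl$q[mid], paste(x[mid], y[mid], wl$dir[mid]),
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))
  # and the in-plane q solves the 2D circle intersection exactly
  dirs <- plexusflow:::lbm_dirs()
  lat <- mid & dirs[wl$dir, 3] == 0
  for (i in which(lat)[1:20]) {
    ck <- dirs[wl$dir[i], 1:2]
    A <- sum(ck^2); B <- 2 * sum(c(x[i], y[i]) * ck)
    C <- x[i]^2 + y[i]^2 - m$R^2
    t1 <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
    expect_equal(wl$q[i], t1, tolerance = 1e-9)
  }
})

test_that("diameter histogram is length-weighted with exact mass", {
  sk <- skeleton_graph(
    nodes = data.frame(x = c(0, 100), y = 0, z = 0, radius = 2.5),
    edges = data.frame(from = 1, to = 2))
  h <- diameter_histogram(sk, bin_width = 1)
  expect_equal(sum(h$length_per_bin), 100)
  expect_equal(h$length_per_bin[findInterval(5, h$bin_edges)], 100)
  expect_true(is.na(h$mode))  # single segment: fit refused

  # 2000 segments, lognormal diameters, equal lengths: mode recovered
  set.seed(9)
  nseg <- 2000
  d <- stats::rlnorm(nseg, log(5), 0.4)
  nodes <- data.frame(x = rep(seq_len(nseg), each = 2) * 10,
                      y = rep(c(0, 5), nseg), z = 0,
                      radius = rep(d / 2, each = 2))
  edges <- data.frame(from = seq(1, 2 * nseg, 2), to = seq(2, 2 * nseg, 2),
                      radius = d / 2)
  h2 <- diameter_histogram(skeleton_graph(nodes, edges), bin_width = 0.5)
  expect_equal(sum(h2$length_per_bin), 2000 * 5)
  expect_equal(h2$mode, 5 * exp(-0.16), tolerance = 0.05)
})

test_that("voxel-size rule returns the length-weighted coverage quantile", {
  # uniform network: dx = D / 3
  sk <- skeleton_graph(
    nodes = data.frame(x = c(0, 50, 100), y = 0, z = 0, radius = 2.5),
    edges = data.frame(from = c(1, 2), to = c(2, 3)))
  expect_equal(choose_voxel_size(sk), 5 / 3)

  # two-diameter network, 96% of length at 6 um, 4% at 1 um: the thin tail
  # is sacrificed and dx = 2 um (hand-computed quantile)
  sk2 <- skeleton_graph(
    nodes = data.frame(x = c(0, 96, 100), y = 0, z = 0, radius = c(3, 3, 0.5)),
    edges = data.frame(from = c(1, 2), to = c(2, 3), radius = c(3, 0.5)))
  expect_equal(choose_voxel_size(sk2, coverage = 0.95), 2)

  # synthetic lognormal-diameter network: the returned dx satisfies the
  # constraint and is maximal (oracle: direct length-weighted tally)
  set.seed(5)
  nseg <- 400
  d <- stats::rlnorm(nseg, log(5), 0.35)
  nodes <- data.frame(x = rep(seq_len(nseg), each = 2) * 10,
                      y = rep(c(0, 7), nseg), z = 0, radius = rep(d / 2, each = 2))
  edges <- data.frame(from = seq(1, 2 * nseg, 2), to = seq(2, 2 * nseg, 2),
                      radius = d / 2)
  sk3 <- skeleton_graph(nodes, edges)
  dx <- choose_voxel_size(sk3, coverage = 0.95)
  covered <- function(dd) sum((d >= dd * 3) * 7) / (nseg * 7)
  expect_gte(covered(dx), 0.95)
  expect_lt(covered(dx * 1.001), 0.95)

  expect_error(choose_voxel_size(skeleton_graph(
    data.frame(x = c(0, 1), y = 0, z = 0, radius = 1e-12),
    data.frame(from = 1, to = 2))), "degenerate")
})

test_that("synthetic plexus is deterministic with the advertised topology", {
  sk1 <- generate_synthetic_plexus(n_rungs = 6, seed = 11)
  sk2 <- generate_synthetic_plexus(n_rungs = 6, seed = 11)
  expect_identical(sk1, sk2)
  expect_false(identical(sk1, generate_synthetic_plexus(n_rungs = 6, seed = 12)))

  # cycle rank equals the rung count
  g <- igraph::graph_from_edgelist(as.matrix(sk1$edges[, 1:2]), directed = FALSE)
  expect_equal(igraph::ecount(g) - igraph::vcount(g) +
               igraph::components(g)$no, 6)
  expect_length(sk1$inlet, 1)
  expect_length(sk1$outlet, 1)

  # capillary diameter law: histogram mode near the lognormal mode
  skbig <- generate_synthetic_plexus(n_rungs = 40, cap_meanlog = log(5),
                                     cap_sdlog = 0.3, seed = 2)
  caps <- plexusflow:::segment_table(skbig)
  caps <- caps[abs(2 * caps$radius - 16) > 1e-9 & abs(2 * caps$radius - 20) > 1e-9, ]
  mu <- sum(caps$length * log(2 * caps$radius)) / sum(caps$length)
  expect_equal(exp(mu), 5, tolerance = 0.1)

  expect_error(generate_synthetic_plexus(width = 20), "overlap")
})

test_that("skeleton IO round-trips through CSV and JSON", {
  sk <- generate_synthetic_plexus(n_rungs = 3, seed = 4)
  stem <- tempfile()
  write_skeleton_csv(sk, stem)
  sk2 <- read_skeleton_csv(stem)
  expect_equal(sk2$nodes$x, sk$nodes$x)
  expect_equal(sk2$nodes$radius, sk$nodes$radius)
  expect_equal(sk2$inlet, sk$inlet)
  jp <- tempfile(fileext = ".json")
  write_skeleton_json(sk, jp)
  sk3 <- read_skeleton_json(jp)
  expect_equal(sk3$edges$radius, sk$edges$radius)
  expect_equal(sk3$outlet, sk$outlet)

  # plain-text mask reader
  mp <- tempfile(fileext = ".txt")
  m <- matrix(0L, 4, 6); m[2:3, 2:5] <- 1L
  write.table(m, mp, row.names = FALSE, col.names = FALSE)
  expect_equal(read_mask(mp), m > 0)
})
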