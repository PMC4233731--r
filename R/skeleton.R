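# Vessel-network skeletons: the centreline-plus-radius representation that
# links the imaging side (binary masks) to the simulation side (voxel
# domains), with diameter statistics and fixture generators.

#' Construct a skeleton graph
#'
#' A skeleton graph is the package's reconstruction currency: centreline
#' nodes carrying positions (micrometres) and local radii (the
#' maximum-inscribed-circle radius), an edge list of centreline segments,
#' and the designation of boundary nodes acting as flow inlets and outlets.
#'
#' @param nodes data frame with columns `x`, `y`, `z` (um; `z` may be
#'   omitted for planar networks) and `radius` (um).
#' @param edges data frame with columns `from`, `to` (node indices) and
#'   optionally `radius` (um, per-segment override of the node radii).
#' @param inlet,outlet integer vectors of boundary node indices.
#' @return object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges, inlet = integer(), outlet = integer()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (is.null(nodes$z)) nodes$z <- 0
  stopifnot(all(c("x", "y", "z", "radius") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (nrow(nodes) && any(nodes$radius <= 0)) stop("node radii must be positive")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    if (any(edges$from < 1 | edges$from > nrow(nodes) |
            edges$to < 1 | edges$to > nrow(nodes)))
      stop("edge endpoints out of range")
  }
  structure(list(nodes = nodes, edges = edges,
                 inlet = as.integer(inlet), outlet = as.integer(outlet)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  seg <- segment_table(x)
  cat(sprintf(
    "skeleton graph: %d nodes, %d segments, total length %.1f um\n  diameters %.2f-%.2f um; %d inlet(s), %d outlet(s)\n",
    nrow(x$nodes), nrow(x$edges), sum(seg$length),
    min(2 * seg$radius), max(2 * seg$radius),
    length(x$inlet), length(x$outlet)))
  invisible(x)
}

# per-edge segment table: endpoints, radius (edge override or mean of node
# radii), length
segment_table <- function(sk) {
  n <- sk$nodes; e <- sk$edges
  if (!nrow(e)) stop("skeleton has no segments")
  r <- if (!is.null(e$radius)) e$radius else
    (n$radius[e$from] + n$radius[e$to]) / 2
  data.frame(
    from = e$from, to = e$to,
    x1 = n$x[e$from], y1 = n$y[e$from], z1 = n$z[e$from],
    x2 = n$x[e$to], y2 = n$y[e$to], z2 = n$z[e$to],
    radius = r,
    length = sqrt((n$x[e$from] - n$x[e$to])^2 + (n$y[e$from] - n$y[e$to])^2 +
                  (n$z[e$from] - n$z[e$to])^2))
}

#' Skeletonize a binary vessel mask
#'
#' Reduces a 2D binary lumen mask to a centreline graph with the
#' maximum-inscribed-circle radius at every centreline pixel: the mask is
#' thinned to a one-pixel skeleton and the radius at each skeleton pixel is
#' read off the Euclidean distance transform of the mask. Short terminal
#' spurs (an artefact of thinning at boundary irregularities) are pruned,
#' and runs of adjacent junction pixels are merged into single branch
#' points.
#'
#' @param mask logical or 0/1 matrix (TRUE/1 = lumen). If several foreground
#'   components exist the largest is kept with a warning.
#' @param pixel_size pixel edge length, micrometres.
#' @param prune_factor terminal spurs shorter than `prune_factor` times the
#'   local radius are removed (default 2).
#' @return a [skeleton_graph()] (coordinates in um: `x` = column index,
#'   `y` = row index, scaled by `pixel_size`; no inlets/outlets designated).
#' @export
skeletonize_mask <- function(mask, pixel_size = 1, prune_factor = 2) {
  m <- mask
  if (is.numeric(m)) m <- m > 0.5
  if (!is.logical(m) || !is.matrix(m)) stop("mask must be a logical or 0/1 matrix")
  if (!any(m)) stop("mask is empty")

  lab <- EBImage::bwlabel(m * 1)
  n_comp <- max(lab)
  if (n_comp > 1) {
    warning("mask has ", n_comp, " components; keeping the largest")
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }

  edt <- as.matrix(EBImage::distmap(m * 1))     # Euclidean distance to background
  skel <- .thin_mask_cpp(m)

  px <- which(skel, arr.ind = TRUE)             # (row, col) of skeleton pixels
  if (!nrow(px)) stop("thinning removed all pixels (degenerate mask)")
  idx <- matrix(0L, nrow(m), ncol(m))
  idx[px] <- seq_len(nrow(px))

  # 8-neighbour pixel adjacency (scan E, SE, S, SW to avoid duplicates)
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  el <- list()
  for (i in seq_len(nrow(offs))) {
    r2 <- px[, 1] + offs[i, 1]; c2 <- px[, 2] + offs[i, 2]
    ok <- r2 >= 1 & r2 <= nrow(m) & c2 >= 1 & c2 <= ncol(m)
    ok[ok] <- idx[cbind(r2[ok], c2[ok])] > 0
    if (any(ok))
      el[[length(el) + 1L]] <- cbind(idx[px[ok, , drop = FALSE]],
                                     idx[cbind(r2[ok], c2[ok])])
  }
  edges <- if (length(el)) do.call(rbind, el) else matrix(integer(), 0, 2)

  nodes <- data.frame(x = px[, 2] * pixel_size, y = px[, 1] * pixel_size,
                      z = 0, radius = pmax(edt[px], 0.5) * pixel_size)

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(nodes))
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))

  # prune short terminal spurs
  repeat {
    deg <- igraph::degree(g)
    removed <- FALSE
    for (leaf in which(deg == 1)) {
      path <- leaf
      cur <- leaf
      prev <- 0L
      len <- 0
      repeat {
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nxt) != 1 || deg[nxt[1]] > 2) break
        len <- len + sqrt(sum((nodes[cur, c("x", "y")] - nodes[nxt[1], c("x", "y")])^2))
        prev <- cur; cur <- nxt[1]; path <- c(path, cur)
        if (len > 10 * prune_factor * nodes$radius[leaf]) break
      }
      junction <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
      at_junction <- length(junction) && any(deg[junction] >= 3)
      if (at_junction && len < prune_factor * nodes$radius[cur]) {
        g <- igraph::delete_vertices(g, path)
        keep <- setdiff(seq_len(nrow(nodes)), path)
        nodes <- nodes[keep, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  rownames(nodes) <- NULL

  # merge runs of adjacent junction pixels into single branch points
  deg <- igraph::degree(g)
  jn <- which(deg >= 3)
  if (length(jn) > 1) {
    sub <- igraph::induced_subgraph(g, jn)
    comp <- igraph::components(sub)$membership
    grp <- rep(0L, nrow(nodes)); grp[jn] <- comp
    map <- seq_len(nrow(nodes))
    for (cc in unique(comp)) {
      members <- jn[comp == cc]
      if (length(members) > 1) map[members] <- members[1]
    }
    el2 <- igraph::as_edgelist(g)
    el2 <- cbind(map[el2[, 1]], map[el2[, 2]])
    el2 <- el2[el2[, 1] != el2[, 2], , drop = FALSE]
    el2 <- unique(t(apply(el2, 1, sort)))
    # centroid position/max radius for merged junctions
    for (cc in unique(comp)) {
      members <- jn[comp == cc]
      if (length(members) > 1) {
        nodes$x[members[1]] <- mean(nodes$x[members])
        nodes$y[members[1]] <- mean(nodes$y[members])
        nodes$radius[members[1]] <- max(nodes$radius[members])
      }
    }
    used <- sort(unique(as.integer(el2)))
    renum <- integer(nrow(nodes)); renum[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]; rownames(nodes) <- NULL
    edges_df <- data.frame(from = renum[el2[, 1]], to = renum[el2[, 2]])
  } else {
    el2 <- igraph::as_edgelist(g)
    edges_df <- data.frame(from = el2[, 1], to = el2[, 2])
  }

  skeleton_graph(nodes, edges_df)
}

#' Generate a synthetic planar plexus
#'
#' Builds an arcade-style ladder network emulating the gross topology of a
#' developing retinal plexus region: one feeding (arterial) trunk and one
#' draining (venous) trunk running side by side, joined by `n_rungs`
#' capillary cross-connections and a distal anastomosis, so the graph has
#' exactly `n_rungs` independent cycles. Capillary diameters are drawn from
#' a lognormal distribution, the typical diameter law observed in real
#' plexus reconstructions. Deterministic for a given seed.
#'
#' @param n_rungs number of capillary rungs (>= 1).
#' @param trunk_artery,trunk_vein trunk diameters, um.
#' @param cap_meanlog,cap_sdlog lognormal parameters of capillary diameter
#'   (um scale; defaults give a mode near 5 um as in neonatal plexuses).
#' @param spacing rung spacing along the trunks, um.
#' @param width trunk separation, um.
#' @param seed RNG seed (local).
#' @return a [skeleton_graph()] with the artery root as inlet and the vein
#'   root as outlet.
#' @export
generate_synthetic_plexus <- function(n_rungs = 6, trunk_artery = 16,
                                      trunk_vein = 20,
                                      cap_meanlog = log(5), cap_sdlog = 0.3,
                                      spacing = 30, width = 100, seed = 1L) {
  stopifnot(n_rungs >= 1, spacing > 0)
  if (width <= (trunk_artery + trunk_vein))
    stop("infeasible plexus: trunks overlap at the requested width")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  ys <- seq(0, by = spacing, length.out = n_rungs)
  a_nodes <- data.frame(x = 0, y = c(-spacing, ys), z = 0, radius = trunk_artery / 2)
  v_nodes <- data.frame(x = width, y = c(-spacing, ys), z = 0, radius = trunk_vein / 2)
  top <- data.frame(x = width / 2, y = max(ys) + 0.7 * spacing, z = 0,
                    radius = exp(cap_meanlog) / 2)
  nodes <- rbind(a_nodes, v_nodes, top)
  ai <- seq_len(n_rungs + 1)                 # artery: root then junctions
  vi <- n_rungs + 1 + seq_len(n_rungs + 1)   # vein: root then junctions
  ti <- nrow(nodes)

  cap_d <- stats::rlnorm(n_rungs + 2, cap_meanlog, cap_sdlog)
  edges <- rbind(
    data.frame(from = ai[-length(ai)], to = ai[-1], radius = trunk_artery / 2),
    data.frame(from = vi[-length(vi)], to = vi[-1], radius = trunk_vein / 2),
    data.frame(from = ai[-1], to = vi[-1], radius = cap_d[seq_len(n_rungs)] / 2),
    data.frame(from = c(ai[length(ai)], ti), to = c(ti, vi[length(vi)]),
               radius = cap_d[n_rungs + 1:2] / 2))

  skeleton_graph(nodes, edges, inlet = ai[1], outlet = vi[1])
}

#' Length-weighted vessel diameter histogram
#'
#' Aggregates the total centreline distance covered by vessel segments of a
#' given diameter, and fits a lognormal law to the length-weighted diameter
#' distribution. The distribution mode `exp(mu - sigma^2)` estimates the
#' typical capillary diameter (capillaries dominate the network length).
#'
#' @param skeleton a [skeleton_graph()].
#' @param bin_width histogram bin width, um.
#' @return object of class `diameter_histogram`: `bin_edges`,
#'   `length_per_bin` (um), `lognormal_mu`, `lognormal_sigma`, `mode` (um),
#'   `total_length`; the fit fields are `NA` (flagged) when fewer than two
#'   distinct diameters exist.
#' @export
diameter_histogram <- function(skeleton, bin_width = 1) {
  seg <- segment_table(skeleton)
  d <- 2 * seg$radius; w <- seg$length
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  lpb <- vapply(seq_len(length(edges) - 1),
                function(b) sum(w[bin == b]), numeric(1))
  if (length(unique(d)) >= 2) {
    mu <- sum(w * log(d)) / sum(w)
    sg <- sqrt(sum(w * (log(d) - mu)^2) / sum(w))
    mode <- exp(mu - sg^2)
  } else {
    mu <- sg <- mode <- NA_real_
  }
  structure(list(bin_edges = edges, length_per_bin = lpb,
                 lognormal_mu = mu, lognormal_sigma = sg, mode = mode,
                 total_length = sum(w)),
            class = "diameter_histogram")
}

#' @export
print.diameter_histogram <- function(x, ...) {
  cat(sprintf("diameter histogram: %.1f um total centreline length\n",
              x$total_length))
  if (is.na(x$mode)) cat("  lognormal fit refused (single diameter)\n")
  else cat(sprintf("  lognormal mu = %.4g, sigma = %.4g, mode = %.3g um\n",
                   x$lognormal_mu, x$lognormal_sigma, x$mode))
  invisible(x)
}

#' Choose the voxel size for a network discretization
#'
#' Returns the largest voxel size such that at least a `coverage` fraction
#' of the total centreline length lies in vessels at least
#' `min_diameter_sites` lattice sites across — the resolution rule that
#' keeps the flow solution trustworthy over (by default) 95% of the network
#' while sacrificing only the thinnest tail.
#'
#' @param skeleton a [skeleton_graph()].
#' @param coverage required length fraction (default 0.95).
#' @param min_diameter_sites minimum resolved diameter in lattice sites
#'   (default 3).
#' @return voxel size dx, um.
#' @export
choose_voxel_size <- function(skeleton, coverage = 0.95, min_diameter_sites = 3) {
  seg <- segment_table(skeleton)
  d <- 2 * seg$radius; w <- seg$length
  if (all(d < 1e-9)) stop("degenerate skeleton: all diameters are ~0")
  o <- order(-d)
  frac <- cumsum(w[o]) / sum(w)
  ok <- frac >= coverage
  d_star <- d[o][which(ok)[1]]   # largest diameter threshold meeting coverage
  d_star / min_diameter_sites
}

#' Read / write skeleton graphs
#'
#' CSV pair (`<stem>_nodes.csv` with node_id,x_um,y_um,z_um,radius_um,role;
#' `<stem>_edges.csv` with from,to,radius_um) or a single JSON file.
#'
#' @param stem path stem for the CSV pair.
#' @rdname skeleton_io
#' @export
write_skeleton_csv <- function(skeleton, stem) {
  n <- skeleton$nodes
  role <- rep("", nrow(n))
  role[skeleton$inlet] <- "inlet"; role[skeleton$outlet] <- "outlet"
  utils::write.csv(data.frame(node_id = seq_len(nrow(n)), x_um = n$x,
                              y_um = n$y, z_um = n$z, radius_um = n$radius,
                              role = role),
                   paste0(stem, "_nodes.csv"), row.names = FALSE)
  e <- skeleton$edges
  utils::write.csv(data.frame(from = e$from, to = e$to,
                              radius_um = if (is.null(e$radius)) NA else e$radius),
                   paste0(stem, "_edges.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname skeleton_io
#' @export
read_skeleton_csv <- function(stem) {
  n <- utils::read.csv(paste0(stem, "_nodes.csv"))
  e <- utils::read.csv(paste0(stem, "_edges.csv"))
  nodes <- data.frame(x = n$x_um, y = n$y_um,
                      z = if (is.null(n$z_um)) 0 else n$z_um,
                      radius = n$radius_um)
  edges <- data.frame(from = e$from, to = e$to)
  if (!is.null(e$radius_um) && !all(is.na(e$radius_um))) edges$radius <- e$radius_um
  skeleton_graph(nodes, edges,
                 inlet = which(n$role == "inlet"),
                 outlet = which(n$role == "outlet"))
}

#' @param path JSON file path.
#' @rdname skeleton_io
#' @export
write_skeleton_json <- function(skeleton, path) {
  jsonlite::write_json(list(nodes = skeleton$nodes, edges = skeleton$edges,
                            inlet = skeleton$inlet, outlet = skeleton$outlet),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname skeleton_io
#' @export
read_skeleton_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  skeleton_graph(as.data.frame(j$nodes), as.data.frame(j$edges),
                 inlet = j$inlet, outlet = j$outlet)
}

#' Read a binary mask from file
#'
#' Accepts PNG/TIFF images (any channel > 0.5 is foreground) or a plain-text
#' 0/1 grid (whitespace-separated rows).
#'
#' @param path file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    return(a > 0.5)
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    return(a > 0.5)
  }
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  m > 0.5
}
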