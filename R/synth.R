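#' Straight-vessel chain network
#'
#' A single vessel of uniform diameter discretized into `n_segments`
#' collinear segments — the minimal fully determined validation topology.
#'
#' @param diameter Segment diameter, um.
#' @param length Length of each segment, um.
#' @param n_segments Number of chained segments.
#' @param p_inlet,p_outlet Optional pressure boundary conditions (mmHg) at
#'   the two ends.
#' @return A [vascular_network()] with 2 boundary nodes.
#' @export
make_line <- function(diameter = 10, length = 100, n_segments = 1L,
                      p_inlet = NULL, p_outlet = NULL) {
  stopifnot(diameter > 0, length > 0, n_segments >= 1)
  n_segments <- as.integer(n_segments)
  nodes <- tibble(id = seq_len(n_segments + 1L),
                  x = (seq_len(n_segments + 1L) - 1L) * length, y = 0, z = 0)
  segs <- tibble(id = seq_len(n_segments),
                 node_i = seq_len(n_segments),
                 node_j = seq_len(n_segments) + 1L,
                 diameter = diameter, length = length)
  boundary <- NULL
  if (!is.null(p_inlet) || !is.null(p_outlet)) {
    boundary <- bind_rows(
      if (!is.null(p_inlet)) tibble(node_id = 1L, kind = "pressure",
                                    pressure = p_inlet, flow = NA_real_,
                                    hd = NA_real_),
      if (!is.null(p_outlet)) tibble(node_id = n_segments + 1L,
                                     kind = "pressure", pressure = p_outlet,
                                     flow = NA_real_, hd = NA_real_)
    )
  }
  vascular_network(nodes, segs, boundary)
}

#' Symmetric bifurcation-tree network
#'
#' A perfect binary tree: one root (inlet) segment followed by `depth`
#' generations of paired daughters whose diameters shrink by a fixed ratio
#' per generation. Root and the `2^depth` leaves are boundary nodes.
#'
#' @param depth Number of bifurcation generations (>= 1).
#' @param root_diameter Root segment diameter, um.
#' @param diameter_ratio Daughter/parent diameter ratio per generation.
#' @param segment_length Length of every segment, um.
#' @param p_root,p_leaf Optional pressure boundary conditions (mmHg) at the
#'   root and at every leaf.
#' @return A [vascular_network()] with `2^depth + 1` boundary nodes.
#' @export
make_bifurcation_tree <- function(depth = 3L, root_diameter = 20,
                                  diameter_ratio = 0.75,
                                  segment_length = 100,
                                  p_root = NULL, p_leaf = NULL) {
  stopifnot(depth >= 1, root_diameter > 0, diameter_ratio > 0,
            segment_length > 0)
  depth <- as.integer(depth)
  nodes <- tibble(id = 1L, x = 0, y = 0, z = 0)       # root boundary node
  segs <- tibble(id = integer(), node_i = integer(), node_j = integer(),
                 diameter = numeric(), length = numeric())
  next_node <- 2L
  next_seg <- 1L
  # root segment into the first junction
  nodes <- bind_rows(nodes, tibble(id = next_node, x = segment_length,
                                   y = 0, z = 0))
  segs <- bind_rows(segs, tibble(id = next_seg, node_i = 1L,
                                 node_j = next_node,
                                 diameter = root_diameter,
                                 length = segment_length))
  frontier <- next_node
  next_node <- next_node + 1L
  next_seg <- next_seg + 1L
  d <- root_diameter
  for (lev in seq_len(depth)) {
    d <- d * diameter_ratio
    spread <- segment_length * 2^(depth - lev)
    new_frontier <- integer(0)
    for (p in frontier) {
      px <- nodes$x[match(p, nodes$id)]
      py <- nodes$y[match(p, nodes$id)]
      for (sgn in c(-1, 1)) {
        nodes <- bind_rows(nodes, tibble(id = next_node,
                                         x = px + segment_length,
                                         y = py + sgn * spread / 2, z = 0))
        chord <- sqrt(segment_length^2 + (spread / 2)^2)
        segs <- bind_rows(segs, tibble(id = next_seg, node_i = p,
                                       node_j = next_node, diameter = d,
                                       length = chord))
        new_frontier <- c(new_frontier, next_node)
        next_node <- next_node + 1L
        next_seg <- next_seg + 1L
      }
    }
    frontier <- new_frontier
  }
  boundary <- NULL
  if (!is.null(p_root) || !is.null(p_leaf)) {
    boundary <- bind_rows(
      if (!is.null(p_root)) tibble(node_id = 1L, kind = "pressure",
                                   pressure = p_root, flow = NA_real_,
                                   hd = NA_real_),
      if (!is.null(p_leaf)) tibble(node_id = frontier, kind = "pressure",
                                   pressure = p_leaf, flow = NA_real_,
                                   hd = NA_real_)
    )
  }
  vascular_network(nodes, segs, boundary)
}

#' Seeded tumor-like synthetic network
#'
#' Generates a reproducible vascular network inside a sphere with the
#' hallmark statistical structure of tumor microvasculature: node density
#' boosted in an outer rim shell relative to the core (dense vascularized
#' rim, sparse core), a positively skewed log-normal diameter distribution
#' smoothed along vessels, loopy topology (a minimum spanning tree plus a
#' fraction of extra short edges), and pendant boundary vessels on the
#' surface. Boundary pressures, when requested, interpolate in
#' log-diameter between the arterial and venous anchors so large feeders
#' sit near the arterial pressure.
#'
#' This generator emulates the geometry and first-order statistics a
#' whole-tumor imaging pipeline would deliver; it makes no claim to
#' simulate angiogenesis.
#'
#' @param n_segments Target total segment count.
#' @param radius Tumor sphere radius, um.
#' @param rim_fraction Thickness of the rim shell as a fraction of the
#'   radius (default 0.25).
#' @param rim_core_ratio Rim:core node-density ratio (default 3).
#' @param diameter_median Median vessel diameter, um.
#' @param diameter_sigma Log-normal sigma of diameters.
#' @param n_boundary Number of pendant boundary vessels.
#' @param loop_fraction Fraction of segments added as extra loop edges.
#' @param tortuosity Centerline length as a multiple of the chord
#'   (default 1.1).
#' @param boundary `"pressure"` to emit pressure boundary conditions,
#'   `"none"` to leave boundary data absent (the optimizer then assigns
#'   pressures).
#' @param arterial_pressure,venous_pressure Anchors (mmHg) for emitted
#'   boundary pressures.
#' @param seed Integer seed; identical seeds and parameters give identical
#'   networks.
#' @return A [vascular_network()] with `volume` set to the sphere volume
#'   (mm^3).
#' @export
make_tumor_like <- function(n_segments = 500L, radius = 400,
                            rim_fraction = 0.25, rim_core_ratio = 3,
                            diameter_median = 10, diameter_sigma = 0.5,
                            n_boundary = 8L, loop_fraction = 0.1,
                            tortuosity = 1.1,
                            boundary = c("pressure", "none"),
                            arterial_pressure = 30, venous_pressure = 10,
                            seed = 1L) {
  stopifnot(n_segments >= 10, radius > 0, rim_fraction > 0, rim_fraction < 1,
            rim_core_ratio > 0, diameter_median > 0, diameter_sigma >= 0,
            n_boundary >= 2, loop_fraction >= 0, tortuosity >= 1)
  boundary <- match.arg(boundary)
  n_boundary <- as.integer(n_boundary)
  # interior node budget: the spanning tree uses n - 1 edges, closing its
  # leaves (~35% of nodes) and the requested loop fraction use the rest
  n_interior <- as.integer(floor((n_segments - n_boundary + 1) /
                                   (1.35 + loop_fraction)))
  if (n_interior < 5L) {
    abort("unreachable target counts: too few interior nodes; raise n_segments")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  # rejection-sample radii: uniform density in the rim shell, reduced by
  # 1/rim_core_ratio in the core
  r_cut <- (1 - rim_fraction) * radius
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n_interior) {
    m <- 3L * (n_interior - nrow(pts)) + 20L
    cand <- matrix(runif(3L * m, -radius, radius), ncol = 3)
    rr <- sqrt(rowSums(cand^2))
    keep <- rr <= radius &
      (rr >= r_cut | runif(m) < 1 / rim_core_ratio)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n_interior), , drop = FALSE]

  # minimum spanning tree on the complete Euclidean graph
  dmat <- as.matrix(dist(pts))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mst, names = FALSE)

  rr <- sqrt(rowSums(pts^2))
  anchors <- order(-rr)[seq_len(n_boundary)]

  edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  have <- edge_key(el)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n_interior)

  # close interior blind ends: every tree leaf (anchors excepted — they
  # receive a pendant boundary vessel) gets an edge to its nearest
  # non-neighbor, giving the loopy topology of tumor vasculature
  leaves <- setdiff(which(deg == 1L), anchors)
  for (lf in sort(leaves)) {
    if (deg[lf] > 1L) next           # fixed by an earlier leaf's edge
    nb <- unique(c(el[el[, 1] == lf, 2], el[el[, 2] == lf, 1]))
    cand <- setdiff(order(dmat[lf, ]), c(lf, nb))
    tgt <- cand[1]
    el <- rbind(el, c(lf, tgt))
    have <- c(have, edge_key(rbind(c(lf, tgt))))
    deg[lf] <- deg[lf] + 1L
    deg[tgt] <- deg[tgt] + 1L
  }

  # top up with short random loop edges to hit the segment target exactly
  n_extra <- n_segments - nrow(el) - n_boundary
  if (n_extra < 0) {
    abort("unreachable target counts: raise n_segments or loop fraction")
  }
  if (n_extra > 0) {
    cand <- which(upper.tri(dmat), arr.ind = TRUE)
    cand <- cand[!(edge_key(cand) %in% have), , drop = FALSE]
    w <- dmat[cand]
    topk <- order(w)[seq_len(min(5L * n_extra, nrow(cand)))]
    pick <- sample(topk, n_extra)
    el <- rbind(el, cand[pick, , drop = FALSE])
  }
  bpts <- pts[anchors, , drop = FALSE] *
    ((rr[anchors] + 0.1 * radius) / rr[anchors])
  all_pts <- rbind(pts, bpts)
  bidx <- n_interior + seq_len(n_boundary)
  el <- rbind(el, cbind(anchors, bidx))

  # node-level log-normal sizes; segment diameter = endpoint mean
  node_d <- rlnorm(nrow(all_pts), meanlog = log(diameter_median),
                   sdlog = diameter_sigma)
  # boundary feeders get upper-tail sizes so anchors spread in log-diameter
  node_d[bidx] <- quantile(node_d[seq_len(n_interior)],
                           probs = seq(0.2, 0.98,
                                       length.out = n_boundary))
  seg_d <- (node_d[el[, 1]] + node_d[el[, 2]]) / 2
  chord <- sqrt(rowSums((all_pts[el[, 1], , drop = FALSE] -
                           all_pts[el[, 2], , drop = FALSE])^2))

  nodes <- tibble(id = seq_len(nrow(all_pts)), x = all_pts[, 1],
                  y = all_pts[, 2], z = all_pts[, 3])
  segs <- tibble(id = seq_len(nrow(el)),
                 node_i = as.integer(el[, 1]), node_j = as.integer(el[, 2]),
                 diameter = seg_d, length = chord * tortuosity)

  bc <- NULL
  if (boundary == "pressure") {
    ld <- log(seg_d[tail(seq_len(nrow(el)), n_boundary)])
    tt <- if (diff(range(ld)) > 0) (ld - min(ld)) / diff(range(ld))
          else seq(0, 1, length.out = n_boundary)
    bc <- tibble(node_id = as.integer(bidx), kind = "pressure",
                 pressure = venous_pressure +
                   tt * (arterial_pressure - venous_pressure),
                 flow = NA_real_, hd = NA_real_)
  }
  vol_mm3 <- 4 / 3 * pi * (radius * 1e-3)^3
  vascular_network(nodes, segs, bc, volume = vol_mm3)
}

#' Load the published rat mesentery validation network
#'
#' Reads a user-supplied copy of the classic 546-segment rat mesentery
#' microvascular dataset, converted to this package's two-file text layout
#' (the dataset itself is not redistributed): a network directory in the
#' [read_network()] CSV schema whose `boundary.csv` carries measured
#' boundary data — inflows with discharge hematocrit
#' (`kind = "flow_hematocrit"`), measured outflows (`kind = "flow"`), and
#' the main venular outlet held at constant pressure (`kind = "pressure"`).
#' The loader verifies the documented composition (546 segments, 31
#' inlets, 5 outlets, 1 pressure node) and errors listing every
#' discrepancy.
#'
#' @param path Directory with `nodes.csv`, `segments.csv`, `boundary.csv`.
#' @param expected Named integer vector with the expected counts
#'   (`segments`, `inlets`, `outlets`, `pressure_nodes`).
#' @return A [vascular_network()] with the measured boundary conditions
#'   attached.
#' @export
load_mesentery <- function(path,
                           expected = c(segments = 546L, inlets = 31L,
                                        outlets = 5L, pressure_nodes = 1L)) {
  net <- read_network(path, format = "csv")
  b <- net$boundary
  inlets <- sum(b$kind == "flow_hematocrit" & b$flow > 0)
  outlets <- sum(b$kind == "flow" & b$flow < 0)
  pnodes <- sum(b$kind == "pressure")
  got <- c(segments = nrow(net$segments), inlets = inlets,
           outlets = outlets, pressure_nodes = pnodes)
  bad <- names(expected)[got[names(expected)] != expected]
  if (length(bad)) {
    msg <- paste(vapply(bad, function(k) {
      paste0(k, ": expected ", expected[[k]], ", found ", got[[k]])
    }, character(1)), collapse = "; ")
    abort(paste0("dataset composition mismatch — ", msg))
  }
  miss_hd <- b$kind == "flow_hematocrit" & b$flow > 0 & !is.finite(b$hd)
  if (any(miss_hd)) {
    abort(paste0("missing hematocrit at inlet node(s): ",
                 paste(b$node_id[miss_hd], collapse = ", ")))
  }
  net
}
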