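# Fixture builders and independent oracles shared across test files.

# Random connected network with pendant boundary vessels carrying pressures.
# Built from scratch (not via the package generators) so solver tests do not
# depend on make_tumor_like().
random_test_network <- function(n_interior = 15, n_boundary = 3, seed = 1,
                                p_hi = 30, p_lo = 10) {
  set.seed(seed)
  pts <- matrix(runif(3 * n_interior, 0, 500), ncol = 3)
  # randomized spanning tree: connect node k to a random earlier node
  edges <- cbind(2:n_interior, vapply(2:n_interior,
                                      function(k) sample(k - 1, 1), 1L))
  extra <- max(1, round(n_interior / 5))
  for (i in seq_len(extra)) {
    pair <- sample(n_interior, 2)
    edges <- rbind(edges, pair)
  }
  anchors <- sample(n_interior, n_boundary)
  bid <- n_interior + seq_len(n_boundary)
  pts <- rbind(pts, pts[anchors, ] + matrix(runif(3 * n_boundary, 30, 60),
                                            ncol = 3))
  edges <- rbind(edges, cbind(anchors, bid))
  nodes <- data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
                      z = pts[, 3])
  chord <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                           pts[edges[, 2], , drop = FALSE])^2))
  segs <- data.frame(id = seq_len(nrow(edges)), node_i = edges[, 1],
                     node_j = edges[, 2],
                     diameter = runif(nrow(edges), 6, 30),
                     length = chord)
  bc <- data.frame(node_id = bid, kind = "pressure",
                   pressure = seq(p_hi, p_lo, length.out = n_boundary),
                   flow = NA_real_, hd = NA_real_)
  vascular_network(nodes, segs, bc)
}

# Dense direct pressure solve, assembled independently of the package's
# sparse path (plain base-R matrix algebra).
dense_solve_oracle <- function(net, viscosity) {
  nodes <- net$nodes
  segs <- net$segments
  n <- nrow(nodes)
  viscosity <- rep_len(viscosity, nrow(segs))
  g <- 1.33322e-4 * pi * segs$diameter^4 / (128 * viscosity * segs$length)
  A <- matrix(0, n, n)
  for (s in seq_len(nrow(segs))) {
    i <- match(segs$node_i[s], nodes$id)
    j <- match(segs$node_j[s], nodes$id)
    A[i, i] <- A[i, i] + g[s]
    A[j, j] <- A[j, j] + g[s]
    A[i, j] <- A[i, j] - g[s]
    A[j, i] <- A[j, i] - g[s]
  }
  b <- rep(0, n)
  fixed <- rep(NA_real_, n)
  for (r in seq_len(nrow(net$boundary))) {
    k <- match(net$boundary$node_id[r], nodes$id)
    if (net$boundary$kind[r] == "pressure") {
      fixed[k] <- net$boundary$pressure[r]
    } else {
      b[k] <- b[k] + net$boundary$flow[r]
    }
  }
  free <- which(is.na(fixed))
  P <- fixed
  rhs <- b[free] - A[free, !is.na(fixed), drop = FALSE] %*%
    fixed[!is.na(fixed)]
  P[free] <- solve(A[free, free, drop = FALSE], rhs)
  Q <- g * (P[match(segs$node_i, nodes$id)] - P[match(segs$node_j, nodes$id)])
  list(pressures = P, flows = Q)
}

# Exhaustive nearest-vessel-voxel search (the distance-map oracle).
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  vox <- which(mask, arr.ind = TRUE)
  all_idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]),
                                   seq_len(d[3])))
  out <- array(NA_real_, d)
  for (r in seq_len(nrow(all_idx))) {
    dd <- sweep(vox, 2, all_idx[r, ])
    dd <- sweep(dd, 2, spacing, `*`)
    out[all_idx[r, 1], all_idx[r, 2], all_idx[r, 3]] <-
      sqrt(min(rowSums(dd^2)))
  }
  out
}

# Scalar oxygen oracle for one eligible vessel: root-find the outlet
# tension from the per-segment balance Q(alpha dP + HD C_bind dS) = J.
single_vessel_oxygen_oracle <- function(q, alpha_b, hd, c_bind, p_in, j_wall,
                                        n_hill = 2.7, p50 = 37) {
  hill <- function(p) p^n_hill / (p^n_hill + p50^n_hill)
  f <- function(p_out) {
    q * (alpha_b * (p_in - p_out) + hd * c_bind * (hill(p_in) - hill(p_out))) -
      j_wall
  }
  stats::uniroot(f, c(0, p_in), tol = 1e-12)$root
}

# Marching oracle for a diverging tree: every junction has one inflow, so
# its tension solves a scalar equation given the upstream tension.
tree_oxygen_oracle <- function(net, state, oxy_params, wf) {
  segs <- state$segments
  nodes <- net$nodes
  qa <- abs(segs$flow) * 1e-3            # ul/s -> ml/s
  from <- ifelse(segs$flow >= 0, segs$node_i, segs$node_j)
  to <- ifelse(segs$flow >= 0, segs$node_j, segs$node_i)
  alpha_b <- vasculr::blood_solubility(pmin(pmax(segs$ht, 0), 1), oxy_params)
  hill <- function(p) {
    p^oxy_params$n_hill / (p^oxy_params$n_hill + oxy_params$p50^oxy_params$n_hill)
  }
  P <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  roots <- setdiff(from, to)
  P[as.character(roots)] <- oxy_params$inlet_po2
  todo <- order(-state$pressures$pressure[match(nodes$id,
                                                state$pressures$id)])
  for (v in nodes$id[todo]) {
    if (!is.na(P[as.character(v)])) next
    ein <- which(to == v)
    if (!length(ein)) next
    eout <- which(from == v)
    carriers <- if (length(eout)) eout else ein
    bal <- function(pv) {
      sum(vapply(ein, function(e) {
        pu <- P[as.character(from[e])]
        qa[e] * (alpha_b[e] * pu +
                   segs$hd[e] * oxy_params$c_bind * hill(pu)) -
          wf$j_wall[e]
      }, 1)) -
        sum(vapply(carriers, function(e) {
          qa[e] * (alpha_b[e] * pv +
                     segs$hd[e] * oxy_params$c_bind * hill(pv))
        }, 1))
    }
    P[as.character(v)] <- stats::uniroot(bal, c(0, oxy_params$inlet_po2),
                                         tol = 1e-12)$root
  }
  P
}

# Brute-force Mann-Whitney U: count of (a, b) pairs with a < b (+ ties/2).
brute_force_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Hand-executable UPGMA on a distance matrix; returns merge heights.
manual_upgma_heights <- function(dm) {
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  active <- seq_len(nrow(dm))
  dmat <- dm
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(dm[clusters[[a]], clusters[[b]]])
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Verifies the converged oxygen tensions satisfy every nodal balance with
# the exact Hill saturation (no lag), relative to the advected inflow.
expect_oxygen_balance_exact <- function(net, state, ox, tol = 1e-8) {
  segs <- state$segments
  nodes <- net$nodes
  p <- ox$params
  qa <- abs(segs$flow)
  live <- qa > max(qa) * 1e-14
  from <- ifelse(segs$flow >= 0, segs$node_i, segs$node_j)
  to <- ifelse(segs$flow >= 0, segs$node_j, segs$node_i)
  P <- setNames(ox$nodes$po2, ox$nodes$id)
  hill <- function(x) x^p$n_hill / (x^p$n_hill + p$p50^p$n_hill)
  ab <- vasculr::blood_solubility(pmin(pmax(segs$ht, 0), 1), p)
  content <- function(e, nid) {
    pv <- P[as.character(nid)]
    qa[e] * 1e-3 * (ab[e] * pv + segs$hd[e] * p$c_bind * hill(pv))
  }
  scale_ref <- ox$balance$advected_in
  for (v in nodes$id[!ox$nodes$known]) {
    ein <- which(live & to == v)
    eout <- which(live & from == v)
    if (!length(ein) && !length(eout)) next
    if (is.na(P[as.character(v)])) next
    carriers <- if (length(eout)) eout else ein
    if (anyNA(P[as.character(from[ein])])) next  # fed by an unsolved pocket
    res <- sum(vapply(ein, function(e) content(e, from[e]), 1)) -
      sum(ox$segments$j_wall[ein]) -
      sum(vapply(carriers, function(e) content(e, v), 1))
    testthat::expect_lt(abs(res) / scale_ref, tol)
  }
}

# Minimal state/oxygen pairs with prescribed velocity (um/s), PO2, diameter
# and length so the classification rules can be probed directly.
fake_states <- function(vel_um_s, po2, diameter = 10, length = 100,
                        flow = NULL) {
  n <- length(vel_um_s)
  diameter <- rep_len(diameter, n)
  length <- rep_len(length, n)
  if (is.null(flow)) flow <- rep(1e-3, n)
  segs <- tibble::tibble(
    id = seq_len(n), node_i = seq_len(n), node_j = seq_len(n) + 1L,
    diameter = diameter, length = length, flow = flow,
    velocity = vel_um_s / 1e3, hd = 0.4, ht = 0.3, viscosity = 2,
    wall_shear = 1, transit_time = 1, zero_flow = FALSE,
    perfused = abs(flow) >= 1e-10
  )
  state <- structure(list(segments = segs), class = "hemodynamic_state")
  oxy <- structure(list(segments = tibble::tibble(id = seq_len(n),
                                                  po2 = po2)),
                   class = "oxygen_state")
  list(state = state, oxy = oxy)
}
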