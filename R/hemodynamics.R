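#' Flow solver configuration
#'
#' Settings of the steady-state hemodynamics fixed point: the arterial and
#' venous pressure anchors used when boundary pressures must be assigned, the
#' discharge hematocrit fed at network inlets, and the convergence controls
#' of the outer viscosity/pressure/hematocrit loop.
#'
#' @param arterial_pressure,venous_pressure Pressure anchors in mmHg bounding
#'   assigned boundary pressures.
#' @param inlet_hematocrit Discharge hematocrit at inflow nodes without a
#'   measured value, fraction in `[0, 1]`.
#' @param tol_pressure,tol_hematocrit Relative/absolute convergence
#'   tolerances of the outer loop.
#' @param tol_imbalance Tolerance on the global inflow/outflow imbalance of
#'   [optimize_boundary_pressures()].
#' @param max_iterations Outer-loop iteration cap.
#' @param relaxation Under-relaxation factor applied to hematocrit updates.
#' @param seed Reserved; solver tie-breaking is deterministic (segment-id
#'   order), so this only matters for stochastic inputs generated elsewhere.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(arterial_pressure = 30, venous_pressure = 10,
                        inlet_hematocrit = 0.45,
                        tol_pressure = 1e-4, tol_hematocrit = 1e-4,
                        tol_imbalance = 1e-3,
                        max_iterations = 200L, relaxation = 0.5,
                        seed = NULL) {
  stopifnot(arterial_pressure > venous_pressure,
            inlet_hematocrit >= 0, inlet_hematocrit <= 1,
            tol_pressure > 0, tol_hematocrit > 0, tol_imbalance > 0,
            max_iterations >= 1, relaxation > 0, relaxation <= 1)
  structure(list(arterial_pressure = arterial_pressure,
                 venous_pressure = venous_pressure,
                 inlet_hematocrit = inlet_hematocrit,
                 tol_pressure = tol_pressure,
                 tol_hematocrit = tol_hematocrit,
                 tol_imbalance = tol_imbalance,
                 max_iterations = as.integer(max_iterations),
                 relaxation = relaxation,
                 seed = seed),
            class = "flow_config")
}

segment_conductance <- function(segments, viscosity) {
  POISEUILLE_UNIT * pi * segments$diameter^4 /
    (128 * viscosity * segments$length)
}

#' Solve nodal pressures and segment flows
#'
#' Assembles the generalized 1D Poiseuille law
#' `Q_ij = pi D^4 (P_i - P_j) / (128 mu L)` with mass conservation at every
#' junction into a sparse linear system and solves for the nodal pressure
#' distribution. Pressure boundary conditions are Dirichlet rows; flow
#' boundary conditions enter the right-hand side (inflow positive).
#'
#' @param net A [vascular_network()].
#' @param viscosity Per-segment apparent viscosity, cP (scalar or vector).
#' @param boundary_pressures Optional tibble `node_id`, `pressure` (mmHg)
#'   overriding/augmenting pressure conditions in `net$boundary`.
#' @return A list with `pressures` (tibble `id`, `pressure`), `flows`
#'   (tibble `id`, `flow` in ul/s, signed by the `node_i -> node_j`
#'   orientation) and `mass_residual`, the largest interior-node flow
#'   imbalance relative to the largest boundary flow.
#' @examples
#' net <- make_line(p_inlet = 30, p_outlet = 10)
#' solve_pressures(net, viscosity = 1)$flows
#' @export
solve_pressures <- function(net, viscosity, boundary_pressures = NULL) {
  stopifnot(inherits(net, "vascular_network"))
  segs <- net$segments
  nodes <- net$nodes
  n <- nrow(nodes)
  viscosity <- rep_len(as.numeric(viscosity), nrow(segs))
  if (any(!is.finite(viscosity) | viscosity <= 0)) {
    abort("`viscosity` must be positive")
  }

  fixed_p <- rep(NA_real_, n)
  inj_q <- rep(0, n)
  b <- net$boundary
  if (nrow(b)) {
    isp <- b$kind == "pressure"
    fixed_p[match(b$node_id[isp], nodes$id)] <- b$pressure[isp]
    inj_q[match(b$node_id[!isp], nodes$id)] <-
      inj_q[match(b$node_id[!isp], nodes$id)] + b$flow[!isp]
  }
  if (!is.null(boundary_pressures)) {
    bp <- as_tibble(as.data.frame(boundary_pressures))
    fixed_p[match(bp$node_id, nodes$id)] <- bp$pressure
  }
  if (!any(is.finite(fixed_p))) {
    abort("at least one pressure boundary condition is required")
  }

  g <- segment_conductance(segs, viscosity)
  i <- match(segs$node_i, nodes$id)
  j <- match(segs$node_j, nodes$id)

  # every connected component needs a pressure anchor
  gg <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(gg)$membership
  anchored <- unique(comp[is.finite(fixed_p)])
  if (!all(unique(comp) %in% anchored)) {
    bad <- setdiff(unique(comp), anchored)
    abort(paste0("singular system: component(s) without a pressure anchor, ",
                 "containing node ids: ",
                 paste(nodes$id[match(bad, comp)], collapse = ", ")))
  }

  A <- Matrix::sparseMatrix(
    i = c(i, j, i, j), j = c(i, j, j, i),
    x = c(g, g, -g, -g), dims = c(n, n)
  )
  free <- which(!is.finite(fixed_p))
  P <- fixed_p
  if (length(free)) {
    rhs <- inj_q[free]
    dirc <- which(is.finite(fixed_p))
    if (length(dirc)) {
      rhs <- rhs - as.numeric(A[free, dirc, drop = FALSE] %*% fixed_p[dirc])
    }
    P[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs))
  }

  Q <- g * (P[i] - P[j])

  imb <- as.numeric(A %*% P) - inj_q   # net outflow demanded at each node
  interior <- !nodes$is_boundary
  bflow <- abs(imb[nodes$is_boundary])
  scale_q <- max(c(bflow, abs(inj_q), 1e-300))
  mass_residual <- if (any(interior)) max(abs(imb[interior])) / scale_q else 0

  list(
    pressures = tibble(id = nodes$id, pressure = P),
    flows = tibble(id = segs$id, flow = Q),
    mass_residual = mass_residual
  )
}

#' Route discharge hematocrit through the flow field
#'
#' Propagates red cells downstream through the directed flow graph: nodes are
#' processed in descending-pressure order (a topological order of the flow
#' digraph, since flow follows the pressure gradient), converging junctions
#' mix red-cell flux conservatively, and diverging junctions split it with
#' the empirical [phase_separation()] law — applied recursively over
#' flow-ranked daughter pairs when more than two daughters diverge. Red-cell
#' flux is conserved exactly at every junction; zero-flow segments carry no
#' advected red cells and are assigned hematocrit 0 with a flag.
#'
#' @param net A [vascular_network()].
#' @param flows Tibble `id`, `flow` from [solve_pressures()].
#' @param pressures Tibble `id`, `pressure` from [solve_pressures()].
#' @param inlet_hematocrit Discharge hematocrit at inflow boundary nodes
#'   lacking a measured value.
#' @param params A [rheology_params()].
#' @param q_floor Flows below this magnitude (ul/s) count as zero for
#'   red-cell advection (the perfused floor).
#' @return Tibble `id`, `hd` (discharge hematocrit), `zero_flow` flag,
#'   ordered as `net$segments`.
#' @export
distribute_hematocrit <- function(net, flows, pressures,
                                  inlet_hematocrit = 0.45,
                                  params = rheology_params(),
                                  q_floor = 1e-10) {
  stopifnot(inherits(net, "vascular_network"))
  segs <- net$segments
  nodes <- net$nodes
  Q <- flows$flow[match(segs$id, flows$id)]
  P <- pressures$pressure[match(nodes$id, pressures$id)]

  qtol <- max(max(abs(Q), 0) * 1e-14, q_floor)
  live <- abs(Q) > qtol
  from <- ifelse(Q >= 0, segs$node_i, segs$node_j)
  to <- ifelse(Q >= 0, segs$node_j, segs$node_i)
  qa <- abs(Q)

  fidx <- match(from, nodes$id)
  tidx <- match(to, nodes$id)

  # measured inlet hematocrits
  hd_inlet <- rep(inlet_hematocrit, nrow(nodes))
  if (nrow(net$boundary)) {
    bb <- net$boundary
    m <- is.finite(bb$hd)
    hd_inlet[match(bb$node_id[m], nodes$id)] <- bb$hd[m]
  }

  ord <- order(-P, nodes$id)
  out_by_node <- split(which(live), fidx[live])
  in_deg_live <- tabulate(tidx[live], nbins = nrow(nodes))

  rbc_in <- numeric(nrow(nodes))
  q_in <- numeric(nrow(nodes))
  hd <- numeric(nrow(segs))

  for (v in ord) {
    eo <- out_by_node[[as.character(v)]]
    if (is.null(eo) || !length(eo)) next
    is_source <- in_deg_live[v] == 0L
    if (is_source) {
      q_out <- sum(qa[eo])
      rbc_avail <- q_out * hd_inlet[v]
      d_feed <- sum(qa[eo] * segs$diameter[eo]) / q_out
    } else {
      rbc_avail <- rbc_in[v]
      d_feed <- {
        ei <- which(live & tidx == v)
        sum(qa[ei] * segs$diameter[ei]) / sum(qa[ei])
      }
    }
    if (length(eo) == 1L) {
      hd[eo] <- min(rbc_avail / qa[eo], 1)
    } else {
      eo <- eo[order(-qa[eo], segs$id[eo])]
      rem <- rbc_avail
      for (k in seq_len(length(eo) - 1L)) {
        rest <- eo[(k + 1L):length(eo)]
        q_rem <- qa[eo[k]] + sum(qa[rest])
        fqb <- qa[eo[k]] / q_rem
        d_sib <- sum(qa[rest] * segs$diameter[rest]) / sum(qa[rest])
        hd_feed <- min(rem / q_rem, 1)
        fqe <- phase_separation(fqb, d_feed, segs$diameter[eo[k]], d_sib,
                                hd_feed, params)
        take <- fqe * rem
        lo <- max(0, rem - sum(qa[rest]))   # siblings cannot exceed HD = 1
        hi <- min(qa[eo[k]], rem)
        take <- min(max(take, lo), hi)
        hd[eo[k]] <- take / qa[eo[k]]
        rem <- rem - take
      }
      last <- eo[length(eo)]
      hd[last] <- min(rem / qa[last], 1)
      rem <- rem - min(rem, qa[last])
    }
    for (e in eo) {
      rbc_in[tidx[e]] <- rbc_in[tidx[e]] + hd[e] * qa[e]
      q_in[tidx[e]] <- q_in[tidx[e]] + qa[e]
    }
  }

  hd[!live] <- 0
  tibble(id = segs$id, hd = hd, zero_flow = !live)
}

#' Assign boundary pressures that keep the network mass-balanced
#'
#' When a network carries no measured boundary data, boundary nodes are
#' classified into feeders and drainers by the diameter of their attached
#' segment: initial pressures interpolate linearly in log-diameter between
#' the arterial anchor (largest feeder) and the venous anchor, and damped
#' global corrections are applied until the relative inflow/outflow
#' imbalance falls below `config$tol_imbalance`. Networks whose boundary
#' nodes all carry conditions are returned unchanged (optimization is
#' bypassed).
#'
#' @param net A [vascular_network()].
#' @param config A [flow_config()].
#' @param params A [rheology_params()].
#' @return Tibble `node_id`, `pressure` covering every boundary node that
#'   needs a pressure, with attributes `imbalance`, `iterations` and
#'   `skipped`.
#' @export
optimize_boundary_pressures <- function(net, config = flow_config(),
                                        params = rheology_params()) {
  stopifnot(inherits(net, "vascular_network"))
  nodes <- net$nodes
  bnodes <- nodes$id[nodes$is_boundary]
  if (length(bnodes) < 2) abort("need at least 2 boundary nodes")
  have <- net$boundary$node_id
  todo <- setdiff(bnodes, have)
  existing <- filter(net$boundary, .data$kind == "pressure")
  existing <- tibble(node_id = existing$node_id, pressure = existing$pressure)
  if (!length(todo)) {
    out <- existing
    attr(out, "skipped") <- TRUE
    attr(out, "imbalance") <- NA_real_
    attr(out, "iterations") <- 0L
    return(out)
  }

  segs <- net$segments
  att_d <- vapply(todo, function(nid) {
    hit <- which(segs$node_i == nid | segs$node_j == nid)[1]
    segs$diameter[hit]
  }, numeric(1))
  ld <- log(att_d)
  tt <- if (diff(range(ld)) > 0) {
    (ld - min(ld)) / (max(ld) - min(ld))
  } else {
    # equal diameters: spread by id rank so both anchors are represented
    (rank(todo, ties.method = "first") - 1) / (length(todo) - 1)
  }
  pr <- config$venous_pressure +
    tt * (config$arterial_pressure - config$venous_pressure)
  assigned <- tibble(node_id = todo, pressure = pr)

  mu <- apparent_viscosity(segs$diameter,
                           pmin(config$inlet_hematocrit, 0.99), params)
  imbalance <- Inf
  it <- 0L
  damp <- 0.5
  repeat {
    it <- it + 1L
    bp <- bind_rows(existing, assigned)
    sol <- solve_pressures(net, mu, boundary_pressures = bp)
    bq <- boundary_flows(net, sol)
    inflow <- sum(bq$flow[bq$flow > 0])
    outflow <- -sum(bq$flow[bq$flow < 0])
    imbalance <- abs(inflow - outflow) / max(inflow, 1e-300)
    if (imbalance < config$tol_imbalance || it >= 50L) break
    shift <- damp * (inflow - outflow) / max(inflow, 1e-300) *
      (config$arterial_pressure - config$venous_pressure)
    assigned$pressure <- pmin(pmax(assigned$pressure - shift,
                                   config$venous_pressure),
                              config$arterial_pressure)
  }
  if (imbalance >= config$tol_imbalance) {
    abort(paste0("boundary pressure optimization did not converge; ",
                 "last relative imbalance ", format(imbalance)))
  }
  out <- bind_rows(existing, assigned)
  attr(out, "skipped") <- FALSE
  attr(out, "imbalance") <- imbalance
  attr(out, "iterations") <- it
  out
}

# signed boundary flow at each boundary node (inflow to the network positive)
boundary_flows <- function(net, sol) {
  nodes <- net$nodes
  segs <- net$segments
  Q <- sol$flows$flow[match(segs$id, sol$flows$id)]
  bn <- nodes$id[nodes$is_boundary]
  flow <- vapply(bn, function(nid) {
    sum(Q[segs$node_i == nid]) - sum(Q[segs$node_j == nid])
  }, numeric(1))
  tibble(node_id = bn, flow = flow)
}

#' Simulate steady-state network hemodynamics
#'
#' Runs the coupled fixed point of the blood flow model: apparent viscosity
#' from the current hematocrit field, nodal pressures and segment flows from
#' the Poiseuille system, hematocrit redistribution through the new flow
#' field, under-relaxed until both the pressure and the hematocrit fields
#' stop changing. Derived per-segment quantities are reported alongside:
#' velocity `u = 4Q/(pi D^2)` (mm/s), wall shear stress
#' `tau = 32 mu Q/(pi D^3)` (dyn/cm^2) and transit time
#' `vstt = pi D^2 L/(4Q)` (s, `Inf` for unperfused segments).
#'
#' @param net A [vascular_network()].
#' @param config A [flow_config()].
#' @param params A [rheology_params()].
#' @return An object of class `hemodynamic_state`: tibbles `pressures`
#'   (per node) and `segments` (per segment: `flow`, `hd`, `ht`,
#'   `viscosity`, `velocity`, `wall_shear`, `transit_time`, `perfused`),
#'   plus convergence metadata. Use [tidy()] / [glance()] to extract them.
#' @examples
#' net <- make_bifurcation_tree(depth = 2, p_root = 30, p_leaf = 10)
#' state <- simulate_hemodynamics(net)
#' glance(state)
#' @export
simulate_hemodynamics <- function(net, config = flow_config(),
                                  params = rheology_params()) {
  stopifnot(inherits(net, "vascular_network"))
  segs <- net$segments
  bp <- optimize_boundary_pressures(net, config, params)

  hd <- rep(config$inlet_hematocrit, nrow(segs))
  P_old <- NULL
  trace <- list()
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    mu <- apparent_viscosity(segs$diameter, pmin(hd, 0.99), params)
    sol <- solve_pressures(net, mu, boundary_pressures = bp)
    hnew <- distribute_hematocrit(net, sol$flows, sol$pressures,
                                  config$inlet_hematocrit, params)
    dh <- max(abs(hnew$hd - hd))
    dp <- if (is.null(P_old)) Inf else {
      max(abs(sol$pressures$pressure - P_old)) /
        max(abs(sol$pressures$pressure), 1e-300)
    }
    trace[[it]] <- tibble(iteration = it, delta_hd = dh, delta_p = dp,
                          mass_residual = sol$mass_residual)
    hd <- hd + config$relaxation * (hnew$hd - hd)
    hd[hnew$zero_flow] <- 0      # advectively dead: no relaxation memory
    if (dh < config$tol_hematocrit &&
        (dp < config$tol_pressure || (it == 1L && dh == 0))) {
      converged <- TRUE
      break
    }
    P_old <- sol$pressures$pressure
  }
  if (!converged) {
    abort(paste0("hemodynamics fixed point did not converge in ",
                 config$max_iterations, " iterations; last delta_hd = ",
                 format(trace[[length(trace)]]$delta_hd)))
  }

  # mu is the viscosity field that produced the final flow solution
  Q <- sol$flows$flow
  qa <- abs(Q)
  seg_out <- tibble(
    id = segs$id, node_i = segs$node_i, node_j = segs$node_j,
    diameter = segs$diameter, length = segs$length,
    flow = Q,
    hd = hnew$hd,
    ht = fahraeus_tube_hematocrit(segs$diameter, hnew$hd, params),
    viscosity = mu,
    velocity = 4e6 * qa / (pi * segs$diameter^2),
    wall_shear = 32e7 * mu * qa / (pi * segs$diameter^3),
    transit_time = pi * segs$diameter^2 * segs$length * 1e-9 / (4 * qa),
    zero_flow = hnew$zero_flow,
    perfused = qa >= 1e-10
  )

  bq <- boundary_flows(net, sol)
  rbc <- rbc_balance(net, seg_out)
  structure(
    list(network = net, pressures = sol$pressures, segments = seg_out,
         boundary_pressures = bp, config = config, params = params,
         iterations = it, converged = converged,
         residuals = list(mass_residual = sol$mass_residual,
                          rbc_rel_imbalance = rbc,
                          trace = bind_rows(trace)),
         boundary_flow = bq),
    class = "hemodynamic_state"
  )
}

# relative imbalance of network red-cell influx vs efflux
rbc_balance <- function(net, seg_out) {
  nodes <- net$nodes
  bn <- nodes$id[nodes$is_boundary]
  influx <- 0
  efflux <- 0
  for (nid in bn) {
    k <- which(seg_out$node_i == nid | seg_out$node_j == nid)
    for (s in k) {
      qs <- seg_out$flow[s] * (if (seg_out$node_i[s] == nid) 1 else -1)
      rbcf <- abs(seg_out$flow[s]) * seg_out$hd[s]
      if (qs > 0) influx <- influx + rbcf else efflux <- efflux + rbcf
    }
  }
  if (influx <= 0) return(0)
  abs(influx - efflux) / influx
}

#' @export
print.hemodynamic_state <- function(x, ...) {
  cat("<hemodynamic_state>\n")
  cat("  segments:", nrow(x$segments),
      sprintf(" (perfused: %d)\n", sum(x$segments$perfused)))
  cat(sprintf("  converged in %d outer iterations; mass residual %.2e\n",
              x$iterations, x$residuals$mass_residual))
  invisible(x)
}
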