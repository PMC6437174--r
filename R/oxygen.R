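#' Oxygen transport parameters
#'
#' Physiological constants and solver controls of the intravascular oxygen
#' model. Hill-curve constants and the plasma solubility carry standard
#' default values (Hill exponent 2.7, half-saturation 37 mmHg, plasma
#' solubility 2.82e-5 ml O2/ml/mmHg), as do the eligibility filters that
#' restrict wall flux to vessels transporting significant oxygen (discharge
#' hematocrit > 0.01 and segment transit time < 25 s). The red-cell
#' solubility `alpha_rbc` and binding capacity `c_bind` defaults are
#' physiologically standard textbook values, not tied to a specific
#' calibration; the tissue oxygen consumption rate `m_c` has no defensible
#' default and must always be supplied.
#'
#' @param m_c Tissue O2 consumption rate, ml O2 / g / s. Required.
#' @param m_tissue Tissue mass, g. If `NULL`, computed as
#'   `tissue_density * volume(net)` when the network carries a tumor volume.
#' @param tissue_density Tissue density, g/ml (default 1).
#' @param c_bind Red-cell O2 binding capacity, ml O2 / ml RBC (default 0.5).
#' @param n_hill Hill cooperativity exponent (default 2.7).
#' @param p50 Half-saturation oxygen tension, mmHg (default 37).
#' @param alpha_pl Plasma O2 solubility, ml O2/ml/mmHg (default 2.82e-5).
#' @param alpha_rbc Red-cell O2 solubility, ml O2/ml/mmHg (default 3.38e-5).
#' @param hd_min,vstt_max Eligibility filters: a segment receives wall flux
#'   only if its discharge hematocrit exceeds `hd_min` (default 0.01) and
#'   its transit time is below `vstt_max` seconds (default 25).
#' @param inlet_po2 Oxygen tension imposed at inflow boundary nodes, mmHg.
#' @param normalize_eligible_only If `TRUE` (default) the per-segment wall
#'   flux `M_c m_tissue L/sum(L)` normalizes by the summed length of
#'   eligible segments, so the delivered total equals `m_c * m_tissue`
#'   exactly; if `FALSE`, by all segment lengths.
#' @param tolerance,max_iterations,relaxation Fixed-point controls of the
#'   saturation iteration.
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(m_c, m_tissue = NULL, tissue_density = 1,
                          c_bind = 0.5, n_hill = 2.7, p50 = 37,
                          alpha_pl = 2.82e-5, alpha_rbc = 3.38e-5,
                          hd_min = 0.01, vstt_max = 25,
                          inlet_po2 = 60,
                          normalize_eligible_only = TRUE,
                          tolerance = 1e-10, max_iterations = 200L,
                          relaxation = 0.5) {
  if (missing(m_c) || is.null(m_c) || !is.finite(m_c)) {
    abort("`m_c` (tissue O2 consumption rate, ml O2/g/s) must be supplied")
  }
  stopifnot(m_c >= 0, tissue_density > 0, c_bind >= 0, n_hill > 0, p50 > 0,
            alpha_pl > 0, alpha_rbc > 0, hd_min >= 0, vstt_max > 0,
            inlet_po2 >= 0, tolerance > 0, max_iterations >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(m_c = m_c, m_tissue = m_tissue,
                 tissue_density = tissue_density, c_bind = c_bind,
                 n_hill = n_hill, p50 = p50, alpha_pl = alpha_pl,
                 alpha_rbc = alpha_rbc, hd_min = hd_min,
                 vstt_max = vstt_max, inlet_po2 = inlet_po2,
                 normalize_eligible_only = normalize_eligible_only,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 relaxation = relaxation),
            class = "oxygen_params")
}

#' Hill hemoglobin oxygen saturation
#'
#' `S = P^n / (P^n + P50^n)`: the sigmoidal oxygen-hemoglobin dissociation
#' curve, strictly increasing in tension.
#'
#' @param po2 Oxygen tension(s), mmHg, non-negative.
#' @param params An [oxygen_params()] (only `n_hill` and `p50` are used).
#' @return Saturation fraction in `[0, 1)`.
#' @examples
#' hill_saturation(37, oxygen_params(m_c = 1e-4))  # 0.5 at P50
#' @export
hill_saturation <- function(po2, params) {
  if (any(po2 < 0, na.rm = TRUE)) abort("`po2` must be non-negative")
  pn <- po2^params$n_hill
  pn / (pn + params$p50^params$n_hill)
}

#' Effective oxygen solubility of blood
#'
#' Tube-hematocrit-weighted blend of red-cell and plasma solubilities:
#' `alpha_b = HT * alpha_RBC + (1 - HT) * alpha_pl`.
#'
#' @param ht Tube hematocrit(s) in `[0, 1]`.
#' @param params An [oxygen_params()].
#' @return Solubility in ml O2/ml/mmHg.
#' @export
blood_solubility <- function(ht, params) {
  if (any(ht < 0 | ht > 1)) abort("`ht` must lie in [0, 1]")
  ht * params$alpha_rbc + (1 - ht) * params$alpha_pl
}

#' Per-segment transmural oxygen fluxes
#'
#' Distributes the whole-tissue oxygen demand `m_c * m_tissue` over vessel
#' segments in proportion to their length, restricted to segments that
#' transport significant oxygen: discharge hematocrit above `hd_min` and
#' transit time below `vstt_max`. Ineligible segments receive zero wall flux
#' (they still advect oxygen).
#'
#' @param net A [vascular_network()].
#' @param state A [simulate_hemodynamics()] result.
#' @param params An [oxygen_params()].
#' @return Tibble `id`, `eligible`, `j_wall` (ml O2/s), ordered as
#'   `net$segments`.
#' @export
wall_fluxes <- function(net, state, params) {
  stopifnot(inherits(net, "vascular_network"),
            inherits(state, "hemodynamic_state"))
  segs <- state$segments
  eligible <- segs$hd > params$hd_min & segs$transit_time < params$vstt_max
  if (!any(eligible) && params$m_c > 0) {
    abort("no eligible segment: the network cannot serve the oxygen demand")
  }
  m_tissue <- params$m_tissue
  if (is.null(m_tissue)) {
    if (!is.finite(net$volume)) {
      abort("supply `m_tissue` in oxygen_params() or a network tumor volume")
    }
    m_tissue <- params$tissue_density * net$volume * 1e-3  # mm^3 -> ml
  }
  denom <- if (params$normalize_eligible_only) {
    sum(segs$length[eligible])
  } else {
    sum(segs$length)
  }
  j <- ifelse(eligible, params$m_c * m_tissue * segs$length / denom, 0)
  tibble(id = segs$id, eligible = eligible, j_wall = j)
}

#' Solve intravascular oxygen transport
#'
#' Computes nodal oxygen tensions from per-segment oxygen balances: along
#' each perfused segment the drop in advected oxygen content — dissolved
#' (`Q alpha_b dP`) plus hemoglobin-bound (`Q H_D C_bind dS_Hb`) — equals
#' the segment's transmural flux, and converging junctions mix flux-weighted
#' compositions. With saturations frozen, the upwinded balances form a
#' sparse linear system in the nodal tensions; saturations are then
#' refreshed from the Hill curve (under-relaxed) and the two steps iterate
#' to a fixed point. Inflow boundary nodes carry the prescribed inlet
#' tension. Negative tensions arising during iteration are clamped to zero
#' with a warning (oxygen demand locally exceeding supply).
#'
#' @param net A [vascular_network()].
#' @param state A converged [simulate_hemodynamics()] result.
#' @param params An [oxygen_params()].
#' @return An object of class `oxygen_state`: tibble `nodes` (`id`, `po2`,
#'   `known`), tibble `segments` (`id`, `po2` mean of endpoint tensions,
#'   `s_hb`, `alpha_b`, `j_wall`, `eligible`), convergence metadata and the
#'   global oxygen balance residual.
#' @export
solve_oxygen <- function(net, state, params) {
  stopifnot(inherits(net, "vascular_network"),
            inherits(state, "hemodynamic_state"))
  segs <- state$segments
  nodes <- net$nodes
  n <- nrow(nodes)

  wf <- wall_fluxes(net, state, params)
  alpha_b <- blood_solubility(pmin(pmax(segs$ht, 0), 1), params)

  qa <- abs(segs$flow)
  qtol <- max(max(qa, 0) * 1e-14, 1e-10)   # perfused floor, ul/s
  live <- qa > qtol
  from <- ifelse(segs$flow >= 0, segs$node_i, segs$node_j)
  to <- ifelse(segs$flow >= 0, segs$node_j, segs$node_i)
  fidx <- match(from, nodes$id)
  tidx <- match(to, nodes$id)

  in_live <- tabulate(tidx[live], nbins = n)
  out_live <- tabulate(fidx[live], nbins = n)
  touched <- in_live + out_live > 0L

  # inflow boundary nodes carry the prescribed tension
  known <- nodes$is_boundary & out_live > 0L & in_live == 0L
  if (!any(known)) abort("no inflow boundary node: cannot impose inlet PO2")

  # only nodes fed (directly or indirectly) by an inlet are solvable;
  # residual numerical circulations disconnected from any inlet are left NA
  dg <- igraph::graph_from_data_frame(
    data.frame(from = fidx[live], to = tidx[live]), directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  reach <- rep(FALSE, n)
  reach[unique(unlist(igraph::ego(dg, order = n, nodes = which(known),
                                  mode = "out")))] <- TRUE
  unknown <- touched & !known & reach

  ku <- which(unknown)
  pos <- integer(n); pos[ku] <- seq_along(ku)

  # advective coefficients in ml O2 / s / mmHg (dissolved) and ml O2 / s
  # (bound): flow converted ul/s -> ml/s to match J_wall in ml O2/s
  qml <- qa * 1e-3
  w_d <- qml * alpha_b
  w_s <- qml * segs$hd * params$c_bind

  # For each unknown node: sum_in w_d P_from - out_w_d P_j = rhs, where the
  # outflow composition at outlet (inflow-only) nodes is carried by the
  # inflow segments themselves, making the per-segment content drop exact.
  lives <- which(live)
  out_carrier <- lapply(seq_len(n), function(v) {
    eo <- lives[fidx[lives] == v]
    if (length(eo)) eo else lives[tidx[lives] == v]
  })

  ein_by <- lapply(seq_len(n), function(v) lives[tidx[lives] == v])

  # Quasi-linearization of the Hill term: the bound advected content
  # H_D C_bind S(P) is written as w_s * sigma * P with the secant slope
  # sigma = S(P)/P refreshed each sweep, so both dissolved and bound
  # transport coefficients sit in the system matrix (the dominant bound
  # term would make a lagged-saturation fixed point diverge).
  secant <- function(p) {
    s <- numeric(length(p))
    pos_p <- !is.na(p) & p > 1e-12
    s[pos_p] <- hill_saturation(p[pos_p], params) / p[pos_p]
    s
  }

  P <- rep(NA_real_, n)
  P[known] <- params$inlet_po2
  P[unknown] <- params$inlet_po2
  sig <- secant(ifelse(is.na(P), 0, P))

  clamped_any <- FALSE
  converged <- FALSE
  trace <- numeric(0)
  nun <- length(ku)
  for (it in seq_len(params$max_iterations)) {
    trip_i <- vector("list", nun); trip_j <- vector("list", nun)
    trip_x <- vector("list", nun)
    rhs <- numeric(nun)
    for (r in seq_len(nun)) {
      v <- ku[r]
      ein <- ein_by[[v]]
      eout <- out_carrier[[v]]
      ti <- r; tj <- r
      tx <- -sum(w_d[eout] + w_s[eout] * sig[v])
      rhs_r <- sum(wf$j_wall[ein])
      for (e in ein) {
        u <- fidx[e]
        ce <- w_d[e] + w_s[e] * sig[u]
        if (unknown[u]) {
          ti <- c(ti, r); tj <- c(tj, pos[u]); tx <- c(tx, ce)
        } else if (!is.na(P[u])) {
          rhs_r <- rhs_r - ce * P[u]
        }
      }
      trip_i[[r]] <- ti; trip_j[[r]] <- tj; trip_x[[r]] <- tx
      rhs[r] <- rhs_r
    }
    A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(nun, nun))
    # advective weights span many orders of magnitude; equilibrate rows by
    # the diagonal so the (topologically triangular) system solves stably
    dg <- Matrix::diag(A)
    A <- A / dg
    Pnew_u <- as.numeric(Matrix::solve(A, rhs / dg))
    if (any(Pnew_u < 0)) {
      clamped_any <- TRUE
      Pnew_u[Pnew_u < 0] <- 0
    }
    dP <- max(abs(Pnew_u - P[ku]))
    P[ku] <- P[ku] + params$relaxation * (Pnew_u - P[ku])
    sig_new <- secant(ifelse(is.na(P), 0, P))
    dSig <- max(abs(sig_new - sig) * params$p50)  # on a tension scale
    sig <- sig_new
    trace <- c(trace, dP)
    if (dP < params$tolerance && dSig < params$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0("oxygen fixed point did not converge; residual trace tail: ",
                 paste(format(tail(trace, 3)), collapse = ", ")))
  }
  if (clamped_any) {
    warn("negative oxygen tensions clamped to 0 (demand exceeds local supply)")
  }
  S <- hill_saturation(pmax(P, 0), params)  # exact Hill residual at the end

  seg_po2 <- rowMeans(cbind(P[match(segs$node_i, nodes$id)],
                            P[match(segs$node_j, nodes$id)]), na.rm = TRUE)
  seg_po2[is.nan(seg_po2)] <- NA_real_
  seg_tbl <- tibble(
    id = segs$id,
    po2 = seg_po2,
    s_hb = ifelse(is.na(seg_po2), NA_real_,
                  hill_saturation(pmax(seg_po2, 0), params)),
    alpha_b = alpha_b,
    j_wall = wf$j_wall,
    eligible = wf$eligible
  )
  node_tbl <- tibble(id = nodes$id, po2 = P, known = known)

  balance <- oxygen_balance(net, state, node_tbl, seg_tbl, params)
  structure(
    list(network = net, nodes = node_tbl, segments = seg_tbl,
         params = params, iterations = it, converged = converged,
         clamped = clamped_any, residual_trace = trace,
         balance = balance),
    class = "oxygen_state"
  )
}

# advected O2 in at inflow boundaries minus out at outflow boundaries,
# compared with the total wall flux (relative residual)
oxygen_balance <- function(net, state, node_tbl, seg_tbl, params) {
  segs <- state$segments
  nodes <- net$nodes
  qa <- abs(segs$flow)
  qtol <- max(max(qa, 0) * 1e-14, 1e-10)
  from <- ifelse(segs$flow >= 0, segs$node_i, segs$node_j)
  to <- ifelse(segs$flow >= 0, segs$node_j, segs$node_i)
  alpha_b <- seg_tbl$alpha_b
  P <- setNames(node_tbl$po2, node_tbl$id)
  S <- hill_saturation(pmax(ifelse(is.na(P), 0, P), 0), params)
  names(S) <- node_tbl$id
  content <- function(e, nid) {
    qa[e] * 1e-3 * (alpha_b[e] * P[as.character(nid)] +
                      segs$hd[e] * params$c_bind * S[as.character(nid)])
  }
  inflow <- 0; outflow <- 0
  bn <- nodes$id[nodes$is_boundary]
  for (e in which(qa > qtol)) {
    if (from[e] %in% bn) inflow <- inflow + content(e, from[e])
    if (to[e] %in% bn) outflow <- outflow + content(e, to[e])
  }
  total_j <- sum(seg_tbl$j_wall)
  rel <- if (inflow > 0) abs(inflow - outflow - total_j) / inflow else NA_real_
  list(advected_in = inflow, advected_out = outflow,
       wall_flux_total = total_j, relative_residual = rel)
}

#' @export
print.oxygen_state <- function(x, ...) {
  cat("<oxygen_state>\n")
  cat(sprintf("  nodes: %d (known inlets: %d)\n", nrow(x$nodes),
              sum(x$nodes$known)))
  cat(sprintf("  eligible segments: %d / %d\n", sum(x$segments$eligible),
              nrow(x$segments)))
  cat(sprintf("  converged in %d iterations; O2 balance residual %.2e\n",
              x$iterations, x$balance$relative_residual))
  invisible(x)
}
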