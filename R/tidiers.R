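#' Tidy a hemodynamic state
#'
#' @param x A [simulate_hemodynamics()] result.
#' @param ... Unused.
#' @return The per-segment tibble (flow, hematocrits, viscosity, velocity,
#'   wall shear, transit time, perfusion flag).
#' @method tidy hemodynamic_state
#' @export
tidy.hemodynamic_state <- function(x, ...) x$segments

#' One-row summary of a hemodynamic state
#'
#' @inheritParams tidy.hemodynamic_state
#' @return Tibble with segment counts, convergence info, conservation
#'   residuals, total boundary inflow (ul/s) and mean path length (um).
#' @method glance hemodynamic_state
#' @export
glance.hemodynamic_state <- function(x, ...) {
  tibble(
    n_segments = nrow(x$segments),
    n_perfused = sum(x$segments$perfused),
    iterations = x$iterations,
    converged = x$converged,
    mass_residual = x$residuals$mass_residual,
    rbc_imbalance = x$residuals$rbc_rel_imbalance,
    total_inflow = sum(x$boundary_flow$flow[x$boundary_flow$flow > 0]),
    mpl = mean_path_length(x)
  )
}

#' Tidy an oxygen state
#'
#' @param x A [solve_oxygen()] result.
#' @param ... Unused.
#' @return The per-segment tibble (PO2, saturation, solubility, wall flux,
#'   eligibility).
#' @method tidy oxygen_state
#' @export
tidy.oxygen_state <- function(x, ...) x$segments

#' One-row summary of an oxygen state
#'
#' @inheritParams tidy.oxygen_state
#' @return Tibble with eligibility counts, convergence info and the global
#'   oxygen balance.
#' @method glance oxygen_state
#' @export
glance.oxygen_state <- function(x, ...) {
  tibble(
    n_segments = nrow(x$segments),
    n_eligible = sum(x$segments$eligible),
    iterations = x$iterations,
    converged = x$converged,
    clamped = x$clamped,
    advected_in = x$balance$advected_in,
    advected_out = x$balance$advected_out,
    wall_flux_total = x$balance$wall_flux_total,
    balance_residual = x$balance$relative_residual,
    median_po2 = median(x$segments$po2, na.rm = TRUE)
  )
}

#' Tidy a network clustering
#'
#' @param x A [cluster_networks()] result.
#' @param ... Unused.
#' @return Tibble `network`, `cluster`.
#' @method tidy network_clustering
#' @export
tidy.network_clustering <- function(x, ...) {
  tibble(network = names(x$labels), cluster = unname(x$labels))
}

#' One-row summary of a network clustering
#'
#' @inheritParams tidy.network_clustering
#' @return Tibble `n_networks`, `n_features`, `k`, `cophenetic`,
#'   `reliable`.
#' @method glance network_clustering
#' @export
glance.network_clustering <- function(x, ...) {
  tibble(
    n_networks = nrow(x$features),
    n_features = ncol(x$features),
    k = length(unique(x$labels)),
    cophenetic = x$cophenetic,
    reliable = x$reliable
  )
}

#' Tidy a CV correlation matrix
#'
#' @param x A [cv_correlation_matrix()] result.
#' @param ... Unused.
#' @return Long tibble `parameter_a`, `parameter_b`, `r`, `p_value`,
#'   `significant` over unique off-diagonal pairs.
#' @method tidy cv_correlation
#' @export
tidy.cv_correlation <- function(x, ...) {
  nm <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    parameter_a = nm[idx[, 1]],
    parameter_b = nm[idx[, 2]],
    r = x$r[idx],
    p_value = x$p[idx],
    significant = x$significant[idx]
  )
}
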