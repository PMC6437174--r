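#' Vessel-niche classification thresholds
#'
#' Literature-based cut points separating the four functional vessel
#' classes: velocity 50 um/s and oxygenation 10 mmHg for the
#' hypoperfused/hyperperfused and hypoxic/normoxic axes, and the shunt
#' criteria (velocity and diameter at least twice the perfused-population
#' median, length at most half the median). Only vessels carrying at least
#' `perfusion_floor` flow are analyzed.
#'
#' @param velocity Velocity threshold, um/s (default 50).
#' @param po2 Oxygen tension threshold, mmHg (default 10).
#' @param shunt_velocity_factor,shunt_diameter_factor Multiples of the
#'   median velocity/diameter a shunt must reach (default 2).
#' @param shunt_length_factor Fraction of the median length a shunt must
#'   stay below (default 0.5).
#' @param perfusion_floor Minimum flow for a segment to count as perfused,
#'   ul/s (default 1e-10).
#' @return An object of class `class_thresholds`.
#' @export
class_thresholds <- function(velocity = 50, po2 = 10,
                             shunt_velocity_factor = 2,
                             shunt_diameter_factor = 2,
                             shunt_length_factor = 0.5,
                             perfusion_floor = 1e-10) {
  stopifnot(velocity > 0, po2 > 0, shunt_velocity_factor > 0,
            shunt_diameter_factor > 0, shunt_length_factor > 0,
            perfusion_floor > 0)
  structure(list(velocity = velocity, po2 = po2,
                 shunt_velocity_factor = shunt_velocity_factor,
                 shunt_diameter_factor = shunt_diameter_factor,
                 shunt_length_factor = shunt_length_factor,
                 perfusion_floor = perfusion_floor),
            class = "class_thresholds")
}

#' Classify vessels into functional niches
#'
#' Labels every perfused segment with one of four classes. Shunts (Class 4)
#' are tested first, since their criteria can co-occur with Class 2's:
#' velocity at least `shunt_velocity_factor` times the median velocity,
#' diameter at least `shunt_diameter_factor` times the median diameter, and
#' length at most `shunt_length_factor` times the median length, medians
#' taken over the perfused segments of the same network. Otherwise Class 1
#' is hypoperfused and hypoxic (velocity < 50 um/s and PO2 < 10 mmHg),
#' Class 2 hyperperfused and normoxic (velocity >= 50 um/s and
#' PO2 >= 10 mmHg), and Class 3 the two mixed quadrants. Unperfused
#' segments get `NA`.
#'
#' @param state A [simulate_hemodynamics()] result.
#' @param oxygen A [solve_oxygen()] result for the same network.
#' @param thresholds A [class_thresholds()].
#' @return A tibble `id`, `velocity_um_s`, `po2`, `perfused`, `class`
#'   (integer 1-4, `NA` for unperfused).
#' @export
classify_vessels <- function(state, oxygen, thresholds = class_thresholds()) {
  stopifnot(inherits(state, "hemodynamic_state"),
            inherits(oxygen, "oxygen_state"))
  segs <- state$segments
  po2 <- oxygen$segments$po2[match(segs$id, oxygen$segments$id)]
  vel <- segs$velocity * 1e3                    # mm/s -> um/s
  perfused <- abs(segs$flow) >= thresholds$perfusion_floor
  if (!any(perfused)) abort("no perfused segment to classify")

  med_v <- median(vel[perfused])
  med_d <- median(segs$diameter[perfused])
  med_l <- median(segs$length[perfused])

  shunt <- vel >= thresholds$shunt_velocity_factor * med_v &
    segs$diameter >= thresholds$shunt_diameter_factor * med_d &
    segs$length <= thresholds$shunt_length_factor * med_l
  slow <- vel < thresholds$velocity
  hypoxic <- po2 < thresholds$po2

  cls <- ifelse(shunt, 4L,
         ifelse(slow & hypoxic, 1L,
         ifelse(!slow & !hypoxic, 2L, 3L)))
  cls[!perfused] <- NA_integer_
  tibble(id = segs$id, velocity_um_s = vel, po2 = po2,
         perfused = perfused, class = as.integer(cls))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean — the package's normalized
#' heterogeneity index, comparable across parameters with different units.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return A single number, `sd(values)/mean(values)`.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("need at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m == 0) abort("mean is zero or non-finite")
  sd(values) / m
}

#' Pairwise Pearson correlations between heterogeneity indices
#'
#' Takes a per-network table of coefficients of variation (rows = networks,
#' columns = parameters) and computes the Pearson correlation and two-sided
#' p-value for every parameter pair. Constant columns have undefined
#' correlations and are reported as `NA`.
#'
#' @param cv_table Data frame of CVs; non-numeric columns (e.g. a network
#'   id) are dropped.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return An object of class `cv_correlation`: list with matrices `r`,
#'   `p`, logical `significant`, and `n` networks. [tidy()] returns the
#'   pairs in long form.
#' @export
cv_correlation_matrix <- function(cv_table, alpha = 0.05) {
  tab <- as_tibble(as.data.frame(cv_table))
  tab <- tab[vapply(tab, is.numeric, logical(1))]
  if (nrow(tab) < 3) abort("need at least 3 networks")
  if (anyNA(tab)) abort("missing entries in the CV table")
  p_names <- names(tab)
  k <- length(p_names)
  r <- matrix(NA_real_, k, k, dimnames = list(p_names, p_names))
  p <- matrix(NA_real_, k, k, dimnames = list(p_names, p_names))
  const <- vapply(tab, function(x) sd(x) == 0, logical(1))
  if (any(const)) {
    inform(paste0("constant column(s), correlation undefined: ",
                  paste(p_names[const], collapse = ", ")))
  }
  for (a in seq_len(k)) {
    r[a, a] <- if (const[a]) NA_real_ else 1
    p[a, a] <- if (const[a]) NA_real_ else 0
    for (b in seq_len(k)[-seq_len(a)]) {
      if (const[a] || const[b]) next
      ct <- suppressWarnings(cor.test(tab[[a]], tab[[b]], method = "pearson"))
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha,
                 n = nrow(tab), alpha = alpha),
            class = "cv_correlation")
}

#' @export
print.cv_correlation <- function(x, ...) {
  cat("<cv_correlation> over", x$n, "networks\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Per-segment derived flow metrics and mean path length
#'
#' Computes velocity `u = 4 Q / (pi D^2)` (mm/s), wall shear stress
#' `tau = 32 mu Q / (pi D^3)` (dyn/cm^2) and transit time
#' `vstt = pi D^2 L / (4 Q)` (s; `Inf` for zero-flow segments) from a
#' per-segment table, and attaches the flow-weighted mean path length
#' `MPL = sum(Q L) / sum(Q)` (um) over perfused segments as an attribute.
#'
#' @param segments A [simulate_hemodynamics()] result or a data frame with
#'   columns `flow` (ul/s), `diameter` (um), `length` (um) and `viscosity`
#'   (cP).
#' @param perfusion_floor Flow floor (ul/s) for the MPL weights.
#' @return The per-segment tibble with `velocity`, `wall_shear`,
#'   `transit_time` columns and attribute `"mpl"` (um).
#' @examples
#' d <- data.frame(flow = c(1, 3), diameter = 10, length = c(10, 20),
#'                 viscosity = 1)
#' attr(derived_flow_metrics(d), "mpl")  # 17.5
#' @export
derived_flow_metrics <- function(segments, perfusion_floor = 1e-10) {
  if (inherits(segments, "hemodynamic_state")) segments <- segments$segments
  segments <- as_tibble(as.data.frame(segments))
  need <- c("flow", "diameter", "length", "viscosity")
  if (!all(need %in% names(segments))) {
    abort(paste0("`segments` needs columns ", paste(need, collapse = ", ")))
  }
  qa <- abs(segments$flow)
  out <- mutate(segments,
    velocity = 4e6 * qa / (pi * .data$diameter^2),
    wall_shear = 32e7 * .data$viscosity * qa / (pi * .data$diameter^3),
    transit_time = pi * .data$diameter^2 * .data$length * 1e-9 / (4 * qa)
  )
  perf <- qa >= perfusion_floor
  attr(out, "mpl") <- if (any(perf)) {
    sum(qa[perf] * segments$length[perf]) / sum(qa[perf])
  } else {
    NA_real_
  }
  out
}

#' Flow-weighted mean path length of a network
#'
#' @inheritParams derived_flow_metrics
#' @return MPL in um.
#' @export
mean_path_length <- function(segments, perfusion_floor = 1e-10) {
  attr(derived_flow_metrics(segments, perfusion_floor), "mpl")
}

#' Compare two tumor groups
#'
#' Two-tailed Mann-Whitney U test on a per-network summary statistic
#' (e.g. median transit time of Day-21 vs Day-35 tumors).
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble `statistic` (U of the first group), `p_value`,
#'   `significant`, `n_a`, `n_b`. Fully tied data yield `p = 1` with a
#'   warning.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  if (length(unique(c(values_a, values_b))) == 1L) {
    warn("all values tied; p set to 1")
    return(tibble(statistic = length(values_a) * length(values_b) / 2,
                  p_value = 1, significant = FALSE,
                  n_a = length(values_a), n_b = length(values_b)))
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         significant = wt$p.value < alpha,
         n_a = length(values_a), n_b = length(values_b))
}

#' UPGMA clustering of networks on median vascular parameters
#'
#' Hierarchical clustering with unweighted pair-group averaging (UPGMA) on
#' Euclidean distances between z-scored per-network feature vectors —
#' typically median morphological (L, L_v, S_v, D_v) and/or hemodynamic
#' (Q, velocity, PO2, vstt, MPL) parameters. The cophenetic correlation
#' coefficient between the dendrogram-implied and original distances is
#' reported and flagged when at or below 0.8 (the conventional validity
#' cut).
#'
#' @param features Data frame with one row per network: an id column
#'   (`network`, or the first non-numeric column, or row order) plus
#'   numeric feature columns.
#' @param feature_set Optional character vector selecting feature columns.
#' @param k Number of flat clusters to cut (default 2); ignored when `h`
#'   given.
#' @param h Optional dendrogram height (distance threshold) for the flat
#'   cut.
#' @return An object of class `network_clustering`: the `hclust` tree,
#'   per-network `labels`, `cophenetic` coefficient, `reliable` flag and
#'   the feature matrix used. [tidy()] gives per-network labels,
#'   [glance()] the fit summary.
#' @export
cluster_networks <- function(features, feature_set = NULL, k = 2L, h = NULL) {
  tab <- as_tibble(as.data.frame(features))
  if (nrow(tab) < 2) abort("need at least 2 networks")
  num <- vapply(tab, is.numeric, logical(1))
  ids <- if ("network" %in% names(tab)) {
    as.character(tab$network)
  } else if (any(!num)) {
    as.character(tab[[which(!num)[1]]])
  } else {
    as.character(seq_len(nrow(tab)))
  }
  x <- tab[num & names(tab) != "network"]
  if (!is.null(feature_set)) {
    missing_f <- setdiff(feature_set, names(x))
    if (length(missing_f)) {
      abort(paste0("unknown feature(s): ", paste(missing_f, collapse = ", ")))
    }
    x <- x[feature_set]
  }
  if (!ncol(x)) abort("no numeric feature columns")
  m <- as.matrix(x)
  rownames(m) <- ids
  # z-score; constant columns carry no information and are dropped
  sds <- apply(m, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    inform(paste0("dropping constant feature(s): ",
                  paste(colnames(m)[!keep], collapse = ", ")))
  }
  m <- m[, keep, drop = FALSE]
  if (!ncol(m)) abort("all features constant")
  z <- scale(m)
  d <- dist(z, method = "euclidean")
  if (any(d == 0)) inform("duplicate feature rows (zero distance)")
  tree <- hclust(d, method = "average")
  coph <- suppressWarnings(cor(d, cophenetic(tree)))
  labels <- if (!is.null(h)) cutree(tree, h = h) else cutree(tree, k = k)
  structure(list(tree = tree, labels = setNames(labels, ids),
                 cophenetic = coph, reliable = is.finite(coph) && coph > 0.8,
                 features = z, distances = d),
            class = "network_clustering")
}

#' @export
print.network_clustering <- function(x, ...) {
  cat("<network_clustering> UPGMA on", nrow(x$features), "networks,",
      ncol(x$features), "features\n")
  cat(sprintf("  cophenetic correlation: %.3f (%s)\n", x$cophenetic,
              if (x$reliable) "reliable" else "below 0.8"))
  print(x$labels)
  invisible(x)
}

#' Heterogeneity report for an ensemble of simulated networks
#'
#' Builds the per-network CV table over the standard morphological and
#' hemodynamic parameters (perfused segments only for the hemodynamic
#' ones), the pairwise CV correlation matrix, and per-network medians plus
#' MPL for clustering.
#'
#' @param states Named list of [simulate_hemodynamics()] results.
#' @param oxygens Optional named list of matching [solve_oxygen()] results.
#' @param perfusion_floor Flow floor for the perfused filter, ul/s.
#' @return List with tibbles `cv` and `medians` (one row per network) and,
#'   when >= 3 networks, the [cv_correlation_matrix()] under `correlation`.
#' @export
heterogeneity_report <- function(states, oxygens = NULL,
                                 perfusion_floor = 1e-10) {
  stopifnot(length(states) >= 1)
  nm <- names(states) %||% as.character(seq_along(states))
  one <- function(state, oxy, id) {
    segs <- state$segments
    perf <- abs(segs$flow) >= perfusion_floor
    vals <- list(
      diameter = segs$diameter,
      length = segs$length,
      flow = abs(segs$flow)[perf],
      velocity = segs$velocity[perf],
      wall_shear = segs$wall_shear[perf],
      transit_time = segs$transit_time[perf],
      hd = segs$hd[perf]
    )
    if (!is.null(oxy)) {
      po2 <- oxy$segments$po2[match(segs$id, oxy$segments$id)]
      vals$po2 <- po2[perf & is.finite(po2)]
    }
    cvs <- purrr::map_dbl(vals, function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2 || mean(x) == 0) NA_real_
      else coefficient_of_variation(x)
    })
    meds <- purrr::map_dbl(vals, function(x) median(x[is.finite(x)]))
    list(
      cv = bind_cols(tibble(network = id), as_tibble(as.list(cvs))),
      med = bind_cols(tibble(network = id), as_tibble(as.list(meds)),
                      tibble(mpl = mean_path_length(state,
                                                    perfusion_floor)))
    )
  }
  rows <- purrr::map(seq_along(states), function(i) {
    one(states[[i]], if (is.null(oxygens)) NULL else oxygens[[i]], nm[i])
  })
  cv <- bind_rows(purrr::map(rows, "cv"))
  medians <- bind_rows(purrr::map(rows, "med"))
  out <- list(cv = cv, medians = medians)
  if (nrow(cv) >= 3) {
    complete <- cv[, colSums(is.na(cv)) == 0, drop = FALSE]
    out$correlation <- cv_correlation_matrix(complete)
  }
  out
}
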