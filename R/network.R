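#' Construct a vascular network
#'
#' A vascular network is a geometric graph: nodes with 3D positions (um),
#' segments (edges) with a diameter and a centerline length (um), optional
#' boundary conditions at degree-1 nodes, and an optional tumor volume used
#' for volume-normalized statistics. This is the common input of the flow,
#' oxygen and morphometry solvers.
#'
#' Boundary nodes are defined structurally as degree-1 nodes. Segment lengths
#' may exceed the Euclidean end-to-end distance (curved centerlines) but never
#' fall below it. Self-loops are rejected; parallel segments between the same
#' node pair are allowed (distinct ids).
#'
#' @param nodes Data frame with columns `id`, `x`, `y`, `z` (um).
#' @param segments Data frame with columns `id`, `node_i`, `node_j`,
#'   `diameter` (um) and `length` (um). A missing `length` column is filled
#'   with the Euclidean distance between endpoints.
#' @param boundary Optional data frame of boundary conditions with columns
#'   `node_id`, `kind` (one of `"pressure"`, `"flow"`, `"flow_hematocrit"`),
#'   `pressure` (mmHg), `flow` (ul/s, inflow positive) and `hd` (discharge
#'   hematocrit fraction). Exactly one of pressure/flow must be given per row;
#'   `hd` is required for `flow_hematocrit` rows.
#' @param volume Optional tumor volume in mm^3 (metadata used by
#'   [morphology_summary()] and [wall_fluxes()]).
#'
#' @return An object of class `vascular_network`: a list with tibbles
#'   `nodes` (with an `is_boundary` flag), `segments`, `boundary`, and the
#'   scalar `volume`.
#' @seealso [read_network()], [validate_network()], [make_tumor_like()]
#' @examples
#' net <- vascular_network(
#'   nodes = data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0),
#'   segments = data.frame(id = 1, node_i = 1, node_j = 2, diameter = 10)
#' )
#' net
#' @export
vascular_network <- function(nodes, segments, boundary = NULL, volume = NA_real_) {
  nodes <- as_tibble(as.data.frame(nodes))
  segments <- as_tibble(as.data.frame(segments))
  need_n <- c("id", "x", "y", "z")
  if (!all(need_n %in% names(nodes))) {
    abort(paste0("`nodes` must have columns ", paste(need_n, collapse = ", ")))
  }
  nodes <- mutate(nodes, across(c("id"), as.integer),
                  across(c("x", "y", "z"), as.numeric))
  if (anyDuplicated(nodes$id)) {
    abort(paste0("duplicate node ids: ",
                 paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  }
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    abort("node positions must be finite")
  }

  need_s <- c("id", "node_i", "node_j", "diameter")
  if (!all(need_s %in% names(segments))) {
    abort(paste0("`segments` must have columns ", paste(need_s, collapse = ", ")))
  }
  segments <- mutate(segments,
                     across(c("id", "node_i", "node_j"), as.integer),
                     across(c("diameter"), as.numeric))
  if (anyDuplicated(segments$id)) {
    abort("duplicate segment ids")
  }
  dangling <- setdiff(c(segments$node_i, segments$node_j), nodes$id)
  if (length(dangling)) {
    abort(paste0("segments reference unknown nodes: ",
                 paste(sort(dangling), collapse = ", ")))
  }
  if (any(segments$node_i == segments$node_j)) {
    bad <- segments$id[segments$node_i == segments$node_j]
    abort(paste0("self-loop segments not allowed: ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(segments$diameter) | segments$diameter <= 0)) {
    abort("segment diameters must be positive")
  }
  chord <- segment_chord_lengths(nodes, segments)
  if (!"length" %in% names(segments)) {
    segments$length <- chord
  }
  segments$length <- as.numeric(segments$length)
  if (any(!is.finite(segments$length) | segments$length <= 0)) {
    abort("segment lengths must be positive")
  }
  short <- segments$length < chord * (1 - 1e-9) - 1e-9
  if (any(short)) {
    abort(paste0("segment length below endpoint distance for ids: ",
                 paste(segments$id[short], collapse = ", ")))
  }

  deg <- node_degrees(nodes$id, segments)
  nodes$is_boundary <- deg == 1L

  boundary <- normalize_boundary(boundary, nodes)
  structure(
    list(nodes = nodes, segments = segments, boundary = boundary,
         volume = as.numeric(volume)[1]),
    class = "vascular_network"
  )
}

segment_chord_lengths <- function(nodes, segments) {
  idx <- match(segments$node_i, nodes$id)
  jdx <- match(segments$node_j, nodes$id)
  sqrt((nodes$x[idx] - nodes$x[jdx])^2 +
       (nodes$y[idx] - nodes$y[jdx])^2 +
       (nodes$z[idx] - nodes$z[jdx])^2)
}

node_degrees <- function(ids, segments) {
  tab <- table(factor(c(segments$node_i, segments$node_j), levels = ids))
  as.integer(tab)
}

empty_boundary <- function() {
  tibble(node_id = integer(), kind = character(),
         pressure = numeric(), flow = numeric(), hd = numeric())
}

normalize_boundary <- function(boundary, nodes) {
  if (is.null(boundary) || nrow(as.data.frame(boundary)) == 0) {
    return(empty_boundary())
  }
  boundary <- as_tibble(as.data.frame(boundary))
  if (!all(c("node_id", "kind") %in% names(boundary))) {
    abort("`boundary` must have columns node_id, kind")
  }
  for (col in c("pressure", "flow", "hd")) {
    if (!col %in% names(boundary)) boundary[[col]] <- NA_real_
  }
  boundary <- mutate(boundary, node_id = as.integer(.data$node_id),
                     kind = as.character(.data$kind),
                     across(c("pressure", "flow", "hd"), as.numeric))
  bad_kind <- setdiff(boundary$kind, c("pressure", "flow", "flow_hematocrit"))
  if (length(bad_kind)) {
    abort(paste0("unknown boundary kind: ", paste(bad_kind, collapse = ", ")))
  }
  unknown <- setdiff(boundary$node_id, nodes$id)
  if (length(unknown)) {
    abort(paste0("boundary conditions reference unknown nodes: ",
                 paste(unknown, collapse = ", ")))
  }
  non_b <- setdiff(boundary$node_id, nodes$id[nodes$is_boundary])
  if (length(non_b)) {
    abort(paste0("boundary conditions at non-boundary (degree != 1) nodes: ",
                 paste(non_b, collapse = ", ")))
  }
  if (anyDuplicated(boundary$node_id)) {
    abort("multiple boundary conditions for one node")
  }
  has_p <- is.finite(boundary$pressure)
  has_q <- is.finite(boundary$flow)
  if (any(has_p == has_q)) {
    bad <- boundary$node_id[has_p == has_q]
    abort(paste0("exactly one of pressure/flow must be given at nodes: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(has_p & boundary$kind != "pressure") ||
      any(has_q & boundary$kind == "pressure")) {
    abort("boundary `kind` inconsistent with supplied values")
  }
  need_hd <- boundary$kind == "flow_hematocrit" & boundary$flow > 0
  if (any(need_hd & !is.finite(boundary$hd))) {
    abort("inflow nodes of kind flow_hematocrit require `hd`")
  }
  if (any(is.finite(boundary$hd) & (boundary$hd < 0 | boundary$hd > 1))) {
    abort("boundary hematocrit must lie in [0, 1]")
  }
  boundary
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network>\n")
  cat("  nodes:    ", nrow(x$nodes),
      " (", sum(x$nodes$is_boundary), " boundary)\n", sep = "")
  cat("  segments: ", nrow(x$segments),
      ", total length ", format(sum(x$segments$length), digits = 6), " um\n",
      sep = "")
  if (nrow(x$boundary)) {
    cat("  boundary conditions:", nrow(x$boundary), "\n")
  }
  if (is.finite(x$volume)) cat("  volume:", x$volume, "mm^3\n")
  invisible(x)
}

#' Structural diagnostics for a vascular network
#'
#' Reporting-only quality checks: connected components, boundary-node count,
#' degree histogram, duplicate (parallel) segments, degenerate geometry.
#' Never mutates or repairs the input.
#'
#' @param net A [vascular_network()].
#' @return A tibble with one row per check: `check`, `value` (numeric),
#'   `ok` (logical), `detail`. The underlying degree histogram is attached as
#'   attribute `"degree_histogram"`.
#' @examples
#' validate_network(make_line(n_segments = 3))
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  nodes <- net$nodes
  segs <- net$segments
  deg <- node_degrees(nodes$id, segs)

  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(segs$node_i), to = as.character(segs$node_j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id))
  )
  comp <- igraph::components(g)

  dup <- duplicated(cbind(pmin(segs$node_i, segs$node_j),
                          pmax(segs$node_i, segs$node_j)))
  chord <- segment_chord_lengths(nodes, segs)

  hist_tab <- table(deg)
  checks <- tibble(
    check = c("components", "isolated_nodes", "boundary_nodes",
              "parallel_segments", "zero_length_segments",
              "zero_diameter_segments", "length_below_chord",
              "boundary_conditions"),
    value = c(comp$no, sum(deg == 0L), sum(deg == 1L), sum(dup),
              sum(segs$length <= 0), sum(segs$diameter <= 0),
              sum(segs$length < chord * (1 - 1e-9) - 1e-9),
              nrow(net$boundary)),
    ok = c(comp$no == 1L, sum(deg == 0L) == 0L, sum(deg == 1L) >= 2L,
           TRUE, sum(segs$length <= 0) == 0L, sum(segs$diameter <= 0) == 0L,
           sum(segs$length < chord * (1 - 1e-9) - 1e-9) == 0L, TRUE),
    detail = c(
      if (comp$no > 1L) paste0("component sizes: ",
                               paste(comp$csize, collapse = ", ")) else "",
      "", "degree-1 nodes",
      "parallel segments are allowed; count reported",
      "", "", "",
      ""
    )
  )
  attr(checks, "degree_histogram") <-
    tibble(degree = as.integer(names(hist_tab)), n = as.integer(hist_tab))
  checks
}
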