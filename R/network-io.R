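#' Read a vascular network from disk
#'
#' Two self-describing plain-text layouts are supported, plus an Amira
#' SpatialGraph ASCII import:
#'
#' * `format = "csv"`: `path` is a directory holding `nodes.csv`
#'   (`id,x,y,z`; um), `segments.csv`
#'   (`id,node_i,node_j,diameter_um,length_um`) and optionally `boundary.csv`
#'   (`node_id,kind,pressure_mmHg,flow_ul_s,hd` with `kind` one of
#'   `pressure`, `flow`, `flow_hematocrit`).
#' * `format = "json"`: a single JSON file with fields `nodes`, `segments`,
#'   `boundary`, `volume_mm3` (as written by [write_network()]).
#' * `format = "amira_spatialgraph"`: Amira/HyperSurface ASCII SpatialGraph;
#'   segment length is the polyline arc length over `EdgePointCoordinates`
#'   and diameter is twice the mean point `thickness` (radius).
#'
#' All coordinates are voxel-center world coordinates in um, axis order
#' (x, y, z); flow is ul/s with inflow positive.
#'
#' @param path Directory (csv) or file (json, amira).
#' @param format One of `"csv"`, `"json"`, `"amira_spatialgraph"`; default
#'   guessed from `path`.
#' @return A validated [vascular_network()].
#' @export
read_network <- function(path, format = c("csv", "json", "amira_spatialgraph")) {
  if (length(format) > 1 || missing(format)) {
    format <- if (dir.exists(path)) "csv"
              else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else if (grepl("\\.am$", path, ignore.case = TRUE)) "amira_spatialgraph"
              else match.arg(format)
  }
  format <- match.arg(format)
  switch(format,
    csv = read_network_csv(path),
    json = read_network_json(path),
    amira_spatialgraph = read_amira_spatialgraph(path)
  )
}

read_network_csv <- function(path) {
  if (!dir.exists(path)) abort(paste0("network directory not found: ", path))
  nf <- file.path(path, "nodes.csv")
  sf <- file.path(path, "segments.csv")
  bf <- file.path(path, "boundary.csv")
  for (f in c(nf, sf)) if (!file.exists(f)) abort(paste0("missing file: ", f))
  # base read.csv parses doubles with strtod (correctly rounded), so a
  # write -> read -> write cycle is byte-stable
  nodes <- utils::read.csv(nf)
  segs <- utils::read.csv(sf)
  need_s <- c("id", "node_i", "node_j", "diameter_um", "length_um")
  if (!all(need_s %in% names(segs))) {
    abort(paste0("segments.csv must have columns ",
                 paste(need_s, collapse = ", ")))
  }
  segs <- rename(segs, diameter = "diameter_um", length = "length_um")
  boundary <- NULL
  if (file.exists(bf)) {
    b <- utils::read.csv(bf)
    if (nrow(b)) {
      boundary <- tibble(node_id = b$node_id, kind = b$kind,
                         pressure = b$pressure_mmHg, flow = b$flow_ul_s,
                         hd = b$hd)
    }
  }
  vol <- NA_real_
  mf <- file.path(path, "meta.json")
  if (file.exists(mf)) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    vol <- as.numeric(meta$volume_mm3 %||% NA_real_)
  }
  vascular_network(nodes, segs, boundary, volume = vol)
}

#' Write a vascular network to disk
#'
#' Inverse of [read_network()] for the `"csv"` and `"json"` layouts.
#' Numeric fields are written at full double precision so a
#' read/write/read round trip is an identity.
#'
#' @param net A [vascular_network()].
#' @param path Target directory (csv) or file (json).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "json")) {
  stopifnot(inherits(net, "vascular_network"))
  format <- match.arg(format)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(select(net$nodes, "id", "x", "y", "z"),
                     file.path(path, "nodes.csv"))
    segs <- select(net$segments, "id", "node_i", "node_j",
                   diameter_um = "diameter", length_um = "length")
    readr::write_csv(segs, file.path(path, "segments.csv"))
    if (nrow(net$boundary)) {
      b <- select(net$boundary, "node_id", "kind",
                  pressure_mmHg = "pressure", flow_ul_s = "flow", "hd")
      readr::write_csv(b, file.path(path, "boundary.csv"))
    }
    if (is.finite(net$volume)) {
      jsonlite::write_json(list(volume_mm3 = net$volume),
                           file.path(path, "meta.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  } else {
    obj <- list(
      nodes = select(net$nodes, "id", "x", "y", "z"),
      segments = net$segments,
      boundary = net$boundary,
      volume_mm3 = if (is.finite(net$volume)) net$volume else NULL
    )
    jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

read_network_json <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundary <- obj$boundary
  if (!is.null(boundary) && NROW(boundary) == 0) boundary <- NULL
  vascular_network(as.data.frame(obj$nodes), as.data.frame(obj$segments),
                   boundary,
                   volume = as.numeric(obj$volume_mm3 %||% NA_real_))
}

#' Read an Amira SpatialGraph ASCII file
#'
#' Parses the `VERTEX`/`EDGE`/`POINT` declarations and the
#' `VertexCoordinates`, `EdgeConnectivity`, `NumEdgePoints`,
#' `EdgePointCoordinates` and `thickness` (point radius) data sections of an
#' Amira SpatialGraph saved in ASCII format. Each edge becomes one segment:
#' length is the arc length of its point polyline and diameter twice the mean
#' thickness of its points.
#'
#' @param path File path.
#' @return A [vascular_network()].
#' @export
read_amira_spatialgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  get_count <- function(kind) {
    m <- grep(paste0("^\\s*define\\s+", kind, "\\s+[0-9]+"), lines, value = TRUE)
    if (!length(m)) abort(paste0("Amira parse error: missing 'define ", kind, "'"))
    as.integer(sub(paste0(".*define\\s+", kind, "\\s+([0-9]+).*"), "\\1", m[1]))
  }
  nv <- get_count("VERTEX")
  ne <- get_count("EDGE")
  np <- get_count("POINT")

  # Map data labels (VertexCoordinates, EdgeConnectivity, ...) to @k markers.
  decl <- grep("@[0-9]+\\s*$", lines)
  decl <- decl[!grepl("^\\s*@[0-9]+\\s*$", lines[decl])]
  labels <- list()
  for (i in decl) {
    mark <- sub(".*(@[0-9]+)\\s*$", "\\1", lines[i])
    lab <- if (grepl("VertexCoordinates", lines[i])) "vertex"
      else if (grepl("EdgeConnectivity", lines[i])) "edge"
      else if (grepl("NumEdgePoints", lines[i])) "nep"
      else if (grepl("EdgePointCoordinates", lines[i])) "points"
      else if (grepl("thickness|Radius", lines[i], ignore.case = TRUE)) "thickness"
      else NA_character_
    if (!is.na(lab) && is.null(labels[[lab]])) labels[[lab]] <- mark
  }
  for (lab in c("vertex", "edge", "nep", "points", "thickness")) {
    if (is.null(labels[[lab]])) {
      abort(paste0("Amira parse error: no data section for '", lab, "'"))
    }
  }
  read_block <- function(mark, n_values) {
    start <- grep(paste0("^\\s*", mark, "\\s*$"), lines)
    if (!length(start)) abort(paste0("Amira parse error: data block ", mark,
                                     " not found"))
    out <- numeric(0)
    i <- start[length(start)] + 1L
    while (length(out) < n_values && i <= length(lines)) {
      ln <- trimws(lines[i])
      if (grepl("^@[0-9]+", ln)) break
      if (nzchar(ln)) {
        out <- c(out, as.numeric(strsplit(ln, "\\s+")[[1]]))
      }
      i <- i + 1L
    }
    if (length(out) < n_values) {
      abort(paste0("Amira parse error: block ", mark, " has ", length(out),
                   " values, expected ", n_values))
    }
    out[seq_len(n_values)]
  }

  vc <- matrix(read_block(labels$vertex, 3L * nv), ncol = 3, byrow = TRUE)
  ec <- matrix(as.integer(read_block(labels$edge, 2L * ne)), ncol = 2,
               byrow = TRUE) + 1L  # 0-based in file
  nep <- as.integer(read_block(labels$nep, ne))
  pc <- matrix(read_block(labels$points, 3L * np), ncol = 3, byrow = TRUE)
  th <- read_block(labels$thickness, np)

  offs <- cumsum(c(0L, nep))
  seg_len <- numeric(ne)
  seg_d <- numeric(ne)
  for (e in seq_len(ne)) {
    idx <- (offs[e] + 1L):(offs[e] + nep[e])
    pts <- pc[idx, , drop = FALSE]
    if (nrow(pts) >= 2) {
      d <- diff(pts)
      seg_len[e] <- sum(sqrt(rowSums(d^2)))
    } else {
      seg_len[e] <- 0
    }
    seg_d[e] <- 2 * mean(th[idx])
  }
  nodes <- tibble(id = seq_len(nv), x = vc[, 1], y = vc[, 2], z = vc[, 3])
  segs <- tibble(id = seq_len(ne), node_i = ec[, 1], node_j = ec[, 2],
                 diameter = seg_d, length = seg_len)
  vascular_network(nodes, segs)
}

#' Export per-segment attributes alongside the network geometry
#'
#' Writes simulated per-segment quantities (flow, hematocrit, oxygen, class
#' labels, ...) either as a flat CSV keyed by segment id or as a VTK legacy
#' polydata file with one polyline cell per segment and one `CELL_DATA`
#' scalar array per attribute column — the input for color-coded 3D
#' renderings.
#'
#' @param net A [vascular_network()].
#' @param attributes Data frame keyed by segment `id` with one row per
#'   segment and numeric attribute columns.
#' @param path Output file.
#' @param format `"csv"` or `"vtk_polyline"`.
#' @return `path`, invisibly. Non-finite attribute values are written
#'   verbatim with a warning.
#' @export
write_vessel_attributes <- function(net, attributes, path,
                                    format = c("csv", "vtk_polyline")) {
  stopifnot(inherits(net, "vascular_network"))
  format <- match.arg(format)
  attributes <- as_tibble(as.data.frame(attributes))
  if (!"id" %in% names(attributes)) abort("`attributes` must have an `id` column")
  missing_ids <- setdiff(net$segments$id, attributes$id)
  if (length(missing_ids)) {
    abort(paste0("attributes missing for segment ids: ",
                 paste(sort(missing_ids), collapse = ", ")))
  }
  attributes <- attributes[match(net$segments$id, attributes$id), ]
  vals <- attributes[setdiff(names(attributes), "id")]
  if (any(!vapply(vals, is.numeric, logical(1)))) {
    abort("attribute columns must be numeric")
  }
  if (any(!is.finite(as.matrix(vals)))) {
    warn("non-finite attribute values written verbatim")
  }

  if (format == "csv") {
    readr::write_csv(attributes, path)
    return(invisible(path))
  }

  nodes <- net$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vascular network attributes", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(nodes), "double")), con)
  writeLines(paste(nodes$x, nodes$y, nodes$z), con)
  i0 <- match(net$segments$node_i, nodes$id) - 1L
  j0 <- match(net$segments$node_j, nodes$id) - 1L
  ns <- nrow(net$segments)
  writeLines(paste("LINES", ns, 3L * ns), con)
  writeLines(paste(2L, i0, j0), con)
  writeLines(paste("CELL_DATA", ns), con)
  for (nm in names(vals)) {
    writeLines(c(paste("SCALARS", nm, "double", 1),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(vals[[nm]], digits = 17, trim = TRUE, scientific = FALSE),
               con)
  }
  invisible(path)
}
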