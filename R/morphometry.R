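#' Voxel grid container
#'
#' A scalar field sampled on a regular 3D grid: a numeric (or logical) 3D
#' array plus the world position of the first voxel center (`origin`, um)
#' and the per-axis voxel pitch (`spacing`, um). Axis order is (x, y, z),
#' coordinates are voxel-center world coordinates.
#'
#' @param values 3D array.
#' @param origin Numeric 3-vector, um: world position of voxel `[1, 1, 1]`.
#' @param spacing Numeric (scalar or 3-vector), um per voxel along each axis.
#' @return An object of class `voxel_grid` (the array with attributes).
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), spacing = 8) {
  stopifnot(length(dim(values)) == 3, all(spacing > 0), all(dim(values) >= 1))
  spacing <- rep_len(as.numeric(spacing), 3)
  structure(values, origin = as.numeric(rep_len(origin, 3)),
            spacing = spacing, class = c("voxel_grid", class(values)))
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s um, origin (%s) um\n",
              d[1], d[2], d[3],
              paste(attr(x, "spacing"), collapse = " x "),
              paste(format(attr(x, "origin")), collapse = ", ")))
  rng <- suppressWarnings(range(x, na.rm = TRUE))
  if (all(is.finite(rng))) cat("  values in [",
                               format(rng[1]), ", ", format(rng[2]), "]\n",
                               sep = "")
  invisible(x)
}

grid_geometry <- function(net, spacing, margin) {
  nodes <- net$nodes
  r <- max(net$segments$diameter) / 2
  lo <- c(min(nodes$x), min(nodes$y), min(nodes$z)) - r - margin
  hi <- c(max(nodes$x), max(nodes$y), max(nodes$z)) + r + margin
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)), 1L)
  # center the voxel lattice on the bounding box (symmetric margins)
  ctr <- (lo + hi) / 2
  origin <- ctr - (dims - 1) / 2 * spacing
  list(lo = origin - spacing / 2, dims = dims, origin = origin)
}

#' Rasterize a network into a binary vessel mask
#'
#' A voxel is a vessel voxel iff its center lies within `diameter/2` of a
#' segment's centerline chord (vessels as straight cylinders with spherical
#' caps at the endpoints).
#'
#' @param net A [vascular_network()].
#' @param spacing Voxel pitch in um (default 8, isotropic).
#' @param margin Extra padding around the network bounding box, um.
#' @return A logical [voxel_grid()].
#' @export
rasterize_network <- function(net, spacing = 8, margin = spacing) {
  stopifnot(inherits(net, "vascular_network"), spacing > 0)
  if (!nrow(net$segments)) {
    warn("network has no segments; returning an empty grid")
    return(voxel_grid(array(FALSE, c(1, 1, 1)), spacing = spacing))
  }
  geo <- grid_geometry(net, spacing, margin)
  dims <- geo$dims
  mask <- array(FALSE, dims)
  nodes <- net$nodes
  ax <- list(geo$origin[1] + (seq_len(dims[1]) - 1) * spacing,
             geo$origin[2] + (seq_len(dims[2]) - 1) * spacing,
             geo$origin[3] + (seq_len(dims[3]) - 1) * spacing)
  for (s in seq_len(nrow(net$segments))) {
    a <- unlist(nodes[match(net$segments$node_i[s], nodes$id), c("x", "y", "z")])
    b <- unlist(nodes[match(net$segments$node_j[s], nodes$id), c("x", "y", "z")])
    r <- net$segments$diameter[s] / 2
    lo <- pmin(a, b) - r
    hi <- pmax(a, b) + r
    ir <- lapply(1:3, function(k) which(ax[[k]] >= lo[k] & ax[[k]] <= hi[k]))
    if (any(!lengths(ir))) next
    pts <- as.matrix(expand.grid(x = ax[[1]][ir[[1]]], y = ax[[2]][ir[[2]]],
                                 z = ax[[3]][ir[[3]]]))
    v <- b - a
    vv <- sum(v^2)
    t <- if (vv > 0) {
      pmin(pmax(((pts[, 1] - a[1]) * v[1] + (pts[, 2] - a[2]) * v[2] +
                   (pts[, 3] - a[3]) * v[3]) / vv, 0), 1)
    } else {
      rep(0, nrow(pts))
    }
    dx <- pts[, 1] - (a[1] + t * v[1])
    dy <- pts[, 2] - (a[2] + t * v[2])
    dz <- pts[, 3] - (a[3] + t * v[3])
    inside <- dx * dx + dy * dy + dz * dz <= r * r
    if (any(inside)) {
      sub <- as.matrix(expand.grid(ir[[1]], ir[[2]], ir[[3]]))[inside, ,
                                                               drop = FALSE]
      mask[sub] <- TRUE
    }
  }
  voxel_grid(mask, origin = geo$origin, spacing = spacing)
}

#' Distance-to-nearest-vessel map
#'
#' Exact 3D Euclidean distance (um) from every voxel center to the nearest
#' vessel voxel center; zero on vessel voxels.
#'
#' @param mask A logical [voxel_grid()] as produced by
#'   [rasterize_network()].
#' @return A numeric [voxel_grid()] of distances in um.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"))
  if (!any(mask)) abort("distance map undefined: no vessel voxel in mask")
  d <- .edt3d(as.logical(mask), dim(mask), attr(mask, "spacing"))
  voxel_grid(d, origin = attr(mask, "origin"),
             spacing = attr(mask, "spacing"))
}

block_sum <- function(a, k) {
  d <- dim(a)
  stopifnot(all(d %% k == 0))
  n <- d %/% k
  b <- array(a, c(k, n[1], k, n[2], k, n[3]))
  apply(b, c(2, 4, 6), sum)
}

#' Vascular length- and surface-density maps
#'
#' Every centerline voxel is assigned its segment's share of length (and of
#' lateral cylinder surface `pi D L`), by supersampling each centerline at a
#' quarter of the voxel pitch. The fine grid is then reduced with a
#' `kernel^3` box window (default 20, i.e. 160 um regions at 8 um pitch),
#' normalized by the in-bounds window volume, yielding the vascular length
#' density `L_v` (mm/mm^3) and surface-area density `S_v` (mm^2/mm^3).
#' Length and surface are conserved exactly: summing density times window
#' volume recovers the network totals.
#'
#' @param net A [vascular_network()].
#' @param spacing Fine-grid voxel pitch, um (default 8).
#' @param kernel Box-window width in fine voxels (default 20).
#' @return List with [voxel_grid()]s `l_v` and `s_v` on the coarse grid,
#'   and the fine per-voxel `length_um` grid.
#' @export
density_maps <- function(net, spacing = 8, kernel = 20L) {
  stopifnot(inherits(net, "vascular_network"), spacing > 0, kernel >= 1)
  kernel <- as.integer(kernel)
  geo <- grid_geometry(net, spacing, margin = spacing)
  dims0 <- geo$dims
  dims <- as.integer(ceiling(dims0 / kernel) * kernel)  # pad for blocks
  lo <- geo$lo

  len <- array(0, dims)
  surf <- array(0, dims)
  nodes <- net$nodes
  step <- spacing / 4
  for (s in seq_len(nrow(net$segments))) {
    a <- unlist(nodes[match(net$segments$node_i[s], nodes$id), c("x", "y", "z")])
    b <- unlist(nodes[match(net$segments$node_j[s], nodes$id), c("x", "y", "z")])
    chord <- sqrt(sum((b - a)^2))
    n_pts <- max(2L, ceiling(chord / step))
    t <- (seq_len(n_pts) - 0.5) / n_pts
    px <- a[1] + t * (b[1] - a[1])
    py <- a[2] + t * (b[2] - a[2])
    pz <- a[3] + t * (b[3] - a[3])
    ix <- pmin(pmax(floor((px - lo[1]) / spacing) + 1, 1), dims[1])
    iy <- pmin(pmax(floor((py - lo[2]) / spacing) + 1, 1), dims[2])
    iz <- pmin(pmax(floor((pz - lo[3]) / spacing) + 1, 1), dims[3])
    lin <- ix + dims[1] * (iy - 1 + dims[2] * (iz - 1))
    wl <- net$segments$length[s] / n_pts
    ws <- pi * net$segments$diameter[s] * net$segments$length[s] / n_pts
    add <- rowsum(cbind(rep(wl, n_pts), rep(ws, n_pts)), lin)
    at <- as.integer(rownames(add))
    len[at] <- len[at] + add[, 1]
    surf[at] <- surf[at] + add[, 2]
  }

  inb <- array(0, dims)
  inb[seq_len(dims0[1]), seq_len(dims0[2]), seq_len(dims0[3])] <- 1
  vol_blk <- block_sum(inb, kernel) * spacing^3        # in-bounds um^3
  len_blk <- block_sum(len, kernel)
  surf_blk <- block_sum(surf, kernel)
  lv <- ifelse(vol_blk > 0, len_blk / vol_blk * 1e6, 0)    # mm/mm^3
  sv <- ifelse(vol_blk > 0, surf_blk / vol_blk * 1e3, 0)   # mm^2/mm^3

  coarse_sp <- spacing * kernel
  coarse_origin <- lo + coarse_sp / 2
  list(
    l_v = voxel_grid(lv, origin = coarse_origin, spacing = coarse_sp),
    s_v = voxel_grid(sv, origin = coarse_origin, spacing = coarse_sp),
    length_um = voxel_grid(len, origin = lo + spacing / 2, spacing = spacing),
    window_volume_um3 = vol_blk
  )
}

#' Morphometry maps for a network
#'
#' Convenience wrapper computing the binary vessel mask, the
#' distance-to-nearest-vessel map `D_v` on the fine grid and the density
#' maps `L_v`/`S_v` on the coarse grid, plus the vascular volume density
#' `sum(pi D^2/4 L) / Vol` when the network carries a tumor volume.
#'
#' @inheritParams density_maps
#' @return An object of class `morphometry_maps`: list with `d_v`, `l_v`,
#'   `s_v`, `mask`, `volume_density`.
#' @export
morphometry_maps <- function(net, spacing = 8, kernel = 20L) {
  mask <- rasterize_network(net, spacing = spacing)
  dv <- distance_map(mask)
  dens <- density_maps(net, spacing = spacing, kernel = kernel)
  vd <- vascular_volume_density(net)
  structure(list(d_v = dv, l_v = dens$l_v, s_v = dens$s_v, mask = mask,
                 length_um = dens$length_um,
                 window_volume_um3 = dens$window_volume_um3,
                 volume_density = vd),
            class = "morphometry_maps")
}

vascular_volume_density <- function(net) {
  if (!is.finite(net$volume)) return(NA_real_)
  vasc_um3 <- sum(pi * net$segments$diameter^2 / 4 * net$segments$length)
  vasc_um3 / (net$volume * 1e9)
}

#' @export
print.morphometry_maps <- function(x, ...) {
  cat("<morphometry_maps>\n  D_v: ")
  print(x$d_v)
  cat("  L_v: ")
  print(x$l_v)
  if (is.finite(x$volume_density)) {
    cat(sprintf("  vascular volume density: %.4g\n", x$volume_density))
  }
  invisible(x)
}

#' Scalar morphology statistics
#'
#' Per-network distributional summaries (n, median, mean, sd, CV) of
#' segment diameter and length and, when maps are supplied, of the `D_v`,
#' `L_v` and `S_v` voxel distributions, plus the vascular volume density
#' as a final row (NA spread). Volume density is omitted with a warning if
#' the network has no tumor volume.
#'
#' @param net A [vascular_network()].
#' @param maps Optional [morphometry_maps()] result.
#' @return A tibble `parameter`, `unit`, `n`, `median`, `mean`, `sd`, `cv`.
#' @export
morphology_summary <- function(net, maps = NULL) {
  stopifnot(inherits(net, "vascular_network"))
  row <- function(name, unit, x) {
    x <- x[is.finite(x)]
    tibble(parameter = name, unit = unit, n = length(x),
           median = median(x), mean = mean(x), sd = sd(x),
           cv = sd(x) / mean(x))
  }
  out <- bind_rows(
    row("diameter", "um", net$segments$diameter),
    row("length", "um", net$segments$length)
  )
  if (!is.null(maps)) {
    out <- bind_rows(
      out,
      row("d_v", "um", as.numeric(maps$d_v)),
      row("l_v", "mm/mm^3", as.numeric(maps$l_v)),
      row("s_v", "mm^2/mm^3", as.numeric(maps$s_v))
    )
  }
  vd <- vascular_volume_density(net)
  if (is.na(vd)) {
    warn("network has no tumor volume; volume density omitted")
  } else {
    out <- bind_rows(out, tibble(parameter = "volume_density", unit = "",
                                 n = NA_integer_, median = vd, mean = vd,
                                 sd = NA_real_, cv = NA_real_))
  }
  out
}

#' Write morphometry maps to volumetric files
#'
#' Exports each map as NIfTI (voxel spacing in the header, values in native
#' units; requires the RNifti package) and/or multipage TIFF (requires the
#' tiff package). TIFF is a visualization export: values are scaled to
#' `[0, 1]` by the map maximum, which is recorded in a `*_scale.txt`
#' sidecar; the NIfTI files carry the quantitative values.
#'
#' @param maps A [morphometry_maps()] result.
#' @param dir Output directory.
#' @param formats Subset of `c("nifti", "tiff")`.
#' @return Tibble of written files, invisibly.
#' @export
write_morphometry <- function(maps, dir, formats = c("nifti", "tiff")) {
  stopifnot(inherits(maps, "morphometry_maps"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in c("d_v", "l_v", "s_v")) {
    g <- maps[[nm]]
    vals <- array(as.numeric(g), dim(g))
    vals[is.na(vals)] <- 0
    if ("nifti" %in% formats) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        warn("RNifti not installed; skipping NIfTI export")
      } else {
        f <- file.path(dir, paste0(nm, ".nii"))
        img <- RNifti::asNifti(vals)
        RNifti::pixdim(img) <- attr(g, "spacing") / 1000  # um -> mm
        RNifti::writeNifti(img, f)
        written <- c(written, f)
      }
    }
    if ("tiff" %in% formats) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        warn("tiff not installed; skipping TIFF export")
      } else {
        f <- file.path(dir, paste0(nm, ".tif"))
        mx <- max(vals, 1e-300)
        pages <- lapply(seq_len(dim(vals)[3]), function(z) {
          matrix(vals[, , z] / mx, nrow = dim(vals)[1])
        })
        tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
        writeLines(format(mx), file.path(dir, paste0(nm, "_scale.txt")))
        written <- c(written, f)
      }
    }
  }
  invisible(tibble(file = written))
}
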