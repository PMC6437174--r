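test_that("minimal CSV network reads with both endpoints as boundary nodes", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(id = 1:2, x = c(0, 100), y = 0, z = 0),
                   file.path(dir, "nodes.csv"))
  readr::write_csv(tibble::tibble(id = 1, node_i = 1, node_j = 2,
                                  diameter_um = 10, length_um = 100),
                   file.path(dir, "segments.csv"))
  net <- read_network(dir)
  expect_s3_class(net, "vascular_network")
  expect_equal(nrow(net$segments), 1)
  expect_true(all(net$nodes$is_boundary))
})

test_that("CSV and JSON round trips reproduce the network exactly", {
  net <- make_tumor_like(n_segments = 60, radius = 200, seed = 11)
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "csvnet"), format = "csv")
  back <- read_network(file.path(dir, "csvnet"))
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$segments, net$segments)
  expect_equal(back$boundary, net$boundary)
  expect_equal(back$volume, net$volume)

  jf <- file.path(dir, "net.json")
  write_network(net, jf, format = "json")
  back2 <- read_network(jf)
  expect_equal(back2$segments, net$segments)
  expect_equal(back2$boundary, net$boundary)

  # write -> read -> write is byte-stable
  write_network(back, file.path(dir, "csvnet2"), format = "csv")
  for (f in c("nodes.csv", "segments.csv", "boundary.csv")) {
    expect_identical(readLines(file.path(dir, "csvnet", f)),
                     readLines(file.path(dir, "csvnet2", f)))
  }
})

test_that("constructor rejects structural violations", {
  nodes <- data.frame(id = 1:3, x = c(0, 100, 200), y = 0, z = 0)
  seg <- function(node_i, node_j, diameter = 10, ...) {
    data.frame(id = 1, node_i = node_i, node_j = node_j,
               diameter = diameter, ...)
  }
  expect_error(vascular_network(nodes, seg(node_i = 1, node_j = 1)),
               "self-loop")
  expect_error(vascular_network(nodes, seg(node_i = 1, node_j = 9)),
               "unknown nodes")
  expect_error(vascular_network(nodes, seg(node_i = 1, node_j = 2,
                                           length = 50)),
               "below endpoint distance")
  expect_error(vascular_network(nodes, seg(node_i = 1, node_j = 2,
                                           diameter = -1)),
               "positive")
  # boundary condition on an interior (degree-2) node
  segs2 <- data.frame(id = 1:2, node_i = 1:2, node_j = 2:3, diameter = 10)
  expect_error(
    vascular_network(nodes, segs2,
                     data.frame(node_id = 2, kind = "pressure",
                                pressure = 10, flow = NA, hd = NA)),
    "non-boundary")
  expect_error(
    vascular_network(nodes, segs2,
                     data.frame(node_id = 1, kind = "pressure",
                                pressure = 10, flow = 1, hd = NA)),
    "exactly one")
})

test_that("curved centerlines are allowed, shorter-than-chord is not", {
  nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0)
  net <- vascular_network(nodes, data.frame(id = 1, node_i = 1, node_j = 2,
                                            diameter = 8, length = 140))
  expect_equal(net$segments$length, 140)
})

test_that("validation reports components, boundary counts and degrees", {
  v <- validate_network(make_line())
  expect_equal(v$value[v$check == "components"], 1)
  expect_equal(v$value[v$check == "boundary_nodes"], 2)

  # isolated node -> two components
  nodes <- data.frame(id = 1:3, x = c(0, 100, 500), y = 0, z = 0)
  segs <- data.frame(id = 1, node_i = 1, node_j = 2, diameter = 10)
  net <- vascular_network(nodes, segs)
  v2 <- validate_network(net)
  expect_equal(v2$value[v2$check == "components"], 2)
  expect_false(v2$ok[v2$check == "components"])
  expect_equal(v2$value[v2$check == "isolated_nodes"], 1)

  # bifurcation tree of depth 3: leaves + root = 2^3 + 1 boundary nodes
  v3 <- validate_network(make_bifurcation_tree(depth = 3))
  expect_equal(v3$value[v3$check == "boundary_nodes"], 9)
})

test_that("generator outputs validate cleanly", {
  for (seed in 1:3) {
    net <- make_tumor_like(n_segments = 80, radius = 250, seed = seed)
    v <- validate_network(net)
    expect_true(all(v$ok), info = paste("seed", seed))
  }
  expect_true(all(validate_network(make_bifurcation_tree(depth = 2))$ok))
  expect_true(all(validate_network(make_line(n_segments = 4))$ok))
})

test_that("Amira SpatialGraph import uses polyline arc length and mean thickness", {
  # 2 vertices, 1 edge with a 3-point polyline bent at right angles:
  # (0,0,0) -> (30,40,0) -> (30,40,120); arc = 50 + 120 = 170, chord < arc
  f <- withr::local_tempfile(fileext = ".am")
  writeLines(c(
    "# AmiraMesh 3D ASCII 2.0",
    "define VERTEX 2",
    "define EDGE 1",
    "define POINT 3",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "POINT { float thickness } @5",
    "@1",
    "0 0 0",
    "30 40 120",
    "@2",
    "0 1",
    "@3",
    "3",
    "@4",
    "0 0 0",
    "30 40 0",
    "30 40 120",
    "@5",
    "4 5 6"
  ), f)
  net <- read_network(f, format = "amira_spatialgraph")
  expect_equal(nrow(net$segments), 1)
  expect_equal(net$segments$length, 170)                  # 50 + 120
  expect_equal(net$segments$diameter, 2 * mean(c(4, 5, 6)))
  chord <- sqrt(30^2 + 40^2 + 120^2)
  expect_gte(net$segments$length, chord)
})

test_that("attribute export writes VTK polylines and round-trips CSV", {
  net <- make_line()
  attrs <- tibble::tibble(id = 1, flow = 0.5)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vessel_attributes(net, attrs, f, format = "vtk_polyline")
  lines <- readLines(f)
  expect_true(any(grepl("^LINES 1 3$", lines)))
  expect_true(any(grepl("^SCALARS flow double 1$", lines)))
  expect_true(any(grepl("^CELL_DATA 1$", lines)))

  fc <- withr::local_tempfile(fileext = ".csv")
  write_vessel_attributes(net, attrs, fc, format = "csv")
  back <- readr::read_csv(fc, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(attrs))

  expect_warning(
    write_vessel_attributes(net, tibble::tibble(id = 1, q = NaN), fc),
    "non-finite")
  expect_error(
    write_vessel_attributes(net, tibble::tibble(id = 99, q = 1), fc),
    "missing for segment ids")
})
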