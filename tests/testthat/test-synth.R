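test_that("line generator produces the expected chain", {
  net <- make_line(n_segments = 1)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$segments), 1)

  net5 <- make_line(n_segments = 5, length = 80)
  expect_equal(nrow(net5$nodes), 6)
  expect_equal(nrow(net5$segments), 5)
  expect_equal(sum(net5$segments$length), 5 * 80)
  deg <- table(c(net5$segments$node_i, net5$segments$node_j))
  expect_equal(sort(unique(as.integer(deg))), c(1L, 2L))
  expect_equal(sum(deg == 2L), 4)   # interior nodes
})

test_that("bifurcation tree counts follow the construction", {
  t1 <- make_bifurcation_tree(depth = 1)
  expect_equal(nrow(t1$segments), 3)
  expect_equal(nrow(t1$nodes), 4)

  t3 <- make_bifurcation_tree(depth = 3)
  expect_equal(sum(t3$nodes$is_boundary), 9)       # 2^3 leaves + root
  expect_equal(nrow(t3$segments), 15)
})

test_that("symmetric leaf pressures split flow symmetrically at every fork", {
  net <- make_bifurcation_tree(depth = 3, p_root = 30, p_leaf = 10)
  sol <- solve_pressures(net, viscosity = 2)
  q <- abs(sol$flows$flow)
  # generations: segment 1 root; 2-3; 4-7; 8-15
  expect_equal(q[2], q[3], tolerance = 1e-12)
  expect_equal(max(abs(q[4:7] - q[4])), 0, tolerance = 1e-12)
  expect_equal(max(abs(q[8:15] - q[8])), 0, tolerance = 1e-12)
  expect_equal(q[1], q[2] + q[3], tolerance = 1e-10)
})

test_that("tumor-like generator is deterministic and reproducible on disk", {
  a <- make_tumor_like(n_segments = 100, radius = 250, seed = 42)
  b <- make_tumor_like(n_segments = 100, radius = 250, seed = 42)
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$segments, b$segments)
  expect_equal(a$boundary, b$boundary)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_network(a, d1); write_network(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  c_ <- make_tumor_like(n_segments = 100, radius = 250, seed = 43)
  expect_false(isTRUE(all.equal(a$nodes, c_$nodes)))
})

test_that("tumor-like networks hit the requested composition", {
  net <- make_tumor_like(n_segments = 150, radius = 300, n_boundary = 6,
                         seed = 3)
  expect_equal(nrow(net$segments), 150)
  expect_equal(sum(net$nodes$is_boundary), 6)
  expect_true(all(validate_network(net)$ok))
  expect_equal(net$volume, 4 / 3 * pi * 0.3^3, tolerance = 1e-12)
  # solvable out of the box
  st <- simulate_hemodynamics(net)
  expect_true(st$converged)
  expect_error(make_tumor_like(n_segments = 10, n_boundary = 8, seed = 1),
               "unreachable")
})

test_that("diameters are positively skewed for lognormal sigma 0.5", {
  net <- make_tumor_like(n_segments = 400, radius = 400,
                         diameter_sigma = 0.5, seed = 9)
  d <- net$segments$diameter
  skew <- mean((d - mean(d))^3) / sd(d)^3
  expect_gt(skew, 0)
})

test_that("rim length density exceeds core length density in most seeds", {
  # direct geometric attribution of segment length by midpoint radius
  frac_hit <- mean(vapply(1:25, function(seed) {
    net <- make_tumor_like(n_segments = 120, radius = 300,
                           rim_core_ratio = 3, seed = seed)
    nodes <- net$nodes
    mid_r <- sqrt((nodes$x[match(net$segments$node_i, nodes$id)] +
                     nodes$x[match(net$segments$node_j, nodes$id)])^2 +
                  (nodes$y[match(net$segments$node_i, nodes$id)] +
                     nodes$y[match(net$segments$node_j, nodes$id)])^2 +
                  (nodes$z[match(net$segments$node_i, nodes$id)] +
                     nodes$z[match(net$segments$node_j, nodes$id)])^2) / 2
    r_cut <- 0.75 * 300
    rim_vol <- 4 / 3 * pi * (300^3 - r_cut^3)
    core_vol <- 4 / 3 * pi * r_cut^3
    rim_d <- sum(net$segments$length[mid_r >= r_cut]) / rim_vol
    core_d <- sum(net$segments$length[mid_r < r_cut]) / core_vol
    rim_d > core_d
  }, logical(1)))
  expect_gte(frac_hit, 0.95)
})

test_that("mesentery loader enforces the documented dataset composition", {
  # synthetic miniature in the documented layout (3 segments, 2 inlets,
  # 1 outlet, 1 pressure node) standing in for the published network
  dir <- withr::local_tempdir()
  nodes <- tibble::tibble(id = 1:5, x = c(0, 0, 100, 200, 200),
                          y = c(0, 100, 50, 50, 150), z = 0)
  segs <- tibble::tibble(id = 1:4, node_i = c(1, 2, 3, 3),
                         node_j = c(3, 3, 4, 5),
                         diameter = c(20, 18, 22, 12))
  bc <- tibble::tibble(
    node_id = c(1, 2, 4, 5),
    kind = c("flow_hematocrit", "flow_hematocrit", "flow", "pressure"),
    pressure = c(NA, NA, NA, 12),
    flow = c(2e-3, 1e-3, -2.5e-3, NA),
    hd = c(0.45, 0.4, NA, NA)
  )
  net <- vascular_network(nodes, segs, bc)
  write_network(net, dir)
  expected <- c(segments = 4L, inlets = 2L, outlets = 1L,
                pressure_nodes = 1L)
  loaded <- load_mesentery(dir, expected = expected)
  expect_equal(nrow(loaded$segments), 4)
  # wrong composition is rejected with the discrepancies listed
  expect_error(load_mesentery(dir), "546")
  bad <- expected; bad["inlets"] <- 3L
  expect_error(load_mesentery(dir, expected = bad), "inlets")
  # a measured inlet lacking hematocrit is rejected
  bc2 <- bc; bc2$hd[1] <- NA
  expect_error(vascular_network(nodes, segs, bc2), "hematocrit")
})

test_that("measured mixed boundary conditions drive the solver directly", {
  # miniature with measured inflows/outflow + one pressure node: flow BCs
  # are honored exactly and the optimizer is bypassed
  nodes <- tibble::tibble(id = 1:5, x = c(0, 0, 100, 200, 200),
                          y = c(0, 100, 50, 50, 150), z = 0)
  segs <- tibble::tibble(id = 1:4, node_i = c(1, 2, 3, 3),
                         node_j = c(3, 3, 4, 5),
                         diameter = c(20, 18, 22, 12))
  bc <- tibble::tibble(
    node_id = c(1, 2, 4, 5),
    kind = c("flow_hematocrit", "flow_hematocrit", "flow", "pressure"),
    pressure = c(NA, NA, NA, 12),
    flow = c(2e-3, 1e-3, -2.5e-3, NA),
    hd = c(0.45, 0.4, NA, NA)
  )
  net <- vascular_network(nodes, segs, bc)
  st <- simulate_hemodynamics(net)
  expect_equal(st$segments$flow[1], 2e-3, tolerance = 1e-10)
  expect_equal(st$segments$flow[2], 1e-3, tolerance = 1e-10)
  expect_equal(st$segments$flow[3], 2.5e-3, tolerance = 1e-10)
  expect_equal(st$segments$flow[4], 0.5e-3, tolerance = 1e-10)
  # measured inlet hematocrits are used as-is
  expect_equal(st$segments$hd[1], 0.45, tolerance = 1e-10)
  expect_equal(st$segments$hd[2], 0.4, tolerance = 1e-10)
})
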