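test_that("single-vessel flow matches the closed-form Poiseuille value", {
  dp_mmhg <- 100 / 133.322                 # 100 Pa
  net <- make_line(diameter = 10, length = 100,
                   p_inlet = dp_mmhg, p_outlet = 0)
  sol <- solve_pressures(net, viscosity = 1)
  expect_equal(sol$flows$flow, 2.454369260617026e-4, tolerance = 1e-8)
})

test_that("zero pressure difference gives zero flow everywhere", {
  net <- make_bifurcation_tree(depth = 2, p_root = 20, p_leaf = 20)
  sol <- solve_pressures(net, viscosity = 2)
  expect_true(all(abs(sol$flows$flow) < 1e-14))
})

test_that("sparse solve agrees with a dense direct solve", {
  for (seed in 1:5) {
    net <- random_test_network(n_interior = 12 + 2 * seed, seed = seed)
    mu <- runif(nrow(net$segments), 1, 5)
    sol <- solve_pressures(net, mu)
    oracle <- dense_solve_oracle(net, mu)
    expect_equal(sol$pressures$pressure, unname(oracle$pressures),
                 tolerance = 1e-10)
    expect_equal(sol$flows$flow, unname(oracle$flows), tolerance = 1e-10)
    expect_lt(sol$mass_residual, 1e-10)
  }
})

test_that("flow scales linearly with boundary pressure deviations at fixed viscosity", {
  net <- random_test_network(seed = 4)
  datum <- 10
  k <- 3.5
  sol1 <- solve_pressures(net, 2)
  net2 <- net
  net2$boundary$pressure <- datum + k * (net$boundary$pressure - datum)
  sol2 <- solve_pressures(net2, 2)
  expect_equal(sol2$flows$flow, k * sol1$flows$flow, tolerance = 1e-10)
})

test_that("disconnected component without a pressure anchor is a structural error", {
  nodes <- data.frame(id = 1:4, x = c(0, 100, 0, 100), y = c(0, 0, 300, 300),
                      z = 0)
  segs <- data.frame(id = 1:2, node_i = c(1, 3), node_j = c(2, 4),
                     diameter = 10)
  bc <- data.frame(node_id = 1:2, kind = "pressure", pressure = c(20, 10),
                   flow = NA, hd = NA)
  net <- vascular_network(nodes, segs, bc)
  expect_error(solve_pressures(net, 1), "singular")
})

test_that("symmetric bifurcations pass the parent hematocrit unchanged", {
  net <- make_bifurcation_tree(depth = 1, root_diameter = 20,
                               diameter_ratio = 0.7,
                               p_root = 30, p_leaf = 10)
  sol <- solve_pressures(net, 1.5)
  hd <- distribute_hematocrit(net, sol$flows, sol$pressures,
                              inlet_hematocrit = 0.45)
  expect_equal(hd$hd, rep(0.45, 3), tolerance = 1e-12)
})

test_that("a daughter carrying all flow inherits all red cells", {
  # fork where one daughter has zero flow (equal end pressures)
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 200),
                      y = c(0, 0, 80, -80), z = 0)
  segs <- data.frame(id = 1:3, node_i = c(1, 2, 2), node_j = c(2, 3, 4),
                     diameter = c(20, 14, 14))
  net <- vascular_network(nodes, segs)
  flows <- tibble::tibble(id = 1:3, flow = c(1e-3, 1e-3, 0))
  pressures <- tibble::tibble(id = 1:4, pressure = c(30, 20, 10, 20))
  hd <- distribute_hematocrit(net, flows, pressures, 0.45)
  expect_equal(hd$hd[2], 0.45, tolerance = 1e-12)
  expect_equal(hd$hd[3], 0)
  expect_true(hd$zero_flow[3])
})

test_that("asymmetric bifurcation follows the phase-separation closed form", {
  # parent 20 um, daughters 12/16 um with 30/70 flow split, feed HD 0.45;
  # expected daughter hematocrits frozen from an independent evaluation
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 200),
                      y = c(0, 0, 80, -80), z = 0)
  segs <- data.frame(id = 1:3, node_i = c(1, 2, 2), node_j = c(2, 3, 4),
                     diameter = c(20, 12, 16))
  net <- vascular_network(nodes, segs)
  qp <- 2e-3
  flows <- tibble::tibble(id = 1:3, flow = c(qp, 0.3 * qp, 0.7 * qp))
  pressures <- tibble::tibble(id = 1:4, pressure = c(30, 20, 10, 10))
  hd <- distribute_hematocrit(net, flows, pressures, 0.45)
  expect_equal(hd$hd[2], 0.41606621375208935, tolerance = 1e-10)
  expect_equal(hd$hd[3], 0.46454305124910455, tolerance = 1e-10)
  # red-cell flux conservation at the bifurcation
  expect_lt(abs(qp * 0.45 - 0.3 * qp * hd$hd[2] - 0.7 * qp * hd$hd[3]),
            1e-12)
})

test_that("red-cell flux is conserved across whole networks", {
  for (seed in c(2, 9)) {
    net <- make_tumor_like(n_segments = 120, radius = 300, seed = seed)
    st <- simulate_hemodynamics(net)
    expect_lt(st$residuals$rbc_rel_imbalance, 1e-8)
  }
})

test_that("raising inlet hematocrit never increases total network flow", {
  net <- random_test_network(seed = 7)
  total_inflow <- function(h) {
    st <- simulate_hemodynamics(net, flow_config(inlet_hematocrit = h))
    sum(st$boundary_flow$flow[st$boundary_flow$flow > 0])
  }
  q <- vapply(c(0.2, 0.4, 0.6), total_inflow, 1)
  expect_true(all(diff(q) <= 1e-12))
})

test_that("plasma-only perfusion converges immediately to the H = 0 viscosity", {
  net <- make_bifurcation_tree(depth = 2, p_root = 25, p_leaf = 5)
  st <- simulate_hemodynamics(net, flow_config(inlet_hematocrit = 0))
  expect_equal(st$iterations, 1L)
  expect_equal(st$segments$hd, rep(0, nrow(st$segments)))
  expect_equal(st$segments$viscosity,
               apparent_viscosity(st$segments$diameter, 0, rheology_params()),
               tolerance = 1e-12)
})

test_that("derived metrics satisfy their algebraic identities", {
  dp_mmhg <- 100 / 133.322
  net <- make_line(diameter = 10, length = 100,
                   p_inlet = dp_mmhg, p_outlet = 0)
  sol <- solve_pressures(net, viscosity = 1)
  m <- derived_flow_metrics(data.frame(flow = sol$flows$flow, diameter = 10,
                                       length = 100, viscosity = 1))
  expect_equal(m$velocity, 3.125, tolerance = 1e-8)
  expect_equal(m$wall_shear, 25, tolerance = 1e-8)
  expect_equal(m$transit_time, 0.032, tolerance = 1e-8)

  st <- simulate_hemodynamics(make_tumor_like(n_segments = 80, radius = 250,
                                              seed = 5))
  perf <- st$segments$perfused
  # vstt = L / u for every perfused segment (u in mm/s, L in um)
  expect_equal(st$segments$transit_time[perf],
               st$segments$length[perf] / (1e3 * st$segments$velocity[perf]),
               tolerance = 1e-10)
  expect_true(all(st$segments$ht <= st$segments$hd + 1e-12))
})

test_that("boundary optimization is bypassed with complete boundary data", {
  net <- make_tumor_like(n_segments = 80, radius = 250, seed = 2,
                         boundary = "pressure")
  bp <- optimize_boundary_pressures(net)
  expect_true(attr(bp, "skipped"))
  expect_equal(bp$pressure,
               net$boundary$pressure[match(bp$node_id, net$boundary$node_id)])
})

test_that("boundary optimization balances networks lacking boundary data", {
  net <- make_tumor_like(n_segments = 80, radius = 250, seed = 2,
                         boundary = "none")
  cfg <- flow_config(arterial_pressure = 30, venous_pressure = 10)
  bp <- optimize_boundary_pressures(net, cfg)
  expect_false(attr(bp, "skipped"))
  expect_true(all(bp$pressure >= 10 & bp$pressure <= 30))
  expect_lt(attr(bp, "imbalance"), 1e-3)
  # two-boundary single vessel: any in-anchor pair balances exactly
  net2 <- make_line()
  bp2 <- optimize_boundary_pressures(net2, cfg)
  expect_equal(nrow(bp2), 2)
  expect_lt(attr(bp2, "imbalance"), 1e-3)
})

test_that("interior mass residuals stay at solver precision after simulation", {
  net <- make_tumor_like(n_segments = 150, radius = 300, seed = 6)
  st <- simulate_hemodynamics(net)
  expect_lt(st$residuals$mass_residual, 1e-10)
  expect_true(st$converged)
})
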