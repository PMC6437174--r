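test_that("classification follows the velocity/PO2 quadrants exactly", {
  # nine cases around the (50 um/s, 10 mmHg) thresholds; boundary values
  # belong to the hyperperfused/normoxic side of each inequality
  vel <- c(30, 30, 30, 50, 50, 50, 60, 60, 60)
  po2 <- c(5, 10, 20, 5, 10, 20, 5, 10, 20)
  f <- fake_states(vel, po2)
  cls <- classify_vessels(f$state, f$oxy)
  expect_equal(cls$class, c(1L, 3L, 3L, 3L, 2L, 2L, 3L, 2L, 2L))
  # labels partition the perfused set
  expect_true(all(!is.na(cls$class[cls$perfused])))
})

test_that("shunts override the quadrant classes", {
  # median velocity 50, median diameter 10, median length 100 (11 vessels);
  # the last one is fast, wide and short: 2.5x, 2.2x and 0.4x the medians
  vel <- c(rep(50, 10), 125)
  po2 <- rep(20, 11)
  f <- fake_states(vel, po2, diameter = c(rep(10, 10), 22),
                   length = c(rep(100, 10), 40))
  cls <- classify_vessels(f$state, f$oxy)
  expect_equal(cls$class[11], 4L)
  expect_true(all(cls$class[1:10] == 2L))
  # failing any one shunt criterion demotes to the quadrant class
  f2 <- fake_states(vel, po2, diameter = c(rep(10, 10), 22),
                    length = c(rep(100, 10), 90))   # not short enough
  expect_equal(classify_vessels(f2$state, f2$oxy)$class[11], 2L)
})

test_that("unperfused vessels are excluded from classification", {
  f <- fake_states(c(60, 60, 30), c(20, 20, 5), flow = c(1e-3, 1e-3, 1e-12))
  cls <- classify_vessels(f$state, f$oxy)
  expect_true(is.na(cls$class[3]))
  expect_false(cls$perfused[3])
})

test_that("coefficient of variation matches its definition", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(7, 5)), 0)
  x <- rlnorm(20, 1, 0.4)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(1), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
})

test_that("CV correlation matrix recovers exact linear relations", {
  tab <- tibble::tibble(a = c(1, 2, 3, 5), b = c(2, 4, 6, 10),
                        c = c(5, 4, 3, 1), k = 1)
  m <- suppressMessages(cv_correlation_matrix(tab))
  expect_equal(m$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(m$r["a", "c"], -1, tolerance = 1e-12)
  expect_true(is.na(m$r["a", "k"]))            # constant column
  expect_equal(m$r, t(m$r))
  expect_error(cv_correlation_matrix(tab[1:2, ]), "at least 3")
})

test_that("planted CV correlation is recovered on average", {
  set.seed(42)
  rho <- 0.8
  rbar <- mean(replicate(100, {
    x <- rnorm(8)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(8)
    suppressWarnings(cor(x, y))
  }))
  expect_lt(abs(rbar - rho), 0.25)
})

test_that("mean path length is the flow-weighted mean segment length", {
  d <- data.frame(flow = c(1, 3), diameter = 10, length = c(10, 20),
                  viscosity = 1)
  expect_equal(attr(derived_flow_metrics(d), "mpl"), 17.5)
  d2 <- data.frame(flow = rep(2, 4), diameter = 8,
                   length = c(10, 20, 30, 40), viscosity = 1)
  expect_equal(mean_path_length(d2), 25)        # uniform flow: plain mean
  expect_equal(mean_path_length(data.frame(flow = 1, diameter = 10,
                                           length = 123, viscosity = 1)),
               123)
  # zero-flow segments report infinite transit time and drop out of MPL
  d3 <- data.frame(flow = c(1, 0), diameter = 10, length = c(10, 99),
                   viscosity = 1)
  m <- derived_flow_metrics(d3)
  expect_true(is.infinite(m$transit_time[2]))
  expect_equal(attr(m, "mpl"), 10)
})

test_that("group comparison reproduces the exact Mann-Whitney U", {
  a <- c(1.2, 3.4, 0.7, 2.2)
  b <- c(2.9, 5.1, 4.4, 3.3)
  got <- suppressWarnings(compare_groups(a, b))
  expect_equal(got$statistic, brute_force_u(a, b))
  # complete separation: U = 0
  lo <- 1:10
  hi <- 101:110
  expect_equal(suppressWarnings(compare_groups(lo, hi))$statistic, 0)
  # identical tied groups
  expect_warning(res <- compare_groups(rep(1, 4), rep(1, 4)), "tied")
  expect_equal(res$p_value, 1)
})

test_that("UPGMA merges closest pairs first and matches a manual trace", {
  # 3 points on a line: 0, 1, 11 -> the close pair merges first
  feats <- tibble::tibble(network = c("a", "b", "c"), f = c(0, 1, 11))
  cl <- cluster_networks(feats, k = 2)
  expect_equal(unname(cl$labels["a"]), unname(cl$labels["b"]))
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])

  # 4-point manual UPGMA trace on the z-scored feature distances
  feats4 <- tibble::tibble(network = letters[1:4],
                           f1 = c(0, 1, 4, 9), f2 = c(0, 2, 5, 7))
  cl4 <- cluster_networks(feats4)
  dm <- as.matrix(cl4$distances)
  expect_equal(sort(cl4$tree$height), sort(manual_upgma_heights(dm)),
               tolerance = 1e-12)
  # ultrametric input distances give a cophenetic coefficient of 1
  um <- tibble::tibble(network = 1:4, f = c(0, 0, 10, 10))
  cl_um <- suppressMessages(cluster_networks(um))
  expect_equal(cl_um$cophenetic, 1, tolerance = 1e-12)
})

test_that("planted two-group ensembles are recovered with a reliable tree", {
  set.seed(7)
  feats <- tibble::tibble(
    network = sprintf("t%02d", 1:10),
    group = rep(c(1, 2), each = 5),
    med_d = c(rnorm(5, 8, 0.5), rnorm(5, 16, 0.5)),
    med_l = c(rnorm(5, 60, 5), rnorm(5, 110, 5))
  )
  cl <- cluster_networks(dplyr::select(feats, -"group"), k = 2)
  split_ok <- length(unique(cl$labels[feats$group == 1])) == 1 &&
    length(unique(cl$labels[feats$group == 2])) == 1 &&
    cl$labels[1] != cl$labels[10]
  expect_true(split_ok)
  expect_gt(cl$cophenetic, 0.8)
  expect_true(glance(cl)$reliable)
})

test_that("heterogeneity report collates CVs, medians and correlations", {
  states <- lapply(1:3, function(s) {
    simulate_hemodynamics(make_tumor_like(n_segments = 80, radius = 250,
                                          seed = s))
  })
  rep <- heterogeneity_report(states)
  expect_equal(nrow(rep$cv), 3)
  expect_true(all(c("diameter", "flow", "velocity") %in% names(rep$cv)))
  expect_true(all(rep$cv$flow > 0, na.rm = TRUE))
  expect_s3_class(rep$correlation, "cv_correlation")
  expect_true(all(abs(rep$correlation$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(rep$medians$mpl >= 0))
})
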