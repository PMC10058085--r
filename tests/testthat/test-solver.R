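hemo0 <- hemodynamic_state(120, 80)   # MAP 96, Pv 5

test_that("segment coefficients reproduce hand-evaluated Poiseuille resistance", {
  # 8 mu L / (pi r^4) for L = 10 mm, r = 2 mm, mu = 0.0035 Pa s
  a_si_expected <- 8 * 0.0035 * 0.010 / (pi * 0.002^4)
  co <- segment_coefficients(10, 2, blood = hemo0)
  a_si <- co$a * 133.322 / (1e-6 / 60)   # back to Pa s m^-3
  expect_equal(a_si, a_si_expected, tolerance = 1e-12)
  expect_equal(a_si_expected, 5.57e6, tolerance = 1e-3)
  expect_equal(co$b, 0)
  expect_error(segment_coefficients(0, 2), class = "ctpffr_domain_error")
  expect_error(segment_coefficients(10, -1), class = "ctpffr_domain_error")
})

test_that("a zero-severity stenosis degenerates to the plain segment", {
  plain <- segment_coefficients(20, 1.5, blood = hemo0)
  degen <- segment_coefficients(20, 1.5,
                                stenosis = list(center = 10, length = 8,
                                                severity = 0),
                                blood = hemo0)
  expect_equal(degen$a, plain$a)
  expect_equal(degen$b, 0)
})

test_that("both loss coefficients increase with stenosis severity", {
  sev <- seq(10, 90, by = 10)
  co <- lapply(sev, function(s) {
    segment_coefficients(30, 1.5,
                         stenosis = list(center = 15, length = 10,
                                         severity = s),
                         blood = hemo0)
  })
  a <- vapply(co, `[[`, numeric(1), "a")
  b <- vapply(co, `[[`, numeric(1), "b")
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(b) > 0))
})

test_that("single-tube solve matches the series-resistance closed form", {
  tree <- tube_tree(length = 60, radius = 1.5)
  r_out <- 6
  bc <- tibble::tibble(outlet = 2L, r_hyp = r_out)
  fit <- solve_tree(tree, bc, hemo0)
  a <- segment_coefficients(60, 1.5, blood = hemo0)$a
  p_exp <- hemo0$pv + r_out * (hemo0$map - hemo0$pv) / (a + r_out)
  p_num <- fit$solution$pressures$pressure[
    fit$solution$pressures$node == 2L]
  expect_equal(p_num, p_exp, tolerance = 1e-12)

  # stenosed tube: quadratic closed form a q + b q^2 + R q = MAP - Pv
  tree_s <- tube_tree(length = 60, radius = 1.5, severity = 60)
  fit_s <- solve_tree(tree_s, bc, hemo0)
  co <- segment_coefficients(60, 1.5,
                             stenosis = list(center = 25, length = 10,
                                             severity = 60),
                             blood = hemo0)
  bb <- co$b; aa <- co$a + r_out
  q_exp <- (-aa + sqrt(aa^2 + 4 * bb * (hemo0$map - hemo0$pv))) / (2 * bb)
  expect_equal(fit_s$solution$inlet_flow, q_exp, tolerance = 1e-9)
  expect_equal(fit_s$solution$pressures$pressure[
    fit_s$solution$pressures$node == 2L],
    hemo0$pv + r_out * q_exp, tolerance = 1e-9)
})

test_that("zero-loss network equilibrates at MAP with FFR of one", {
  # hand-zeroed coefficients: every nodal pressure collapses to MAP
  tree <- tube_tree(length = 60, radius = 2, severity = 40)
  graph <- build_vessel_graph(tree, tibble::tibble(outlet = 2L, r_hyp = 6),
                              hemo0)
  graph$edges$a <- 0
  graph$edges$b <- 0
  sol <- solve_network(graph, hemo0$map)
  expect_equal(sol$pressures$pressure, rep(hemo0$map, nrow(sol$pressures)),
               tolerance = 1e-9)
  # physically near-lossless tube (wide lumen, negligible narrowing)
  fat <- tube_tree(length = 60, radius = 10, severity = 1)
  fit <- solve_tree(fat, tibble::tibble(outlet = 2L, r_hyp = 6), hemo0)
  expect_equal(fit$vessels$ffr, 1, tolerance = 1e-5)
})

test_that("a symmetric bifurcation splits flow exactly in half", {
  tree <- bifurcation_tree()
  bc <- tibble::tibble(outlet = c(3L, 4L), r_hyp = c(7, 7))
  fit <- solve_tree(tree, bc, hemo0)
  q <- fit$solution$outlet_flows$q
  expect_equal(q[1], q[2], tolerance = 1e-14)
})

test_that("solver matches the direct linear-network elimination oracle", {
  withr::with_seed(41, {
    for (rep in 1:8) {
      # random tree of <= 4 edges, viscous losses only
      tree <- if (rep %% 2 == 0) bifurcation_tree(r_stem = runif(1, 1.5, 2.5)) else tube_tree(radius = runif(1, 1, 2.5))
      bc <- tibble::tibble(outlet = tree$outlets$node,
                           r_hyp = runif(nrow(tree$outlets), 3, 30))
      graph <- build_vessel_graph(tree, bc, hemo0)
      sol <- solve_network(graph, hemo0$map)
      oracle <- linear_network_oracle(graph, hemo0$map)
      expect_equal(sol$pressures$pressure, oracle$pressure,
                   tolerance = 1e-10)
    }
  })
})

test_that("mass is conserved at every node and pressures stay bounded", {
  cfg <- cohort_config()
  tree <- generate_tree(cfg, 7)
  bc <- tibble::tibble(outlet = tree$outlets$node,
                       r_hyp = c(5, 6, 20, 7, 8))
  fit <- solve_tree(tree, bc, hemo0, fine_step = 1)
  sol <- fit$solution
  # nodal imbalance from the reported edge flows
  imb <- vapply(sol$pressures$node, function(nd) {
    inflow <- sum(sol$flows$q[sol$flows$to == nd])
    outflow <- sum(sol$flows$q[sol$flows$from == nd])
    o <- match(nd, fit$graph$outlets$node)
    if (!is.na(o)) {
      outflow <- outflow + sol$outlet_flows$q[o]
    }
    if (nd == fit$graph$inlet) inflow <- inflow + sol$inlet_flow
    inflow - outflow
  }, numeric(1))
  expect_lt(max(abs(imb)), 1e-9 * sol$inlet_flow)
  expect_true(all(sol$pressures$pressure <= hemo0$map + 1e-9))
  expect_true(all(sol$pressures$pressure >= hemo0$pv - 1e-9))
})

test_that("per-vessel FFR is stable under discretization refinement", {
  tree <- tube_tree(length = 80, radius = 1.6, severity = 65,
                    sten_center = 30)
  bc <- tibble::tibble(outlet = 2L, r_hyp = 6)
  f2 <- solve_tree(tree, bc, hemo0, fine_step = 2)$vessels$ffr
  f1 <- solve_tree(tree, bc, hemo0, fine_step = 1)$vessels$ffr
  f05 <- solve_tree(tree, bc, hemo0, fine_step = 0.5)$vessels$ffr
  expect_lt(abs(f2 - f1), 1e-3)
  expect_lt(abs(f1 - f05), 1e-3)
})

test_that("FFR readout decreases with distance downstream of the lesion", {
  tree <- tube_tree(length = 80, radius = 1.4, severity = 60,
                    sten_center = 30)
  bc <- tibble::tibble(outlet = 2L, r_hyp = 8)
  fit <- solve_tree(tree, bc, hemo0)
  f0 <- ffr_at(fit$solution, fit$graph, 1L, offset = 0)
  f20 <- ffr_at(fit$solution, fit$graph, 1L, offset = 20)
  expect_lte(f20$ffr, f0$ffr)
  expect_false(f20$clamped)
  # beyond the vessel end: clamped to the most distal point, flagged
  ffar <- ffr_at(fit$solution, fit$graph, 1L, offset = 500)
  expect_true(ffar$clamped)
  expect_error(ffr_at(fit$solution, fit$graph, 99L),
               class = "ctpffr_domain_error")
})
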