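test_that("mean aortic pressure is the fixed 0.4 convex combination", {
  expect_equal(mean_aortic_pressure(120, 80), 96)
  expect_equal(mean_aortic_pressure(140, 70), 98)
  # degenerate pulse pressure: MAP -> the common value
  expect_equal(mean_aortic_pressure(100, 100 - 1e-9), 100, tolerance = 1e-8)
  expect_error(mean_aortic_pressure(80, 80), class = "ctpffr_domain_error")
  expect_error(mean_aortic_pressure(80, 90), class = "ctpffr_domain_error")
  sbp <- runif(50, 100, 180); dbp <- runif(50, 50, 95)
  map <- mean_aortic_pressure(sbp, dbp)
  expect_true(all(map >= dbp & map <= sbp))
})

test_that("outlet flow is the territory perfusion integral", {
  # two voxels of 0.5 mm^3 with MBF 1 and 2 -> Q = 1.5e-3 mL/min
  map <- mbf_map(array(c(1, 2), dim = c(2, 1, 1)),
                 array(TRUE, dim = c(2, 1, 1)),
                 spacing = c(1, 1, 0.5), origin = c(0, 0, 0))
  tree <- star_tree(matrix(c(1, 0.5, 0.25), nrow = 1))
  terr <- assign_territories(map, tree)
  expect_equal(outlet_flow(terr, map, tree$outlets$node[1]), 1.5e-3)
  # uniform field factorizes as v * V
  umap <- uniform_map(value = 1.3, dims = c(6, 6, 4), spacing = c(1, 1, 1))
  t2 <- assign_territories(umap, tree)
  expect_equal(outlet_flow(t2, umap, tree$outlets$node[1]),
               1.3 * sum(umap$mask) * 1e-3)
})

test_that("outlet flows conserve the whole-mask perfusion integral", {
  withr::with_seed(31, {
    pos <- cbind(runif(5, 0, 12), runif(5, 0, 12), runif(5, 0, 8))
    tree <- star_tree(pos)
    map <- uniform_map(dims = c(12, 12, 8))
    map$values[map$mask] <- runif(sum(map$mask), 0.2, 3)
    terr <- assign_territories(map, tree)
    q <- vapply(terr$outlets$node, function(o) outlet_flow(terr, map, o),
                numeric(1))
    total <- sum(map$values[map$mask]) * prod(map$spacing) / 1000
    expect_lt(abs(sum(q) - total), 1e-12 * total)
  })
})

test_that("outlet resistance is the arteriovenous gradient over flow", {
  expect_equal(outlet_resistance(96, 5, 1.5), 91 / 1.5)
  expect_error(outlet_resistance(96, 5, 0), class = "ctpffr_domain_error")
  expect_error(outlet_resistance(4, 5, 1), class = "ctpffr_domain_error")
  withr::with_seed(32, {
    mp <- runif(20, 60, 120); pv <- runif(20, 0, 10); q <- runif(20, 0.1, 500)
    r <- outlet_resistance(mp, pv, q)
    expect_equal(r * q + pv, mp)   # algebraic identity, exact
  })
})

test_that("doubling MBF halves every outlet resistance", {
  withr::with_seed(33, {
    pos <- cbind(runif(4, 0, 10), runif(4, 0, 10), runif(4, 0, 6))
    tree <- star_tree(pos)
    map <- uniform_map(dims = c(10, 10, 6))
    map$values[map$mask] <- runif(sum(map$mask), 0.5, 2)
    terr <- assign_territories(map, tree)
    hemo <- hemodynamic_state(120, 80)
    bc1 <- compute_outlet_bc(terr, map, hemo)
    map2 <- map; map2$values <- map$values * 2
    bc2 <- compute_outlet_bc(terr, map2, hemo)
    expect_equal(bc2$r_hyp, bc1$r_hyp / 2)
    expect_equal(bc2$q_hyp, bc1$q_hyp * 2)
  })
})

test_that("zero-flow territories are flagged and capped, not infinite", {
  tree <- star_tree(rbind(c(0, 0.5, 0.5), c(9, 0.5, 0.5)))
  map <- uniform_map(dims = c(10, 1, 1))
  map$values[6:10, , ] <- 0   # second outlet's territory fully infarcted
  terr <- assign_territories(map, tree)
  expect_warning(bc <- compute_outlet_bc(terr, map, hemodynamic_state(120, 80),
                                         r_ceiling = 5e5))
  expect_true(bc$zero_flow[2])
  expect_equal(bc$r_hyp[2], 5e5)
  expect_false(bc$zero_flow[1])
})

test_that("effective dose is the k-scaled dose-length product", {
  expect_equal(effective_dose(500), 7.0)
  expect_equal(effective_dose(0), 0)
  expect_equal(effective_dose(1), 0.014)
  expect_error(effective_dose(-1), class = "ctpffr_domain_error")
})
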