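demo_cohort <- function() {
  cached("demo_cohort",
         simulate_cohort(fast_config(n_patients = 24, seed = 301)))
}

test_that("tree generation is deterministic under a fixed seed", {
  cfg <- fast_config()
  t1 <- generate_tree(cfg, 42)
  t2 <- generate_tree(cfg, 42)
  expect_identical(t1, t2)
  t3 <- generate_tree(cfg, 43)
  expect_false(identical(t1$nodes, t3$nodes))
})

test_that("patient generation is deterministic end to end", {
  cfg <- fast_config(n_patients = 1, seed = 77)
  p1 <- generate_patient(cfg, 1)
  p2 <- generate_patient(cfg, 1)
  expect_identical(p1$truth$invasive_ffr, p2$truth$invasive_ffr)
  expect_identical(p1$map$values, p2$map$values)
  expect_identical(p1$tree, p2$tree)
})

test_that("a degenerate severity range forces every stenosis to it", {
  cfg <- fast_config(stenosis_severity_range = c(30, 30))
  for (s in 1:5) {
    tr <- generate_tree(cfg, s)
    expect_true(all(tr$stenoses$severity == 30))
  }
})

test_that("Murray's law holds at every bifurcation of generated trees", {
  cfg <- fast_config()
  for (s in 1:10) {
    res <- murray_residuals(generate_tree(cfg, s))
    expect_lt(max(res$residual), 0.01)
  }
})

test_that("generated vessels satisfy the QCA inclusion window", {
  rec <- demo_cohort()$records
  expect_true(all(rec$qca_percent >= 30 & rec$qca_percent <= 90))
  expect_true(all(rec$invasive_ffr > 0 & rec$invasive_ffr <= 1))
  expect_true(all(rec$lesion_location %in% c("proximal", "middle", "distal")))
  expect_true(all(rec$cac_class %in% c("<400", ">=400")))
})

test_that("cohort prevalence stays within binomial bounds of the target", {
  rec <- demo_cohort()$records
  phat <- mean(rec$invasive_ffr <= 0.80)
  half_width <- 1.96 * sqrt(0.46 * 0.54 / nrow(rec))
  expect_lt(abs(phat - 0.46), half_width)
})

test_that("noise-free perfusion map realizes the stated FFR coupling", {
  cfg <- fast_config(mbf_noise_sd = 0)
  tree <- generate_tree(cfg, 5)
  # all vessels non-ischemic: every masked voxel at the normal mean
  healthy <- tibble::tibble(vessel = c("LAD", "LCX"),
                            invasive_ffr = c(1, 1))
  m1 <- generate_mbf_map(tree, healthy, cfg)
  expect_true(all(abs(m1$values[m1$mask] - cfg$mbf_normal_mean) < 1e-12))
  # one outlet at FFR 0.4 -> its territory at half the normal mean
  terr <- assign_territories(m1, tree)
  target_outlet <- tree$outlets$node[1]
  truth <- tibble::tibble(vessel = "LAD", invasive_ffr = 0.4)
  attr(truth, "outlet_ffr") <- tibble::tibble(
    outlet = tree$outlets$node,
    ffr = ifelse(tree$outlets$node == target_outlet, 0.4, 1))
  m2 <- generate_mbf_map(tree, truth, cfg)
  in_t <- !is.na(terr$labels) & terr$labels == target_outlet
  expect_true(all(abs(m2$values[in_t] - 0.5 * cfg$mbf_normal_mean) < 1e-12))
  expect_true(all(abs(m2$values[m2$mask & !in_t] - cfg$mbf_normal_mean) < 1e-12))
})

test_that("noisy map voxel mean matches the configured mean within 3 SE", {
  cfg <- cohort_config(mbf_noise_sd = 0.15)   # full-resolution grid, n ~ 1e5
  tree <- generate_tree(cfg, 9)
  healthy <- tibble::tibble(vessel = c("LAD", "LCX"), invasive_ffr = c(1, 1))
  m <- generate_mbf_map(tree, healthy, cfg, seed = 88)
  v <- m$values[m$mask]
  se <- cfg$mbf_noise_sd / sqrt(length(v))
  expect_lt(abs(mean(v) - cfg$mbf_normal_mean), 3 * se)
})

test_that("a stenosis-free tree loses at most a few percent to viscosity", {
  cfg <- fast_config(ffr_measurement_noise_sd = 0)
  tree <- generate_tree(cfg, 3)
  tree$stenoses <- tree$stenoses[0, ]
  hemo <- hemodynamic_state(120, 80)
  truth <- simulate_invasive_ffr(tree, hemo, cfg)
  expect_true(all(truth$invasive_ffr >= 0.97))
  truth2 <- simulate_invasive_ffr(tree, hemo, cfg)
  expect_identical(truth$invasive_ffr, truth2$invasive_ffr)
})

test_that("ground-truth FFR decreases with stenosis severity", {
  cfg <- fast_config(ffr_measurement_noise_sd = 0)
  tree <- generate_tree(cfg, 11)
  hemo <- hemodynamic_state(120, 80)
  lesioned <- unique(tree$stenoses$vessel)
  with_sev <- function(s) {
    tree$stenoses$severity[tree$stenoses$primary] <- s
    tr <- simulate_invasive_ffr(tree, hemo, cfg)
    tr$invasive_ffr[tr$vessel %in% lesioned]
  }
  f50 <- with_sev(50); f70 <- with_sev(70); f90 <- with_sev(90)
  expect_true(all(f90 < f70))
  expect_true(all(f70 < f50))
})

test_that("cohort vessel mix leans LAD as configured", {
  rec <- demo_cohort()$records
  expect_true(all(rec$vessel_name %in% c("LAD", "LCX")))
  expect_gt(mean(rec$vessel_name == "LAD"), 0.5)
})
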