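#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic-cohort generator. Defaults encode the
#' study conditions the generator is meant to emulate: ~46% of evaluable
#' vessels hemodynamically significant (invasive FFR <= 0.80), LAD/LCX mix
#' and lesion-location frequencies as observed clinically, QCA severities
#' inside the 30-90% inclusion window, and the CT voxel spacing
#' 0.625 x 0.625 x 1.25 mm.
#'
#' @param n_patients number of patients.
#' @param two_vessel_prob probability a patient contributes two evaluable
#'   vessels (LAD and LCX). Default 10/93.
#' @param lad_single_prob probability a single-vessel patient's lesion is in
#'   the LAD. Default 74/83 (so LAD carries ~82% of lesions overall).
#' @param stenosis_severity_range allowed % diameter stenosis, within
#'   `[30, 90]`.
#' @param ischemic_fraction proportion of vessels with invasive
#'   FFR <= 0.80. Default 0.46.
#' @param ffr_band_weights_pos,ffr_band_weights_neg band weights for the
#'   target invasive FFR, conditional on ischemic / non-ischemic status:
#'   positives split between FFR <= 0.70 and 0.70-0.80, negatives between
#'   0.80-0.90 and > 0.90.
#' @param mbf_normal_mean,mbf_normal_sd remote (non-ischemic) hyperemic MBF
#'   mean and between-patient SD, mL min^-1 mL^-1.
#' @param mbf_noise_sd per-voxel MBF noise SD, mL min^-1 mL^-1.
#' @param ffr_measurement_noise_sd SD of the invasive wire-measurement noise
#'   (dimensionless FFR units).
#' @param voxel_spacing voxel spacing in mm (x, y, z).
#' @param lv_inner_radius,lv_outer_radius radii (mm) of the half-shell used
#'   as the LV-myocardium mask (right-coronary side absent).
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd brachial cuff pressure
#'   distribution, mmHg.
#' @param cac_severe_prob probability a vessel is labeled severely
#'   calcified (Agatston >= 400). Default 24/103.
#' @param location_probs lesion-location probabilities
#'   (proximal/middle/distal).
#' @param second_stenosis_prob probability of an additional mild serial
#'   lesion on an evaluable vessel.
#' @param seed master integer seed; all patient/stage streams derive from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 40,
                          two_vessel_prob = 10 / 93,
                          lad_single_prob = 74 / 83,
                          stenosis_severity_range = c(30, 90),
                          ischemic_fraction = 0.46,
                          ffr_band_weights_pos = c(22, 25) / 47,
                          ffr_band_weights_neg = c(44, 12) / 56,
                          mbf_normal_mean = 1.5,
                          mbf_normal_sd = 0.2,
                          mbf_noise_sd = 0.15,
                          ffr_measurement_noise_sd = 0.04,
                          voxel_spacing = c(0.625, 0.625, 1.25),
                          lv_inner_radius = 25,
                          lv_outer_radius = 35,
                          sbp_mean = 128, sbp_sd = 14,
                          dbp_mean = 77, dbp_sd = 9,
                          cac_severe_prob = 24 / 103,
                          location_probs = c(proximal = 59, middle = 38,
                                             distal = 6) / 103,
                          second_stenosis_prob = 0.25,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1,
            two_vessel_prob >= 0, two_vessel_prob <= 1,
            length(stenosis_severity_range) == 2,
            stenosis_severity_range[1] >= 30, stenosis_severity_range[2] <= 90,
            stenosis_severity_range[1] <= stenosis_severity_range[2],
            ischemic_fraction >= 0, ischemic_fraction <= 1,
            mbf_normal_mean > 0, mbf_normal_sd >= 0, mbf_noise_sd >= 0,
            ffr_measurement_noise_sd >= 0,
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            lv_outer_radius > lv_inner_radius, lv_inner_radius > 0,
            cac_severe_prob >= 0, cac_severe_prob <= 1,
            abs(sum(location_probs) - 1) < 1e-8)
  structure(cfg, class = "cohort_config")
}

# Empty LV half-shell map on the configured grid: spherical shell centered
# at the origin restricted to y > 0 (the LAD/LCX side; the right-coronary
# wall is omitted). Deterministic given the config.
make_lv_map <- function(config) {
  r_out <- config$lv_outer_radius
  sp <- config$voxel_spacing
  margin <- 2
  x <- seq(-(r_out + margin), r_out + margin, by = sp[1])
  y <- seq(-margin, r_out + margin, by = sp[2])
  z <- seq(-(r_out + margin), r_out + margin, by = sp[3])
  origin <- c(x[1], y[1], z[1])
  d <- c(length(x), length(y), length(z))
  xc <- origin[1] + (seq_len(d[1]) - 0.5) * sp[1]
  yc <- origin[2] + (seq_len(d[2]) - 0.5) * sp[2]
  zc <- origin[3] + (seq_len(d[3]) - 0.5) * sp[3]
  r2 <- outer(outer(xc^2, yc^2, `+`), zc^2, `+`)
  ymat <- array(rep(yc, each = d[1]), dim = d)
  mask <- r2 >= config$lv_inner_radius^2 & r2 <= r_out^2 & ymat > 0
  if (!any(mask)) abort("degenerate LV mask (zero voxels)",
                        class = "ctpffr_domain_error")
  mbf_map(array(0, dim = d), mask, spacing = sp, origin = origin)
}

#' Generate a synthetic left coronary tree
#'
#' Builds a left-main / LAD / LCX skeleton with diagonal and obtuse-marginal
#' branches wrapped around the LV half-shell, radii obeying Murray's law
#' (`r_parent^3 = sum r_child^3`) exactly at every bifurcation, and 1-2
#' stenoses per evaluable vessel with severity drawn from the configured
#' range. Geometry (positions, lengths, root caliber) is jittered per
#' patient under the given seed, so repeated calls are byte-identical.
#'
#' @param config a [cohort_config()].
#' @param patient_seed integer seed for this patient's geometry stream.
#' @return a [coronary_tree()]; evaluable vessels are the stenosed ones.
#' @export
generate_tree <- function(config, patient_seed) {
  withr::with_seed(patient_seed, {
    jit <- function(n, s) runif(n, -s, s)
    scale_r <- exp(rnorm(1, 0, 0.08))
    scale_l <- function(l) l * runif(length(l), 0.85, 1.15)

    pos <- rbind(
      c(0, 5, 48),      # 1 inlet (aortic root side)
      c(0, 12, 40),     # 2 LM bifurcation
      c(18, 25, 22),    # 3 LAD prox/mid junction (D1 takeoff)
      c(26, 28, -2),    # 4 LAD mid/dist junction (D2 takeoff)
      c(18, 26, -26),   # 5 LAD apex outlet
      c(34, 18, 12),    # 6 D1 outlet
      c(38, 20, -12),   # 7 D2 outlet
      c(-20, 24, 20),   # 8 LCX prox junction (OM takeoff)
      c(-28, 26, -10),  # 9 LCX outlet
      c(-36, 18, 6)     # 10 OM1 outlet
    )
    pos[2:10, ] <- pos[2:10, ] + matrix(jit(27, 3), ncol = 3)

    r_root <- 2.0 * scale_r
    taper <- 0.96
    cube <- function(r, f) (r^3 * f)^(1 / 3)
    r_lm <- c(r_root, r_root * taper)
    r_lad1p <- cube(r_lm[2], 0.65); r_lcx1p <- cube(r_lm[2], 0.35)
    r_lad1 <- c(r_lad1p, r_lad1p * taper)
    r_lad2p <- cube(r_lad1[2], 0.75); r_d1p <- cube(r_lad1[2], 0.25)
    r_lad2 <- c(r_lad2p, r_lad2p * taper)
    r_lad3p <- cube(r_lad2[2], 0.78); r_d2p <- cube(r_lad2[2], 0.22)
    r_lcx1 <- c(r_lcx1p, r_lcx1p * taper)
    r_lcx2p <- cube(r_lcx1[2], 0.72); r_om1p <- cube(r_lcx1[2], 0.28)

    seg <- tibble(
      id = 1:9,
      parent = c(1, 2, 3, 4, 3, 4, 2, 8, 8),
      child  = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
      length = scale_l(c(10, 25, 25, 30, 28, 25, 20, 30, 28)),
      r_prox = c(r_lm[1], r_lad1[1], r_lad2[1], r_lad3p, r_d1p, r_d2p,
                 r_lcx1[1], r_lcx2p, r_om1p),
      r_dist = c(r_lm[2], r_lad1[2], r_lad2[2], r_lad3p * taper,
                 r_d1p * taper, r_d2p * taper, r_lcx1[2],
                 r_lcx2p * taper, r_om1p * taper),
      branch = c("LM", "LAD-prox", "LAD-mid", "LAD-dist", "D1", "D2",
                 "LCX-prox", "LCX-dist", "OM1")
    )
    nodes <- tibble(
      id = 1:10, x = pos[, 1], y = pos[, 2], z = pos[, 3],
      r = c(r_root, seg$r_dist[match(2:10, seg$child)])
    )
    outlets <- tibble(node = c(5, 6, 7, 9, 10),
                      label = c("LAD", "diagonal", "diagonal", "LCX", "marginal"),
                      vessel = c("LAD", "LAD", "LAD", "LCX", "LCX"))

    # evaluable vessels for this patient
    vessels <- if (runif(1) < config$two_vessel_prob) {
      c("LAD", "LCX")
    } else if (runif(1) < config$lad_single_prob) "LAD" else "LCX"

    loc_seg <- list(
      LAD = c(proximal = 2, middle = 3, distal = 4),
      LCX = c(proximal = 7, middle = 8, distal = 8)
    )
    sev_range <- config$stenosis_severity_range
    sten <- list()
    for (v in vessels) {
      loc <- sample(names(config$location_probs), 1,
                    prob = config$location_probs)
      sid <- loc_seg[[v]][[loc]]
      len <- runif(1, 8, 14)
      slen <- seg$length[seg$id == sid]
      center <- runif(1, len / 2 + 1, slen - len / 2 - 1)
      sten[[length(sten) + 1]] <- tibble(
        segment = sid, center = center, length = len,
        severity = runif(1, sev_range[1], sev_range[2]),
        vessel = v, location = loc, primary = TRUE
      )
      if (runif(1) < config$second_stenosis_prob) {
        path_segs <- if (v == "LAD") c(2, 3, 4) else c(7, 8)
        open <- setdiff(path_segs, sid)
        if (length(open) > 0) {
          sid2 <- if (length(open) == 1) open else sample(open, 1)
          len2 <- runif(1, 6, 10)
          slen2 <- seg$length[seg$id == sid2]
          sten[[length(sten) + 1]] <- tibble(
            segment = sid2, center = runif(1, len2 / 2 + 1, slen2 - len2 / 2 - 1),
            length = len2,
            severity = runif(1, sev_range[1],
                             min(sev_range[1] + 15, sev_range[2])),
            vessel = v, location = "serial", primary = FALSE
          )
        }
      }
    }
    sten <- dplyr::bind_rows(sten)
    sten$id <- seq_len(nrow(sten))
    coronary_tree(nodes, seg, sten, outlets, inlet = 1L)
  })
}

# Ground-truth fixed point: outlet resistances, outlet pressure ratios and
# the relative-flow coupling g are mutually consistent:
#   R_i = (MAP - Pv) / (V_i * mbf_mean * g_i),  g_i = g(P_i / MAP).
# This is exactly the state whose MBF map, pushed back through the
# territory-flow equations, reproduces the same resistances - which is what
# makes noise-free parameter recovery well-posed.
ground_truth_state <- function(tree, hemo, volumes, mbf_mean,
                               settings = solver_settings(),
                               max_iter = 120, tol = 1e-11) {
  out_nodes <- volumes$outlet
  # the graph topology never changes across iterations; only outlet
  # resistances do, so build once and update in place
  graph <- build_vessel_graph(tree, tibble(outlet = out_nodes, r_hyp = 1),
                              hemo, fine_step = NULL)
  ord <- match(out_nodes, graph$outlets$node)
  g <- rep(1, nrow(volumes))
  r <- f_out <- NULL
  for (it in seq_len(max_iter)) {
    q0 <- volumes$volume_ml * mbf_mean * g
    r <- (hemo$map - hemo$pv) / q0
    graph$outlets$r_hyp[ord] <- r
    sol <- solve_network(graph, hemo$map, settings)
    p_out <- sol$pressures$pressure[match(out_nodes, sol$pressures$node)]
    f_out <- p_out / hemo$map
    g_new <- ffr_flow_coupling(pmin(pmax(f_out, 1e-6), 1))
    delta <- max(abs(g_new - g))
    g <- 0.5 * g + 0.5 * g_new
    if (delta < tol) break
  }
  list(bc = tibble(outlet = out_nodes, r_hyp = r), outlet_ffr = f_out, g = g)
}

# per-vessel noise-free FFR of the fixed-point state, at fine discretization;
# stenosis-free vessels are read at their main outlet (flagged clamped)
ground_truth_ffr <- function(tree, hemo, volumes, mbf_mean,
                             settings = solver_settings(), offset = 20,
                             fine_step = settings$fine_step) {
  st <- ground_truth_state(tree, hemo, volumes, mbf_mean, settings)
  fine <- solve_tree(tree, st$bc, hemo, settings = settings,
                     fine_step = fine_step, offset = offset)
  vessels <- fine$vessels
  open <- setdiff(unique(tree$outlets$vessel), vessels$vessel)
  if (length(open) > 0) {
    extra <- purrr::map_dfr(open, function(v) {
      out <- tree$outlets$node[tree$outlets$label == v]
      p <- fine$solution$pressures$pressure[
        fine$solution$pressures$node == out]
      segs <- tree$segments[match(vessel_path(tree, v), tree$segments$id), ]
      tibble(vessel = v, ffr = p / hemo$map,
             query_arc_mm = sum(segs$length), clamped = TRUE)
    })
    vessels <- dplyr::bind_rows(vessels, extra)
  }
  list(vessels = vessels, outlet_ffr = st$outlet_ffr, g = st$g,
       bc = st$bc, solution = fine$solution, graph = fine$graph)
}

# replace the primary stenosis severity of `vessel` so the noise-free FFR
# hits `target`, clamped to the configured severity range
calibrate_severity <- function(tree, hemo, volumes, mbf_mean, vessel, target,
                               sev_range, settings = solver_settings()) {
  set_sev <- function(s) {
    i <- which(tree$stenoses$vessel == vessel & tree$stenoses$primary)
    tree$stenoses$severity[i] <- s
    tree
  }
  # coarse readout suffices here: loss coefficients are integrated in
  # closed form, so subdivision does not move the pressures
  ffr_of <- function(s) {
    gt <- ground_truth_ffr(set_sev(s), hemo, volumes, mbf_mean, settings,
                           fine_step = NULL)
    gt$vessels$ffr[gt$vessels$vessel == vessel]
  }
  f_lo <- ffr_of(sev_range[1])
  f_hi <- ffr_of(sev_range[2])
  sev <- if (target >= f_lo) {
    sev_range[1]
  } else if (target <= f_hi) {
    sev_range[2]
  } else {
    uniroot(function(s) ffr_of(s) - target,
            lower = sev_range[1], upper = sev_range[2], tol = 0.05)$root
  }
  set_sev(sev)
}

#' Simulate invasive FFR measurement on a synthetic patient
#'
#' Runs the network solver at fine discretization (segment subdivision at
#' the configured step, <= 1 mm by default) with the noise-free ground-truth
#' outlet resistances, reads FFR 20 mm distal to each vessel's most distal
#' stenosis, and adds wire-measurement noise clipped to (0, 1].
#'
#' @param tree a [generate_tree()] result.
#' @param hemo a [hemodynamic_state()].
#' @param config a [cohort_config()].
#' @param seed seed for the measurement-noise stream.
#' @param volumes optional precomputed [territory_volumes()] table; computed
#'   from the config's LV shell when omitted.
#' @param mbf_mean patient remote MBF; defaults to `config$mbf_normal_mean`.
#' @param settings a [solver_settings()].
#' @return tibble: `vessel`, `invasive_ffr` (noisy), `invasive_ffr_true`,
#'   plus attribute tables `outlet_ffr` and `bc` used by the map generator.
#' @export
simulate_invasive_ffr <- function(tree, hemo, config, seed = 1L,
                                  volumes = NULL,
                                  mbf_mean = config$mbf_normal_mean,
                                  settings = solver_settings()) {
  if (is.null(volumes)) {
    map0 <- make_lv_map(config)
    volumes <- territory_volumes(assign_territories(map0, tree), map0)
  }
  gt <- ground_truth_ffr(tree, hemo, volumes, mbf_mean, settings)
  noise <- withr::with_seed(seed,
    rnorm(nrow(gt$vessels), 0, config$ffr_measurement_noise_sd))
  out <- tibble(
    vessel = gt$vessels$vessel,
    invasive_ffr = pmin(pmax(gt$vessels$ffr + noise, 1e-3), 1),
    invasive_ffr_true = gt$vessels$ffr
  )
  attr(out, "outlet_ffr") <- tibble(outlet = volumes$outlet,
                                    ffr = gt$outlet_ffr, g = gt$g)
  attr(out, "bc") <- gt$bc
  out
}

#' Generate a hyperemic MBF map consistent with the ground truth
#'
#' Voxelizes the LV half-shell, assigns ground-truth Voronoi territories on
#' the noise-free tree, and fills each territory with
#' `Normal(mbf_normal_mean * g(FFR), mbf_noise_sd)` truncated at zero,
#' where `g` is the piecewise-linear flow coupling
#' ([ffr_flow_coupling()]) evaluated at the territory outlet's FFR.
#'
#' @param tree a [generate_tree()] result.
#' @param truth a [simulate_invasive_ffr()] result (carries the per-outlet
#'   FFR); alternatively any tibble with a `vessel`/`invasive_ffr` pair, in
#'   which case each outlet inherits its vessel's FFR.
#' @param config a [cohort_config()].
#' @param seed seed for the voxel-noise stream.
#' @param mbf_mean patient remote MBF; defaults to `config$mbf_normal_mean`.
#' @return an [mbf_map()].
#' @export
generate_mbf_map <- function(tree, truth, config, seed = 1L,
                             mbf_mean = config$mbf_normal_mean) {
  map <- make_lv_map(config)
  terr <- assign_territories(map, tree)
  outlet_ffr <- attr(truth, "outlet_ffr")
  if (is.null(outlet_ffr)) {
    v_ffr <- setNames(truth$invasive_ffr, truth$vessel)
    ffr <- ifelse(tree$outlets$vessel %in% names(v_ffr),
                  v_ffr[tree$outlets$vessel], 1)
    outlet_ffr <- tibble(outlet = tree$outlets$node, ffr = ffr)
  }
  g <- ffr_flow_coupling(pmin(pmax(outlet_ffr$ffr, 1e-6), 1))
  mean_of <- setNames(mbf_mean * g, outlet_ffr$outlet)
  idx <- masked_indices(map)
  lab <- terr$labels[idx]
  vals <- mean_of[as.character(lab)]
  if (config$mbf_noise_sd > 0) {
    vals <- withr::with_seed(seed,
      vals + rnorm(length(vals), 0, config$mbf_noise_sd))
  }
  map$values[idx] <- pmax(vals, 0)
  map
}

#' Generate one synthetic patient
#'
#' Draws geometry, cuff pressures and remote MBF; picks a target invasive
#' FFR per evaluable vessel (band weights matching the configured ischemic
#' fraction and FFR strata); calibrates the primary stenosis severity to
#' hit the target within the QCA inclusion range; then simulates the
#' invasive measurement and the perfusion map.
#'
#' @param config a [cohort_config()].
#' @param patient_id patient index (also the per-patient stream index).
#' @param settings a [solver_settings()].
#' @return list: `patient_id`, `tree`, `hemo`, `map`, `truth` (per-vessel
#'   record tibble), `mbf_mean`.
#' @export
generate_patient <- function(config, patient_id,
                             settings = solver_settings()) {
  s <- function(stage) derive_seed(config$seed, patient_id, stage)
  tree <- generate_tree(config, s(1))

  draws <- withr::with_seed(s(2), {
    sbp <- rnorm(1, config$sbp_mean, config$sbp_sd)
    dbp <- rnorm(1, config$dbp_mean, config$dbp_sd)
    dbp <- min(dbp, sbp - 25)
    m <- max(rnorm(1, config$mbf_normal_mean, config$mbf_normal_sd),
             0.5 * config$mbf_normal_mean)
    list(sbp = sbp, dbp = dbp, m = m)
  })
  hemo <- hemodynamic_state(draws$sbp, draws$dbp)

  vessels <- unique(tree$stenoses$vessel[tree$stenoses$primary])
  targets <- withr::with_seed(s(3), {
    vapply(vessels, function(v) {
      if (runif(1) < config$ischemic_fraction) {
        if (runif(1) < config$ffr_band_weights_pos[1]) {
          runif(1, 0.50, 0.70)
        } else runif(1, 0.70, 0.795)
      } else {
        if (runif(1) < config$ffr_band_weights_neg[1]) {
          runif(1, 0.805, 0.90)
        } else runif(1, 0.90, 0.98)
      }
    }, numeric(1))
  })

  map0 <- make_lv_map(config)
  volumes <- territory_volumes(assign_territories(map0, tree), map0)
  for (k in seq_along(vessels)) {
    tree <- calibrate_severity(tree, hemo, volumes, draws$m, vessels[k],
                               targets[k], config$stenosis_severity_range,
                               settings)
  }

  truth <- simulate_invasive_ffr(tree, hemo, config, seed = s(4),
                                 volumes = volumes, mbf_mean = draws$m,
                                 settings = settings)
  outlet_ffr <- attr(truth, "outlet_ffr")
  truth <- truth[truth$vessel %in% vessels, ]   # evaluable vessels only
  labels <- withr::with_seed(s(5), {
    prim <- tree$stenoses[tree$stenoses$primary, ]
    tibble(
      vessel = prim$vessel,
      qca_percent = prim$severity,
      lesion_location = prim$location,
      cac_class = ifelse(runif(nrow(prim)) < config$cac_severe_prob,
                         ">=400", "<400")
    )
  })
  truth <- dplyr::left_join(truth, labels, by = "vessel")
  truth$patient_id <- patient_id
  truth$vessel_name <- truth$vessel
  attr(truth, "outlet_ffr") <- outlet_ffr

  map <- generate_mbf_map(tree, truth, config, seed = s(6),
                          mbf_mean = draws$m)
  list(patient_id = patient_id, tree = tree, hemo = hemo, map = map,
       truth = truth, mbf_mean = draws$m)
}

#' Simulate a whole synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param settings a [solver_settings()].
#' @return list: `patients` (list of [generate_patient()] results) and
#'   `records` (per-vessel ground-truth tibble across the cohort).
#' @export
simulate_cohort <- function(config, settings = solver_settings()) {
  patients <- purrr::map(seq_len(config$n_patients), function(i) {
    generate_patient(config, i, settings)
  })
  records <- purrr::map_dfr(patients, "truth")
  list(patients = patients, records = records)
}

#' Compute CTP-FFR for one patient from map-derived boundary conditions
#'
#' The analysis stage of the pipeline: Voronoi territories on the MBF map,
#' territory perfusion integrals to outlet flows, outlet resistances from
#' the arteriovenous gradient, network solve at MAP, and per-vessel FFR
#' read 20 mm distal to the most distal lesion. With `map_kind = "k1"` the
#' voxel values are first inverted from K1 to MBF through the Renkin-Crone
#' relation (per-gram, using the configured tissue density).
#'
#' @param tree a [coronary_tree()].
#' @param map an [mbf_map()].
#' @param hemo a [hemodynamic_state()].
#' @param settings a [solver_settings()].
#' @param offset FFR readout offset, mm. Default 20.
#' @param map_kind `"mbf"` (values are MBF) or `"k1"` (values are K1 and are
#'   corrected to MBF first).
#' @param rc_params a [renkin_crone_params()] (used when
#'   `map_kind = "k1"`).
#' @return list: `vessels` (tibble `vessel`, `ctp_ffr`, `query_arc_mm`,
#'   `clamped`), `bc`, `solution`, `territories`.
#' @export
compute_ctp_ffr <- function(tree, map, hemo, settings = solver_settings(),
                            offset = 20, map_kind = c("mbf", "k1"),
                            rc_params = renkin_crone_params()) {
  map_kind <- match.arg(map_kind)
  if (map_kind == "k1") {
    idx <- masked_indices(map)
    k1_g <- map$values[idx] / rc_params$tissue_density  # per-mL -> per-g
    pos <- k1_g > 0
    mbf_g <- k1_g
    mbf_g[pos] <- mbf_from_k1(k1_g[pos], rc_params)
    map$values[idx] <- mbf_g * rc_params$tissue_density
  }
  terr <- assign_territories(map, tree)
  bc <- compute_outlet_bc(terr, map, hemo)
  fit <- solve_tree(tree, bc, hemo, settings = settings,
                    fine_step = settings$fine_step, offset = offset)
  vessels <- dplyr::rename(fit$vessels, ctp_ffr = "ffr")
  list(vessels = vessels, bc = bc, solution = fit$solution,
       territories = terr)
}
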