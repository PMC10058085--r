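#' Patient hemodynamic state
#'
#' Collects the pressures and blood constants that set the network boundary
#' conditions: brachial cuff pressures give the inlet mean aortic pressure
#' (MAP), the venous pressure closes each outlet, and viscosity/density feed
#' the segment loss coefficients.
#'
#' @param sbp,dbp brachial systolic / diastolic pressure, mmHg; `sbp > dbp > 0`.
#' @param pv venous pressure, mmHg. Default 5.
#' @param viscosity blood dynamic viscosity, Pa s. Default 0.0035.
#' @param density blood density, kg m^-3. Default 1050.
#' @return a list of class `hemodynamic_state` with `map` filled in.
#' @export
hemodynamic_state <- function(sbp, dbp, pv = 5, viscosity = 0.0035,
                              density = 1050) {
  map <- mean_aortic_pressure(sbp, dbp)
  if (pv < 0 || pv >= map) {
    abort("`pv` must satisfy 0 <= pv < MAP.", class = "ctpffr_domain_error")
  }
  stopifnot(viscosity > 0, density > 0)
  structure(list(sbp = sbp, dbp = dbp, map = map, pv = pv,
                 viscosity = viscosity, density = density),
            class = "hemodynamic_state")
}

#' Mean aortic pressure from brachial cuff pressures
#'
#' `MAP = 0.4 * (SBP - DBP) + DBP`, a fixed convex combination, so MAP always
#' lies between the diastolic and systolic pressures.
#'
#' @param sbp,dbp systolic / diastolic pressure, mmHg; vectorized.
#' @return MAP in mmHg.
#' @export
mean_aortic_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp <= dbp)) {
    abort("require SBP > DBP > 0.", class = "ctpffr_domain_error")
  }
  0.4 * (sbp - dbp) + dbp
}

#' Hyperemic flow of one outlet's territory
#'
#' The outlet flow is the perfusion integral over its territory,
#' `Q = sum_n Vol_n * MBF_n`, with voxel volume in mL and MBF in
#' mL min^-1 mL^-1, so Q is in mL min^-1.
#'
#' @param territories a [assign_territories()] result.
#' @param map the matching [mbf_map()].
#' @param outlet outlet node id.
#' @return flow in mL min^-1.
#' @export
outlet_flow <- function(territories, map, outlet) {
  sel <- !is.na(territories$labels) & territories$labels == outlet
  if (!any(sel)) {
    abort(sprintf("outlet %s has an empty territory", outlet),
          class = "ctpffr_empty_territory")
  }
  sum(map$values[sel]) * voxel_volume_ml(map)
}

#' Lumped outlet resistance from the perfusion pressure gradient
#'
#' `R = (MAP - Pv) / Q`: the downstream microvascular bed is collapsed to
#' the single resistance that would carry the territory's hyperemic flow
#' under the full arteriovenous gradient.
#'
#' @param map_pressure mean aortic pressure, mmHg.
#' @param pv venous pressure, mmHg; `map_pressure > pv`.
#' @param q hyperemic outlet flow, mL min^-1; positive.
#' @return resistance in mmHg min mL^-1.
#' @export
outlet_resistance <- function(map_pressure, pv, q) {
  if (any(q <= 0)) {
    abort("outlet flow must be > 0 (zero-flow territory).",
          class = "ctpffr_domain_error")
  }
  if (any(map_pressure <= pv)) {
    abort("require MAP > Pv (non-physical gradient).",
          class = "ctpffr_domain_error")
  }
  (map_pressure - pv) / q
}

#' Outlet boundary-condition table for a whole tree
#'
#' Combines the territory perfusion integrals with the arteriovenous
#' gradient to produce one hyperemic flow and resistance per outlet. Outlets
#' whose territory flow is zero (fully infarcted synthetic territory) are
#' flagged and assigned `r_ceiling` instead of an infinite resistance so the
#' network stays solvable.
#'
#' @param territories a [assign_territories()] result.
#' @param map the matching [mbf_map()].
#' @param hemo a [hemodynamic_state()].
#' @param r_ceiling resistance assigned to zero-flow outlets,
#'   mmHg min mL^-1. Default 1e6.
#' @return tibble: `outlet`, `label`, `n_voxels`, `volume_ml`, `q_hyp`
#'   (mL min^-1), `r_hyp` (mmHg min mL^-1), `zero_flow` (logical).
#' @export
compute_outlet_bc <- function(territories, map, hemo, r_ceiling = 1e6) {
  vols <- territory_volumes(territories, map)
  q <- vapply(vols$outlet, function(o) {
    sel <- !is.na(territories$labels) & territories$labels == o
    if (!any(sel)) return(0) else sum(map$values[sel]) * voxel_volume_ml(map)
  }, numeric(1))
  zero <- q <= 0
  if (any(zero)) {
    warn(sprintf("%d outlet(s) with zero territory flow assigned the resistance ceiling",
                 sum(zero)))
  }
  r <- ifelse(zero, r_ceiling, (hemo$map - hemo$pv) / pmax(q, .Machine$double.xmin))
  tibble(outlet = vols$outlet,
         label = territories$outlets$label[match(vols$outlet, territories$outlets$node)],
         n_voxels = vols$n_voxels, volume_ml = vols$volume_ml,
         q_hyp = q, r_hyp = r, zero_flow = zero)
}

#' Effective radiation dose from dose-length product
#'
#' @param dlp dose-length product, mGy cm; non-negative, vectorized.
#' @param k conversion coefficient, mSv mGy^-1 cm^-1. Default 0.014.
#' @return effective dose in mSv.
#' @export
effective_dose <- function(dlp, k = 0.014) {
  if (any(dlp < 0)) abort("`dlp` must be >= 0.", class = "ctpffr_domain_error")
  k * dlp
}
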