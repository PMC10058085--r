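# Closed-form Poiseuille integral over a linearly tapered piece:
# int ds / r(s)^4 with r from r1 to r2 over length len (all meters).
taper_integral <- function(len, r1, r2) {
  ifelse(abs(r2 - r1) < 1e-12 * pmax(r1, r2),
         len / r1^4,
         len / (3 * (r2 - r1)) * (1 / r1^3 - 1 / r2^3))
}

# Loss coefficients of (a prefix of) one segment.
#
# The radius profile is a linear taper r_prox -> r_dist with, inside a
# stenosis, a constant throat r_t = (1 - severity/100) * r_ref(center)
# (top-hat narrowing). The viscous coefficient integrates Poiseuille
# resistance through that profile; the quadratic (Young-Tsai) expansion loss
# b = (K_t rho / 2) (1/A_throat - 1/A_ref)^2 is charged where the flow exits
# the throat, so a prefix ending inside the stenosis carries no b.
# Returns clinical units (mmHg min mL^-1; mmHg min^2 mL^-2).
segment_loss_coeffs <- function(len, r_prox, r_dist, stenosis, blood,
                                upto = NULL, k_t = 1.52) {
  upto <- upto %||% len
  stopifnot(len > 0, r_prox > 0, r_dist > 0, upto >= 0, upto <= len)
  if (upto == 0) return(list(a = 0, b = 0))
  r_at <- function(s) r_prox + (r_dist - r_prox) * s / len
  pieces <- c(0, upto)
  b_si <- 0
  throat <- NULL
  if (!is.null(stenosis) && stenosis$severity > 0) {
    s1 <- stenosis$center - stenosis$length / 2
    s2 <- stenosis$center + stenosis$length / 2
    r_ref <- r_at(stenosis$center)
    throat <- list(s1 = s1, s2 = s2,
                   r = (1 - stenosis$severity / 100) * r_ref, r_ref = r_ref)
    pieces <- sort(unique(pmin(pmax(c(0, s1, s2, upto), 0), upto)))
    if (s2 <= upto) {
      a_th <- pi * throat$r^2 * 1e-6    # mm^2 -> m^2
      a_ref <- pi * r_ref^2 * 1e-6
      b_si <- k_t * blood$density / 2 * (1 / a_th - 1 / a_ref)^2
    }
  }
  integral <- 0
  for (i in seq_len(length(pieces) - 1)) {
    lo <- pieces[i]; hi <- pieces[i + 1]
    if (hi <= lo) next
    mid <- (lo + hi) / 2
    if (!is.null(throat) && mid > throat$s1 && mid < throat$s2) {
      r1 <- r2 <- throat$r
    } else {
      r1 <- r_at(lo); r2 <- r_at(hi)
    }
    integral <- integral + taper_integral((hi - lo) * 1e-3, r1 * 1e-3, r2 * 1e-3)
  }
  a_si <- 8 * blood$viscosity / pi * integral
  list(a = si_to_clinical_a(a_si), b = si_to_clinical_b(b_si))
}

#' Reduced-order loss coefficients of a vessel segment
#'
#' Returns the coefficients of the segment's pressure-drop law
#' `dP(Q) = a Q + b Q |Q|` (clinical units): `a` is the Poiseuille
#' resistance `8 mu L / (pi r^4)` integrated through the local radius
#' profile (the throat radius inside a stenosis), and for a stenotic
#' segment `b` is the empirical expansion loss
#' `(K_t rho / 2) (1/A_throat - 1/A_ref)^2` with `K_t = 1.52`.
#'
#' @param length segment length, mm.
#' @param radius reference radius, mm; either a scalar or
#'   `c(r_prox, r_dist)` for a linear taper.
#' @param stenosis optional list with `center`, `length` (mm, arc length
#'   from the proximal end) and `severity` (% diameter reduction).
#' @param blood a [hemodynamic_state()] (viscosity and density are used).
#' @param k_t empirical expansion-loss constant. Default 1.52.
#' @return list `a` (mmHg min mL^-1), `b` (mmHg min^2 mL^-2).
#' @export
segment_coefficients <- function(length, radius, stenosis = NULL,
                                 blood = hemodynamic_state(120, 80),
                                 k_t = 1.52) {
  if (length <= 0 || any(radius <= 0)) {
    abort("segment length and radius must be > 0", class = "ctpffr_domain_error")
  }
  r2 <- if (base::length(radius) == 2) radius else c(radius, radius)
  segment_loss_coeffs(length, r2[1], r2[2], stenosis, blood, k_t = k_t)
}

#' Build the solvable flow network from a coronary tree
#'
#' Discretizes every segment into sub-edges (split at stenosis boundaries
#' and, optionally, at a regular arc-length step), computes the loss
#' coefficients of each sub-edge, and attaches each outlet's hyperemic
#' resistance. Loss coefficients are integrated in closed form, so the
#' discretization step changes where pressures are tabulated but not their
#' values.
#'
#' @param tree a [coronary_tree()].
#' @param bc outlet boundary-condition table from [compute_outlet_bc()], or
#'   any tibble with columns `outlet` and `r_hyp` covering all outlets.
#' @param hemo a [hemodynamic_state()].
#' @param fine_step optional discretization step in mm (e.g. 1 for the
#'   fine ground-truth solve); `NULL` keeps one edge per stenosis-free run.
#' @return an object of class `vessel_graph`.
#' @export
build_vessel_graph <- function(tree, bc, hemo, fine_step = NULL) {
  validate_tree(tree)
  if (!all(tree$outlets$node %in% bc$outlet)) {
    abort("`bc` must provide r_hyp for every outlet", class = "ctpffr_domain_error")
  }
  next_id <- max(tree$nodes$id) + 1L
  e_from <- e_to <- e_seg <- integer(0)
  e_s0 <- e_s1 <- e_a <- e_b <- numeric(0)
  for (i in seq_len(nrow(tree$segments))) {
    seg <- tree$segments[i, ]
    sten <- tree$stenoses[tree$stenoses$segment == seg$id, ]
    if (nrow(sten) > 1) {
      abort("at most one stenosis per segment is supported; place serial lesions on distinct segments",
            class = "ctpffr_tree_error")
    }
    sten <- if (nrow(sten) == 1) as.list(sten[1, ]) else NULL
    breaks <- c(0, seg$length)
    if (!is.null(fine_step) && is.finite(fine_step) && fine_step > 0) {
      breaks <- c(breaks, seq(0, seg$length, by = fine_step))
    }
    if (!is.null(sten)) {
      breaks <- c(breaks, sten$center - sten$length / 2, sten$center + sten$length / 2)
    }
    breaks <- sort(unique(pmin(pmax(breaks, 0), seg$length)))
    breaks <- breaks[c(TRUE, diff(breaks) > 1e-9)]
    n_sub <- length(breaks) - 1
    sub_nodes <- if (n_sub > 1) next_id + seq_len(n_sub - 1) - 1L else integer(0)
    next_id <- next_id + max(0L, n_sub - 1L)
    node_seq <- c(seg$parent, sub_nodes, seg$child)
    co <- lapply(breaks, function(u)
      segment_loss_coeffs(seg$length, seg$r_prox, seg$r_dist, sten,
                          blood = hemo, upto = u))
    aa <- vapply(co, `[[`, numeric(1), "a")
    bb <- vapply(co, `[[`, numeric(1), "b")
    e_from <- c(e_from, node_seq[seq_len(n_sub)])
    e_to <- c(e_to, node_seq[seq_len(n_sub) + 1])
    e_seg <- c(e_seg, rep(seg$id, n_sub))
    e_s0 <- c(e_s0, breaks[-length(breaks)])
    e_s1 <- c(e_s1, breaks[-1])
    e_a <- c(e_a, diff(aa))
    e_b <- c(e_b, diff(bb))
  }
  edges <- tibble::new_tibble(
    list(from = e_from, to = e_to, segment = e_seg,
         s0 = e_s0, s1 = e_s1, a = e_a, b = e_b),
    nrow = length(e_from))
  outlets <- dplyr::left_join(tree$outlets, bc[, c("outlet", "r_hyp")],
                              by = c(node = "outlet"))
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$from, edges$to))),
         inlet = tree$inlet,
         outlets = outlets,
         pv = hemo$pv,
         tree = tree),
    class = "vessel_graph"
  )
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges, %d resistive outlets (Pv = %g mmHg)\n",
              length(x$nodes), nrow(x$edges), nrow(x$outlets), x$pv))
  invisible(x)
}
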