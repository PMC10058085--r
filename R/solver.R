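#' Solver settings
#'
#' @param tolerance convergence tolerance, mmHg-equivalent nodal residual
#'   (converted internally to a flow imbalance through the total outlet
#'   conductance). Default 1e-8.
#' @param max_iterations Newton iteration cap. Default 200.
#' @param relaxation under-relaxation factor in (0, 1] applied to the early
#'   Newton steps; full steps are restored near the solution so the
#'   iteration finishes quadratically. Default 0.7.
#' @param fine_step discretization step (mm) used by the fine ground-truth
#'   solve. Default 1.
#' @return a list of class `solver_settings`.
#' @export
solver_settings <- function(tolerance = 1e-8, max_iterations = 200,
                            relaxation = 0.7, fine_step = 1) {
  stopifnot(tolerance > 0, max_iterations >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(tolerance = tolerance, max_iterations = max_iterations,
                 relaxation = relaxation, fine_step = fine_step),
            class = "solver_settings")
}

# flow through one edge given the pressure drop d and dP(Q) = a Q + b Q|Q|
edge_flow <- function(d, a, b) {
  a <- pmax(a, 1e-12)   # zero-loss edges get a vanishing resistance floor
  ifelse(b > 0,
         sign(d) * (-a + sqrt(a^2 + 4 * b * abs(d))) / (2 * pmax(b, .Machine$double.xmin)),
         d / a)
}

#' Solve steady flow on a coronary network
#'
#' Enforces mass conservation at every node by damped Newton iteration on
#' the nodal pressures: the inlet is pinned at the mean aortic pressure,
#' every other node balances the flows of its incident edges
#' (`dP = a Q + b Q|Q|`), and each outlet discharges through its hyperemic
#' resistance to the venous pressure. The Jacobian is the weighted network
#' Laplacian with linearized edge conductances `1/(a + 2 b |Q|)`, so the
#' iteration is globally stable for this monotone resistor class; steps that
#' increase the residual are halved.
#'
#' @param graph a [build_vessel_graph()] result.
#' @param inlet_pressure inlet pressure (MAP), mmHg.
#' @param settings a [solver_settings()].
#' @return an object of class `ffr_solution`: `pressures` (tibble `node`,
#'   `pressure`), `flows` (tibble `from`, `to`, `segment`, `s0`, `s1`, `q`),
#'   `outlet_flows`, `inlet_flow`, `inlet_pressure` and `convergence`.
#' @export
solve_network <- function(graph, inlet_pressure,
                          settings = solver_settings()) {
  if (any(is.na(graph$outlets$r_hyp)) || any(graph$outlets$r_hyp <= 0)) {
    abort("all outlet resistances must be set and > 0",
          class = "ctpffr_domain_error")
  }
  nodes <- graph$nodes
  n <- length(nodes)
  ei0 <- match(graph$edges$from, nodes)
  ej0 <- match(graph$edges$to, nodes)
  a0 <- graph$edges$a
  b0 <- graph$edges$b
  out_i0 <- match(graph$outlets$node, nodes)
  g_out <- 1 / graph$outlets$r_hyp
  inlet0 <- match(graph$inlet, nodes)

  # lossless edges (a = b = 0) would make the Jacobian singular at machine
  # precision; both endpoints share one pressure, so contract them
  zero <- a0 <= 0 & b0 <= 0
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in which(zero)) {
    ru <- find(ei0[k]); rv <- find(ej0[k])
    if (ru != rv) parent[max(ru, rv)] <- min(ru, rv)
  }
  rep_idx <- vapply(seq_len(n), find, integer(1))
  ur <- sort(unique(rep_idx))
  comp <- match(rep_idx, ur)
  m <- length(ur)
  ei <- comp[ei0[!zero]]; ej <- comp[ej0[!zero]]
  a <- a0[!zero]; b <- b0[!zero]
  out_c <- comp[out_i0]
  inlet <- comp[inlet0]
  free <- setdiff(seq_len(m), inlet)

  # mmHg tolerance -> flow imbalance through the total outlet conductance
  tol_flow <- settings$tolerance * sum(g_out)

  p <- rep(inlet_pressure, m)
  residual <- function(p) {
    q <- edge_flow(p[ei] - p[ej], a, b)
    f <- tapply_add(q, ej, m) - tapply_add(q, ei, m) -
      tapply_add((p[out_c] - graph$pv) * g_out, out_c, m)
    list(f = f, q = q)
  }
  res <- residual(p)
  hist <- numeric(0)
  converged <- length(free) == 0
  best <- Inf
  stall <- 0L
  for (iter in seq_len(settings$max_iterations)) {
    if (length(free) == 0) break
    rmax <- max(abs(res$f[free]))
    hist <- c(hist, rmax)
    if (rmax <= tol_flow) { converged <- TRUE; break }
    # rounding floor: on stiff (finely subdivided) networks the nodal
    # imbalance bottoms out above the conductance-scaled tolerance; accept
    # once progress stops provided the imbalance is negligible against the
    # flows being balanced
    stall <- if (rmax >= 0.99 * best) stall + 1L else 0L
    best <- min(best, rmax)
    if (stall >= 5L && rmax <= 1e-9 * max(abs(res$q), 1)) {
      converged <- TRUE
      break
    }
    g_edge <- 1 / pmax(pmax(a, 1e-12) + 2 * b * abs(res$q), 1e-10)
    J <- matrix(0, m, m)
    for (k in seq_along(ei)) {
      u <- ei[k]; v <- ej[k]; g <- g_edge[k]
      J[u, u] <- J[u, u] + g; J[v, v] <- J[v, v] + g
      J[u, v] <- J[u, v] - g; J[v, u] <- J[v, u] - g
    }
    diag(J) <- diag(J) + tapply_add(g_out, out_c, m)
    delta <- solve(J[free, free, drop = FALSE], res$f[free])
    relax <- if (rmax > 1e3 * tol_flow) settings$relaxation else 1
    step <- relax
    repeat {
      p_new <- p
      p_new[free] <- p[free] + step * delta
      res_new <- residual(p_new)
      if (max(abs(res_new$f[free])) <= rmax || step < 1e-4) break
      step <- step / 2
    }
    p <- p_new
    res <- res_new
  }
  if (!converged) {
    abort("network solve did not converge", class = "ctpffr_solver_error",
          residual_history = hist)
  }

  p_full <- p[comp]
  outlet_q <- (p_full[out_i0] - graph$pv) * g_out

  # edge flows: pressure-law for lossy edges; lossless (contracted) edges
  # carry the accumulated downstream demand of their distal node
  q_all <- numeric(length(ei0))
  q_all[!zero] <- res$q
  if (any(zero)) {
    depth <- rep(NA_integer_, n)
    depth[inlet0] <- 0L
    frontier <- inlet0
    while (length(frontier) > 0) {
      hit <- ei0 %in% frontier & is.na(depth[ej0])
      depth[ej0[hit]] <- depth[ei0[hit]] + 1L
      frontier <- ej0[hit]
    }
    disch <- tapply_add(outlet_q, out_i0, n)
    for (k in order(depth[ej0], decreasing = TRUE)) {
      if (!zero[k]) next
      v <- ej0[k]
      q_all[k] <- disch[v] + sum(q_all[ei0 == v])
    }
  }
  q_inlet <- sum(q_all[ei0 == inlet0]) - sum(q_all[ej0 == inlet0])

  nr <- function(l) tibble::new_tibble(l, nrow = length(l[[1]]))
  structure(
    list(
      pressures = nr(list(node = nodes, pressure = p_full)),
      flows = nr(list(from = graph$edges$from, to = graph$edges$to,
                      segment = graph$edges$segment,
                      s0 = graph$edges$s0, s1 = graph$edges$s1, q = q_all)),
      outlet_flows = nr(list(outlet = graph$outlets$node,
                             label = graph$outlets$label,
                             q = outlet_q)),
      inlet_flow = q_inlet,
      inlet_pressure = inlet_pressure,
      convergence = list(iterations = length(hist),
                         residual = if (length(hist)) hist[length(hist)] else 0,
                         tol_flow = tol_flow, converged = TRUE,
                         history = hist)
    ),
    class = "ffr_solution"
  )
}

# scatter-add x into n bins given integer index
tapply_add <- function(x, index, n) {
  out <- numeric(n)
  if (length(x) == 0) return(out)
  s <- rowsum(x, group = index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.ffr_solution <- function(x, ...) {
  cat(sprintf("<ffr_solution> inlet %.1f mmHg, inlet flow %.1f mL/min; %d Newton iterations (residual %.2e)\n",
              x$inlet_pressure, x$inlet_flow,
              x$convergence$iterations, x$convergence$residual))
  invisible(x)
}

#' FFR at a point distal to a stenosis
#'
#' Reads the pressure ratio `P(query)/P(inlet)` at the point `offset` mm
#' distal to the stenosis exit along the root-to-outlet path of the
#' stenosed vessel, mirroring the invasive convention of parking the
#' pressure wire 20 mm beyond the lesion. If the path ends before the
#' offset, the most distal point is used and flagged.
#'
#' @param solution a [solve_network()] result.
#' @param graph the [build_vessel_graph()] the solution came from.
#' @param stenosis stenosis id (row of `tree$stenoses`).
#' @param offset distal offset in mm. Default 20.
#' @return list: `ffr`, `pressure` (mmHg), `arc_mm` (query arc length from
#'   the root), `clamped` (logical).
#' @export
ffr_at <- function(solution, graph, stenosis, offset = 20) {
  tree <- graph$tree
  st <- tree$stenoses[tree$stenoses$id == stenosis, ]
  if (nrow(st) != 1) {
    abort(sprintf("unknown stenosis id %s", stenosis), class = "ctpffr_domain_error")
  }
  path <- vessel_path(tree, st$vessel)
  segs <- tree$segments[match(path, tree$segments$id), ]
  if (!st$segment %in% path) {
    abort("stenosis does not lie on its vessel's main path",
          class = "ctpffr_tree_error")
  }
  arc0 <- cumsum(c(0, segs$length))  # arc at each segment's proximal end
  k_st <- match(st$segment, path)
  target <- arc0[k_st] + st$center + st$length / 2 + offset
  total <- arc0[length(arc0)]
  clamped <- target >= total
  target <- min(target, total)
  k <- max(1, findInterval(min(target, total - 1e-12), arc0, rightmost.closed = TRUE))
  k <- min(k, nrow(segs))
  s_local <- min(max(target - arc0[k], 0), segs$length[k])
  seg <- segs[k, ]
  sten_k <- tree$stenoses[tree$stenoses$segment == seg$id, ]
  sten_k <- if (nrow(sten_k) == 1) as.list(sten_k[1, ]) else NULL
  q_seg <- solution$flows$q[solution$flows$segment == seg$id][1]
  hemo_like <- list(viscosity = graph_viscosity(graph), density = graph_density(graph))
  co <- segment_loss_coeffs(seg$length, seg$r_prox, seg$r_dist, sten_k,
                            blood = hemo_like, upto = s_local)
  p_prox <- solution$pressures$pressure[solution$pressures$node == seg$parent]
  p <- p_prox - (co$a * q_seg + co$b * q_seg * abs(q_seg))
  list(ffr = p / solution$inlet_pressure, pressure = p,
       arc_mm = target, clamped = clamped)
}

# blood constants are needed again at readout; the graph caches them
graph_viscosity <- function(graph) attr(graph, "viscosity") %||% 0.0035
graph_density <- function(graph) attr(graph, "density") %||% 1050

#' Per-vessel CTP-FFR readout
#'
#' For each evaluable vessel with at least one stenosis, reads FFR at
#' `offset` mm distal to the most distal stenosis on the vessel's main
#' path (serial lesions are thus assessed jointly, as a pressure wire
#' would).
#'
#' @inheritParams ffr_at
#' @return tibble: `vessel`, `ffr`, `query_arc_mm`, `clamped`.
#' @export
compute_vessel_ffr <- function(solution, graph, offset = 20) {
  tree <- graph$tree
  if (nrow(tree$stenoses) == 0) {
    return(tibble(vessel = character(), ffr = numeric(),
                  query_arc_mm = numeric(), clamped = logical()))
  }
  purrr::map_dfr(unique(tree$stenoses$vessel), function(v) {
    st <- tree$stenoses[tree$stenoses$vessel == v, ]
    path <- vessel_path(tree, v)
    segs <- tree$segments[match(path, tree$segments$id), ]
    arc0 <- cumsum(c(0, segs$length))
    ends <- arc0[match(st$segment, path)] + st$center + st$length / 2
    distal <- st$id[which.max(ends)]
    r <- ffr_at(solution, graph, distal, offset = offset)
    tibble(vessel = v, ffr = r$ffr, query_arc_mm = r$arc_mm,
           clamped = r$clamped)
  })
}

#' One-call network solve for a tree with boundary conditions
#'
#' Builds the graph, solves it at the patient's MAP and reads per-vessel
#' FFR.
#'
#' @param tree a [coronary_tree()].
#' @param bc outlet BC table ([compute_outlet_bc()]).
#' @param hemo a [hemodynamic_state()].
#' @param settings a [solver_settings()].
#' @param fine_step optional discretization step, mm.
#' @param offset FFR readout offset distal to the lesion, mm. Default 20.
#' @return list: `solution` ([solve_network()]), `graph`, `vessels`
#'   (per-vessel FFR tibble).
#' @export
solve_tree <- function(tree, bc, hemo, settings = solver_settings(),
                       fine_step = NULL, offset = 20) {
  graph <- build_vessel_graph(tree, bc, hemo, fine_step = fine_step)
  attr(graph, "viscosity") <- hemo$viscosity
  attr(graph, "density") <- hemo$density
  solution <- solve_network(graph, hemo$map, settings)
  list(solution = solution, graph = graph,
       vessels = compute_vessel_ffr(solution, graph, offset = offset))
}
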