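# Fixtures are built in code; nothing is stored on disk.

# single straight tube: root -> outlet, optionally stenosed
tube_tree <- function(length = 60, radius = 2, severity = NULL,
                      sten_center = 25, sten_length = 10) {
  sten <- if (is.null(severity)) {
    tibble::tibble(id = integer(), segment = integer(), center = numeric(),
                   length = numeric(), severity = numeric(),
                   vessel = character(), location = character())
  } else {
    tibble::tibble(id = 1L, segment = 1L, center = sten_center,
                   length = sten_length, severity = severity,
                   vessel = "LAD", location = "proximal")
  }
  coronary_tree(
    nodes = tibble::tibble(id = 1:2, x = c(0, 0), y = c(0, 0),
                           z = c(0, -length), r = radius),
    segments = tibble::tibble(id = 1L, parent = 1L, child = 2L,
                              length = length, r_prox = radius,
                              r_dist = radius, branch = "LAD"),
    stenoses = sten,
    outlets = tibble::tibble(node = 2L, label = "LAD", vessel = "LAD"),
    inlet = 1L
  )
}

# symmetric bifurcation: root - stem - two identical children
bifurcation_tree <- function(r_stem = 2, child_frac = 0.5) {
  rc <- (r_stem^3 * child_frac)^(1 / 3)
  coronary_tree(
    nodes = tibble::tibble(id = 1:4,
                           x = c(0, 0, -10, 10), y = c(0, 0, 5, 5),
                           z = c(0, -20, -40, -40),
                           r = c(r_stem, r_stem, rc, rc)),
    segments = tibble::tibble(id = 1:3, parent = c(1, 2, 2),
                              child = c(2, 3, 4),
                              length = c(20, 25, 25),
                              r_prox = c(r_stem, rc, rc),
                              r_dist = c(r_stem, rc, rc),
                              branch = c("LM", "LAD", "LCX")),
    stenoses = tibble::tibble(id = integer(), segment = integer(),
                              center = numeric(), length = numeric(),
                              severity = numeric(), vessel = character(),
                              location = character()),
    outlets = tibble::tibble(node = c(3L, 4L), label = c("LAD", "LCX"),
                             vessel = c("LAD", "LCX")),
    inlet = 1L
  )
}

# star tree with n_leaf terminals at the given positions (for Voronoi tests)
star_tree <- function(positions) {
  n <- nrow(positions)
  leaf_ids <- seq_len(n) + 2L
  coronary_tree(
    nodes = tibble::tibble(id = c(1:2, leaf_ids),
                           x = c(0, 0, positions[, 1]),
                           y = c(0, 0, positions[, 2]),
                           z = c(50, 40, positions[, 3]),
                           r = c(2, 2, rep(1, n))),
    segments = tibble::tibble(id = seq_len(n + 1),
                              parent = c(1L, rep(2L, n)),
                              child = c(2L, leaf_ids),
                              length = 20,
                              r_prox = c(2, rep(2 / n^(1 / 3), n)),
                              r_dist = c(2, rep(2 / n^(1 / 3), n)),
                              branch = c("LM", paste0("B", seq_len(n)))),
    stenoses = tibble::tibble(id = integer(), segment = integer(),
                              center = numeric(), length = numeric(),
                              severity = numeric(), vessel = character(),
                              location = character()),
    outlets = tibble::tibble(node = leaf_ids,
                             label = paste0("B", seq_len(n)),
                             vessel = "LAD"),
    inlet = 1L
  )
}

# small uniform map: full-cube mask with constant MBF
uniform_map <- function(value = 1, dims = c(10, 10, 6),
                        spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mbf_map(array(value, dim = dims), array(TRUE, dim = dims),
          spacing = spacing, origin = origin)
}

# exhaustive per-voxel nearest-seed search (independent Voronoi oracle)
brute_voronoi <- function(map, tree) {
  outlets <- tree$outlets[order(tree$outlets$node), ]
  seeds <- tree$nodes[match(outlets$node, tree$nodes$id), c("x", "y", "z")]
  labels <- array(NA_integer_, dim = dim(map$mask))
  d <- dim(map$mask)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!map$mask[i, j, k]) next
    ctr <- map$origin + (c(i, j, k) - 0.5) * map$spacing
    dist <- sqrt((seeds$x - ctr[1])^2 + (seeds$y - ctr[2])^2 +
                   (seeds$z - ctr[3])^2)
    labels[i, j, k] <- outlets$node[which.min(dist)]  # first minimum
  }
  labels
}

# exhaustive pair-counting AUC oracle (lower score = positive)
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p < n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# exact linear-network solution by direct elimination (b = 0 everywhere)
linear_network_oracle <- function(graph, inlet_pressure) {
  nodes <- graph$nodes
  n <- length(nodes)
  pos <- function(id) match(id, nodes)
  G <- matrix(0, n, n)
  rhs <- rep(0, n)
  for (k in seq_len(nrow(graph$edges))) {
    u <- pos(graph$edges$from[k]); v <- pos(graph$edges$to[k])
    g <- 1 / graph$edges$a[k]
    G[u, u] <- G[u, u] + g; G[v, v] <- G[v, v] + g
    G[u, v] <- G[u, v] - g; G[v, u] <- G[v, u] - g
  }
  for (k in seq_len(nrow(graph$outlets))) {
    o <- pos(graph$outlets$node[k]); g <- 1 / graph$outlets$r_hyp[k]
    G[o, o] <- G[o, o] + g
    rhs[o] <- rhs[o] + g * graph$pv
  }
  inlet <- pos(graph$inlet)
  free <- setdiff(seq_len(n), inlet)
  rhs[free] <- rhs[free] - G[free, inlet] * inlet_pressure
  p <- rep(inlet_pressure, n)
  p[free] <- solve(G[free, free, drop = FALSE], rhs[free])
  tibble::tibble(node = nodes, pressure = p)
}

# reconstruct a per-vessel record table realizing given band counts:
# (correct, total) per invasive-FFR band, index readings placed just on the
# appropriate side of the 0.80 cutoff
banded_records <- function(bands = list(
                             c(correct = 22, n = 22, lo = 0.50, hi = 0.70),
                             c(correct = 19, n = 25, lo = 0.705, hi = 0.80),
                             c(correct = 37, n = 44, lo = 0.805, hi = 0.90),
                             c(correct = 12, n = 12, lo = 0.905, hi = 0.98))) {
  rows <- lapply(bands, function(bd) {
    ffr <- seq(bd[["lo"]], bd[["hi"]], length.out = bd[["n"]])
    positive <- ffr <= 0.80
    correct <- c(rep(TRUE, bd[["correct"]]),
                 rep(FALSE, bd[["n"]] - bd[["correct"]]))
    ctp <- ifelse(positive == correct, 0.70, 0.85)  # agree when correct
    tibble::tibble(invasive_ffr = ffr, ctp_ffr = ctp)
  })
  out <- dplyr::bind_rows(rows)
  out$vessel_name <- "LAD"
  out$patient_id <- seq_len(nrow(out))
  out
}

# shared slow fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small, fast cohort configuration for pipeline-level tests: a coarser,
# smaller LV so each patient takes a fraction of a second
fast_config <- function(...) {
  cohort_config(lv_inner_radius = 12, lv_outer_radius = 18,
                voxel_spacing = c(1.25, 1.25, 2.5), ...)
}
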