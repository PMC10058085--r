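#' Construct a coronary tree
#'
#' A directed rooted tree of centerline nodes and segments with radii,
#' stenosis specifications and labeled outlets. Segment `length` is the
#' arc length used by the hemodynamics; node positions (mm) seed the
#' Voronoi territory assignment.
#'
#' @param nodes tibble: `id` (integer), `x`, `y`, `z` (mm), `r` (reference
#'   radius at the node, mm, > 0).
#' @param segments tibble: `id`, `parent`, `child` (node ids), `length` (mm),
#'   `r_prox`, `r_dist` (mm), `branch` (character label).
#' @param stenoses tibble (possibly empty): `id`, `segment` (segment id),
#'   `center` (arc length from the segment's proximal end, mm), `length`
#'   (mm), `severity` (% diameter reduction in (0, 100)), `vessel`
#'   (`"LAD"`/`"LCX"`), `location` (`"proximal"`/`"middle"`/`"distal"`).
#' @param outlets tibble: `node` (terminal node id), `label` (one of LAD,
#'   LCX, diagonal, marginal), `vessel` (the evaluable vessel the outlet
#'   drains with, `"LAD"`/`"LCX"`).
#' @param inlet root node id.
#' @return an object of class `coronary_tree`.
#' @export
coronary_tree <- function(nodes, segments, stenoses, outlets, inlet) {
  tree <- structure(
    list(nodes = as_tibble(nodes), segments = as_tibble(segments),
         stenoses = as_tibble(stenoses), outlets = as_tibble(outlets),
         inlet = as.integer(inlet)),
    class = "coronary_tree"
  )
  validate_tree(tree)
  tree
}

#' Validate a coronary tree's structural invariants
#'
#' Checks: a single root equal to `inlet`; every non-root node has exactly
#' one parent (acyclic by construction); positive radii and lengths; every
#' terminal node is a labeled outlet; each stenosis lies strictly inside its
#' segment with severity in (0, 100).
#'
#' @param tree a [coronary_tree()].
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  nodes <- tree$nodes; segs <- tree$segments
  if (anyDuplicated(nodes$id)) abort("duplicate node ids", class = "ctpffr_tree_error")
  if (!all(c(segs$parent, segs$child) %in% nodes$id)) {
    abort("segment endpoint not in node table", class = "ctpffr_tree_error")
  }
  if (anyDuplicated(segs$child)) {
    abort("a node has two parents (not a tree)", class = "ctpffr_tree_error")
  }
  roots <- setdiff(nodes$id, segs$child)
  if (length(roots) != 1 || roots != tree$inlet) {
    abort("tree must have exactly one root, equal to `inlet`",
          class = "ctpffr_tree_error")
  }
  if (any(segs$length <= 0) || any(segs$r_prox <= 0) || any(segs$r_dist <= 0) ||
      any(nodes$r <= 0)) {
    abort("lengths and radii must be > 0", class = "ctpffr_tree_error")
  }
  terminals <- setdiff(nodes$id, segs$parent)
  if (!setequal(terminals, tree$outlets$node)) {
    abort("terminal nodes and labeled outlets must coincide",
          class = "ctpffr_tree_error")
  }
  st <- tree$stenoses
  if (nrow(st) > 0) {
    if (any(st$severity <= 0) || any(st$severity >= 100)) {
      abort("stenosis severity must lie in (0, 100)", class = "ctpffr_tree_error")
    }
    seg_len <- segs$length[match(st$segment, segs$id)]
    if (any(is.na(seg_len)) ||
        any(st$center - st$length / 2 < 0) ||
        any(st$center + st$length / 2 > seg_len)) {
      abort("stenosis extent must lie inside its segment",
            class = "ctpffr_tree_error")
    }
  }
  invisible(tree)
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("<coronary_tree> %d nodes, %d segments, %d stenoses, %d outlets\n",
              nrow(x$nodes), nrow(x$segments), nrow(x$stenoses), nrow(x$outlets)))
  if (nrow(x$stenoses) > 0) {
    s <- x$stenoses
    cat(sprintf("  stenoses: %s\n",
                paste(sprintf("%s %s %.0f%%", s$vessel, s$location, s$severity),
                      collapse = ", ")))
  }
  invisible(x)
}

# ordered root->outlet segment-id path for each outlet node
tree_paths <- function(tree) {
  segs <- tree$segments
  parent_of <- setNames(segs$parent, segs$child)
  seg_into <- setNames(segs$id, segs$child)
  lapply(setNames(tree$outlets$node, tree$outlets$node), function(o) {
    path <- integer(0)
    n <- o
    while (n != tree$inlet) {
      path <- c(seg_into[[as.character(n)]], path)
      n <- parent_of[[as.character(n)]]
    }
    path
  })
}

# main root->outlet path (segment ids) of an evaluable vessel ("LAD"/"LCX"):
# the path to the outlet labeled with the vessel's own name
vessel_path <- function(tree, vessel) {
  out <- tree$outlets$node[tree$outlets$label == vessel]
  if (length(out) != 1) {
    abort(sprintf("vessel '%s' has no unique main outlet", vessel),
          class = "ctpffr_tree_error")
  }
  tree_paths(tree)[[as.character(out)]]
}

#' Murray's-law residuals at every bifurcation
#'
#' At each branching node compares the parent cube radius with the sum of
#' child cube radii, `|r_p^3 - sum r_c^3| / r_p^3`, using the distal radius
#' of the parent segment and proximal radii of the child segments.
#'
#' @param tree a [coronary_tree()].
#' @return tibble with one row per bifurcation: `node`, `residual`.
#' @export
murray_residuals <- function(tree) {
  segs <- tree$segments
  branch_nodes <- unique(segs$parent[duplicated(segs$parent)])
  branch_nodes <- setdiff(branch_nodes, tree$inlet)
  purrr::map_dfr(branch_nodes, function(n) {
    rp <- segs$r_dist[segs$child == n]
    rc <- segs$r_prox[segs$parent == n]
    tibble(node = n, residual = abs(rp^3 - sum(rc^3)) / rp^3)
  })
}

#' Write / read a coronary tree as versioned JSON
#'
#' @param tree a [coronary_tree()].
#' @param path output `.json` path.
#' @return `path` (write) or a [coronary_tree()] (read).
#' @export
write_tree_json <- function(tree, path) {
  payload <- list(
    schema = "ctpffr-tree", schema_version = 1L,
    inlet = tree$inlet,
    nodes = tree$nodes, segments = tree$segments,
    stenoses = tree$stenoses, outlets = tree$outlets
  )
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "ctpffr-tree")) {
    abort("not a ctpffr tree JSON file", class = "ctpffr_io_error")
  }
  sten <- as_tibble(p$stenoses)
  if (nrow(sten) == 0) {
    sten <- tibble(id = integer(), segment = integer(), center = numeric(),
                   length = numeric(), severity = numeric(),
                   vessel = character(), location = character())
  }
  coronary_tree(as_tibble(p$nodes), as_tibble(p$segments), sten,
                as_tibble(p$outlets), p$inlet)
}
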