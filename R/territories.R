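#' Assign myocardial perfusion territories by the Voronoi rule
#'
#' Each masked voxel is assigned to the coronary outlet whose terminal-node
#' position is nearest (unweighted Euclidean distance in physical mm, voxel
#' centers at `origin + (index - 1/2) * spacing`). Ties go to the smallest
#' outlet node id. The resulting territories partition the mask exactly and
#' define the perfusion bed feeding each outlet.
#'
#' @param map an [mbf_map()] with a non-empty mask.
#' @param tree a [coronary_tree()] with at least one outlet.
#' @return an object of class `perfusion_territories`: `labels` (integer
#'   array congruent with the map; outlet node id inside the mask, `NA`
#'   outside) and `outlets` (tibble of outlet ids and labels).
#' @export
assign_territories <- function(map, tree) {
  if (nrow(tree$outlets) < 1) {
    abort("tree has no outlets", class = "ctpffr_domain_error")
  }
  if (!any(map$mask)) {
    abort("mask is empty", class = "ctpffr_domain_error")
  }
  outlets <- dplyr::arrange(tree$outlets, .data$node)
  seed_xyz <- as.matrix(tree$nodes[match(outlets$node, tree$nodes$id),
                                   c("x", "y", "z")])
  idx <- masked_indices(map)
  ctr <- voxel_centers(map, idx)
  # squared distances voxel x outlet, vectorized
  d2 <- outer(rowSums(ctr^2), rep(1, nrow(seed_xyz))) -
    2 * ctr %*% t(seed_xyz) +
    outer(rep(1, nrow(ctr)), rowSums(seed_xyz^2))
  nearest <- max.col(-d2, ties.method = "first")  # first = smallest node id
  labels <- array(NA_integer_, dim = dim(map$mask))
  labels[idx] <- outlets$node[nearest]
  structure(list(labels = labels, outlets = outlets),
            class = "perfusion_territories")
}

#' @export
print.perfusion_territories <- function(x, ...) {
  counts <- table(x$labels[!is.na(x$labels)])
  cat(sprintf("<perfusion_territories> %d outlets over %d voxels\n",
              nrow(x$outlets), sum(!is.na(x$labels))))
  print(counts)
  invisible(x)
}

#' Per-territory voxel counts and volumes
#'
#' @param territories a [assign_territories()] result.
#' @param map the [mbf_map()] the territories were computed on.
#' @return tibble: `outlet`, `n_voxels`, `volume_ml`.
#' @export
territory_volumes <- function(territories, map) {
  lab <- territories$labels[map$mask]
  counts <- table(factor(lab, levels = territories$outlets$node))
  tibble(outlet = territories$outlets$node,
         n_voxels = as.integer(counts),
         volume_ml = as.numeric(counts) * voxel_volume_ml(map))
}

#' Write territory labels as NIfTI aligned with the MBF map
#'
#' @param territories a [assign_territories()] result.
#' @param map the matching [mbf_map()] (for spacing/origin).
#' @param path output `.nii`/`.nii.gz` path; unmasked voxels are written 0.
#' @export
write_territories_nifti <- function(territories, map, path) {
  lab <- territories$labels
  lab[is.na(lab)] <- 0L
  xform <- diag(c(map$spacing, 1))
  xform[1:3, 4] <- map$origin
  img <- RNifti::asNifti(array(as.integer(lab), dim = dim(lab)))
  img <- RNifti::`pixdim<-`(img, map$spacing)
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  img$descrip <- "Voronoi territory labels (outlet node id)"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Sample mean MBF in a circular in-plane region of interest
#'
#' Averages masked MBF inside a disc drawn on one axial slice, mirroring
#' ROI sampling of a suspected perfusion defect. The realized area counts
#' only masked in-disc voxels; if it falls below `min_area` the sample is
#' rejected rather than silently returned.
#'
#' @param map an [mbf_map()].
#' @param slice_index 1-based index along the third (slice) axis.
#' @param center in-plane center (x, y) in physical mm.
#' @param min_area minimum acceptable masked area, mm^2. Default 50.
#' @param target_area disc area, mm^2; the disc radius is
#'   `sqrt(target_area / pi)`. Default 100.
#' @return list: `mean_mbf`, `area_mm2`, `n_voxels`.
#' @export
sample_roi <- function(map, slice_index, center, min_area = 50,
                       target_area = 100) {
  stopifnot(slice_index >= 1, slice_index <= dim(map$values)[3],
            length(center) == 2, target_area > 0)
  radius <- sqrt(target_area / pi)
  d <- dim(map$values)
  xc <- map$origin[1] + (seq_len(d[1]) - 0.5) * map$spacing[1]
  yc <- map$origin[2] + (seq_len(d[2]) - 0.5) * map$spacing[2]
  in_disc <- outer((xc - center[1])^2, (yc - center[2])^2, `+`) <= radius^2
  sel <- in_disc & map$mask[, , slice_index]
  area <- sum(sel) * map$spacing[1] * map$spacing[2]
  if (area < min_area) {
    abort(sprintf("ROI rejected: realized masked area %.1f mm^2 < minimum %.1f mm^2",
                  area, min_area),
          class = "ctpffr_roi_error", area_mm2 = area)
  }
  vals <- map$values[, , slice_index][sel]
  list(mean_mbf = mean(vals), area_mm2 = area, n_voxels = sum(sel))
}
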