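#' Construct a voxelized myocardial blood flow map
#'
#' A hyperemic MBF volume (mL min^-1 per mL of tissue) together with a
#' left-ventricular myocardium mask, voxel spacing and physical origin.
#' Voxel centers sit at `origin + (index - 1/2) * spacing` with 1-based array
#' indices, so the first voxel center is half a voxel inside the origin.
#'
#' @param values 3D numeric array, MBF in mL min^-1 mL^-1; must be >= 0
#'   inside the mask.
#' @param mask 3D logical array congruent with `values`.
#' @param spacing voxel spacing in mm, length 3, positive.
#' @param origin physical position (mm) of the grid corner, length 3.
#' @return an object of class `mbf_map`.
#' @export
mbf_map <- function(values, mask, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  stopifnot(is.array(mask), identical(dim(mask), dim(values)))
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (any(values[mask] < 0, na.rm = TRUE)) {
    abort("MBF values inside the mask must be >= 0.", class = "ctpffr_domain_error")
  }
  structure(
    list(values = values, mask = mask,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "mbf_map"
  )
}

#' @export
print.mbf_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mbf_map> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  masked voxels: %d (%.1f mL), MBF range in mask: [%.3g, %.3g]\n",
              sum(x$mask), sum(x$mask) * voxel_volume_ml(x),
              suppressWarnings(min(x$values[x$mask])),
              suppressWarnings(max(x$values[x$mask]))))
  invisible(x)
}

# single-voxel volume in mL (mm^3 * 1e-3)
voxel_volume_ml <- function(map) prod(map$spacing) * 1e-3

# physical centers (mm) of the voxels at the given 1-based index matrix
voxel_centers <- function(map, idx) {
  sweep(sweep(idx - 0.5, 2, map$spacing, `*`), 2, map$origin, `+`)
}

# index matrix (n x 3) of masked voxels, in array order
masked_indices <- function(map) {
  which(map$mask, arr.ind = TRUE)
}

#' Tabulate a map's masked voxels
#'
#' @param x an [mbf_map()].
#' @param ... unused.
#' @return a tibble with one row per masked voxel: array indices `i, j, k`,
#'   physical center `x, y, z` (mm) and `mbf`.
#' @export
as_tibble.mbf_map <- function(x, ...) {
  idx <- masked_indices(x)
  ctr <- voxel_centers(x, idx)
  tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
         x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
         mbf = x$values[idx])
}

#' Write / read an MBF map as NIfTI
#'
#' Spacing is carried in `pixdim`, the origin in the sform translation, and
#' the value units (mL min^-1 mL^-1) in the header description. The mask is
#' written alongside as an integer volume (suffix `_mask`), since NIfTI has
#' no native boolean payload.
#'
#' @param map an [mbf_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mbf_nifti <- function(map, path) {
  xform <- diag(c(map$spacing, 1))
  xform[1:3, 4] <- map$origin
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`pixdim<-`(img, map$spacing)
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  img$descrip <- "hyperemic MBF, mL/min/mL"
  RNifti::writeNifti(img, path)
  mask_img <- RNifti::asNifti(array(as.integer(map$mask), dim = dim(map$mask)))
  mask_img <- RNifti::`pixdim<-`(mask_img, map$spacing)
  mask_img <- RNifti::`sform<-`(mask_img, structure(xform, code = 2L))
  RNifti::writeNifti(mask_img, mask_path(path))
  invisible(path)
}

#' @rdname write_mbf_nifti
#' @param path path previously written by [write_mbf_nifti()].
#' @export
read_mbf_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  mask <- RNifti::readNifti(mask_path(path))
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  origin <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  mbf_map(array(as.numeric(img), dim = dim(img)),
          array(as.numeric(mask) != 0, dim = dim(mask)),
          spacing = spacing, origin = origin)
}

mask_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
}
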