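# Threshold-based lumen segmentation and the geometric measurements
# reported per scan: cross-sectional slice area and equivalent diameter.

#' Analysis plane specification
#'
#' A plane orthogonal to the vessel (y) axis, identified by its axis
#' coordinate. Slices are half-open along the axis: the plane selects the
#' voxel layer whose half-open interval \[y_lo, y_lo + h) contains the
#' coordinate.
#'
#' @param axis_coordinate position along the vessel axis in m.
#' @param role \code{"inlet"} or \code{"mid_vessel"}.
#' @return An object of class \code{plane_spec}.
#' @export
plane_spec <- function(axis_coordinate, role = c("mid_vessel", "inlet")) {
  role <- match.arg(role)
  structure(list(axis_coordinate = axis_coordinate, role = role),
            class = "plane_spec")
}

# index of the voxel layer along y containing the plane coordinate
.slice_index <- function(obj, plane) {
  h <- obj$voxel_size
  j <- floor((plane$axis_coordinate - obj$origin[2]) / h) + 1L
  if (j < 1L || j > obj$dims[2])
    stop("plane does not intersect the voxel grid")
  as.integer(j)
}

#' Threshold segmentation of the lumen
#'
#' Marks as lumen every voxel whose partial-volume magnitude is at least the
#' threshold. The magnitude image is frame-independent (maximum-extent
#' geometry over the cycle), so the returned mask is the maximum-extent
#' lumen mask.
#'
#' @param vox a \code{\link{acquire}} result.
#' @param threshold magnitude threshold in (0, 1). The default 0.25 keeps
#'   boundary voxels with modest lumen coverage and reproduces the dilation
#'   of coarse scans; 0.5 gives asymptotically unbiased areas.
#' @return An object of class \code{lumen_mask}: logical array \code{mask}
#'   (nx x ny x nz) plus the grid metadata of \code{vox}.
#' @export
segment <- function(vox, threshold = 0.25) {
  stopifnot(inherits(vox, "voxel4dflow"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  structure(
    list(mask = vox$magnitude >= threshold, origin = vox$origin,
         voxel_size = vox$voxel_size, dims = vox$dims[1:3],
         threshold = threshold),
    class = "lumen_mask"
  )
}

#' Cross-sectional area of a mask slice
#'
#' Area of the segmented lumen in the plane's voxel layer: the count of
#' lumen voxels times the squared voxel size.
#'
#' @param mask a \code{\link{segment}} result.
#' @param plane a \code{\link{plane_spec}}.
#' @return Area in m^2.
#' @examples
#' # 25 lumen voxels at 2 mm -> 1e-4 m^2
#' @export
slice_area <- function(mask, plane) {
  stopifnot(inherits(mask, "lumen_mask"), inherits(plane, "plane_spec"))
  j <- .slice_index(mask, plane)
  n <- sum(mask$mask[, j, ])
  if (n == 0L) stop("empty lumen slice at the requested plane")
  n * mask$voxel_size^2
}

#' Equivalent circular diameter of a cross-section
#'
#' Diameter of the circle with the same area: \eqn{d = 2\sqrt{A/\pi}}.
#'
#' @param area cross-sectional area in m^2 (positive).
#' @return Diameter in m.
#' @examples
#' equivalent_diameter(1e-4) * 1e3  # 11.2838 mm
#' @export
equivalent_diameter <- function(area) {
  if (any(area <= 0)) stop("`area` must be positive")
  2 * sqrt(area / pi)
}

#' Write / read a lumen mask as NIfTI
#'
#' @param mask a \code{lumen_mask}.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @return \code{write_lumen_mask} returns \code{path} invisibly;
#'   \code{read_lumen_mask} needs the voxel size recovered from the header
#'   and returns a \code{lumen_mask} (origin defaults to zero).
#' @export
write_lumen_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lumen_mask"))
  mm <- mask$voxel_size * 1e3
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = mask$dims))
  RNifti::pixdim(img) <- rep(mm, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_lumen_mask
#' @export
read_lumen_mask <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::pixdim(img)[1] * 1e-3
  arr <- as.array(img) > 0
  structure(
    list(mask = arr, origin = c(0, 0, 0), voxel_size = h, dims = dim(arr),
         threshold = NA_real_),
    class = "lumen_mask"
  )
}

#' Slice summary across resolutions as CSV
#'
#' Writes a per-resolution geometry summary with columns
#' \code{resolution_mm}, \code{area_mm2}, \code{equivalent_diameter_cm}.
#'
#' @param summary data.frame with those columns.
#' @param path output CSV path.
#' @export
write_geometry_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
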