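#' Voxel grid geometry
#'
#' A `volume_grid` describes the lattice a volume lives on: integer
#' dimensions, physical voxel spacing in millimetres, and the physical
#' position of the first voxel. Voxel indices are 1-based array indices;
#' the physical position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`. Axis order is `(x, y, z)` with
#' `x` varying fastest in storage, the native R array layout.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, mm position of voxel (1,1,1).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume of a grid in cubic millimetres
#' @param grid a `volume_grid`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_grid_mismatch <- function(what) {
  stop(sprintf("grid mismatch: %s must share one voxel grid", what),
       call. = FALSE)
}

#' Scalar 3D volume
#'
#' Container for one MRI volume: a 3D numeric array plus its grid
#' geometry. Intensities are in arbitrary scanner units.
#'
#' @param values numeric 3D array (or vector reshaped by `grid$dims`).
#' @param grid a `volume_grid`; defaults to unit spacing at the array dims.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, grid = NULL) {
  if (is.null(grid)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      stop("'values' must be a 3D array when 'grid' is not given")
    grid <- volume_grid(dim(values))
  }
  values <- array(as.numeric(values), dim = grid$dims)
  if (any(!is.finite(values)))
    stop("volume values must all be finite")
  structure(list(grid = grid, values = values), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  r <- range(x$values)
  cat(sprintf("volume_image: %d x %d x %d @ (%g, %g, %g) mm, range [%g, %g]\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3],
              r[1], r[2]))
  invisible(x)
}

#' Binary mask on a voxel grid
#'
#' @param values logical 3D array (or coercible vector).
#' @param grid the `volume_grid` the mask lives on.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid = NULL) {
  if (is.null(grid)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      stop("'values' must be a 3D array when 'grid' is not given")
    grid <- volume_grid(dim(values))
  }
  values <- array(as.logical(values), dim = grid$dims)
  if (any(is.na(values))) stop("mask values must be TRUE/FALSE, no NA")
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  n <- sum(x$values)
  cat(sprintf("binary_mask: %d x %d x %d, %d voxels on (%.3f cm^3)\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              n, n * voxel_volume_mm3(x$grid) / 1000))
  invisible(x)
}

#' Physical volume of a mask in cubic centimetres
#'
#' Count of `TRUE` voxels times the voxel volume, converted from mm^3 to
#' cm^3. This is the unit in which |Breast|, |FGT| and |BPE| are reported.
#'
#' @param mask a `binary_mask`.
#' @return Volume in cm^3.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume_mm3(mask$grid) / 1000
}
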