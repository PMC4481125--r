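#' Read a 3D volume from a NIfTI file
#'
#' Loads a single-channel 3D NIfTI-1 volume (.nii or .nii.gz). Voxel
#' spacing is taken from the header `pixdim`, the origin from the
#' `qoffset` fields. Integer-typed files are read losslessly.
#'
#' @param path path to an existing NIfTI file.
#' @param format input format; only `"nifti"` is supported.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, format = "nifti") {
  format <- match.arg(format, "nifti")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3D single-channel volume, got %dD: %s",
                 length(d), path))
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(hdr$pixdim[2:4])
  if (any(spacing <= 0))
    stop(sprintf("non-positive voxel spacing in header of %s", path))
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  grid <- volume_grid(d, spacing, origin)
  volume_image(as.vector(img), grid)
}

#' Write a volume or mask to a NIfTI file
#'
#' Masks are written as uint8 (0/1); images as float64. Spacing and origin
#' are stored in the header (`pixdim`, `qoffset`).
#'
#' @param x a `volume_image` or `binary_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("volume_image", "binary_mask")))
  g <- x$grid
  is_mask <- inherits(x, "binary_mask")
  vals <- if (is_mask) array(as.integer(x$values), g$dims) else x$values
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, g$dims, 1L, 1L, 1L, 1L),
    pixdim = c(0, g$spacing, 0, 0, 0, 0),
    qoffset_x = g$origin[1], qoffset_y = g$origin[2],
    qoffset_z = g$origin[3], qform_code = 1L))
  img <- RNifti::asNifti(vals, reference = hdr,
                         datatype = if (is_mask) "uint8" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble a DCE study
#'
#' Bundles a pre-contrast volume with the ordered post-contrast time
#' points and, optionally, scanner-provided subtraction (SUB) volumes.
#' All member volumes must share one grid; when `subs` is given it must
#' have one entry per post-contrast volume.
#'
#' @param pre pre-contrast `volume_image`.
#' @param posts list of post-contrast `volume_image`s, time order 1..K.
#' @param subs optional list of precomputed subtraction volumes, same
#'   length and order as `posts`.
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(pre, posts, subs = NULL) {
  stopifnot(inherits(pre, "volume_image"), length(posts) >= 1)
  for (p in posts) {
    stopifnot(inherits(p, "volume_image"))
    if (!same_grid(pre$grid, p$grid))
      stop_grid_mismatch("pre and post-contrast volumes")
  }
  if (!is.null(subs)) {
    if (length(subs) != length(posts))
      stop("'subs' must have one volume per post-contrast time point")
    for (s in subs) {
      stopifnot(inherits(s, "volume_image"))
      if (!same_grid(pre$grid, s$grid))
        stop_grid_mismatch("pre-contrast and SUB volumes")
    }
  }
  structure(list(pre = pre, posts = posts, subs = subs),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat(sprintf("dce_study: pre + %d post-contrast time point(s)%s\n",
              length(x$posts),
              if (!is.null(x$subs)) " (precomputed SUB volumes present)"
              else ""))
  print(x$pre$grid)
  invisible(x)
}

#' Subtraction image for one post-contrast time point
#'
#' Returns the SUB volume for time point `k`: post-contrast minus
#' pre-contrast, voxel-wise. Negative differences are preserved (they
#' never pass a non-negative enhancement cutoff, so clamping is both
#' unnecessary and lossy). If the study carries scanner-provided SUB
#' volumes they are returned unchanged, so recomputed and stored paths
#' agree whenever the inputs are consistent.
#'
#' @param study a [dce_study()].
#' @param k post-contrast index, 1-based.
#' @return A `volume_image` of intensity differences.
#' @export
derive_subtraction <- function(study, k) {
  stopifnot(inherits(study, "dce_study"))
  k <- as.integer(k)
  if (k < 1L || k > length(study$posts))
    stop(sprintf("post-contrast index %d out of range 1..%d",
                 k, length(study$posts)))
  if (!is.null(study$subs)) return(study$subs[[k]])
  post <- study$posts[[k]]
  if (!same_grid(study$pre$grid, post$grid))
    stop_grid_mismatch("pre and post-contrast volumes")
  volume_image(post$values - study$pre$values, study$pre$grid)
}
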