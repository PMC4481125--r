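#' Voxel-wise enhancement ratio map
#'
#' Computes `R% = 100 * I_sub / I_pre` at every voxel of the region of
#' interest. Voxels whose pre-contrast intensity is at or below a guard
#' level `eps` are marked invalid instead of producing huge ratios:
#' fat-suppressed pre-contrast signal can be near zero, and unguarded
#' division would dominate the enhancing-voxel count spuriously. The
#' guard defaults to `1e-6` times the 99th percentile of the pre-contrast
#' intensities inside the ROI.
#'
#' @param pre pre-contrast `volume_image`.
#' @param sub subtraction `volume_image` (post minus pre).
#' @param roi `binary_mask` over which the ratio is defined (normally the
#'   fibroglandular tissue transferred onto the DCE grid).
#' @param eps division guard; `NULL` for the percentile default.
#' @return An object of class `enhancement_map`: `grid`, `ratio` (array,
#'   percent, `NA` outside validity), `valid` (logical array, subset of
#'   the ROI).
#' @export
enhancement_ratio <- function(pre, sub, roi, eps = NULL) {
  stopifnot(inherits(pre, "volume_image"), inherits(sub, "volume_image"),
            inherits(roi, "binary_mask"))
  if (!same_grid(pre$grid, sub$grid) || !same_grid(pre$grid, roi$grid))
    stop_grid_mismatch("pre, sub and ROI")
  m <- roi$values
  if (is.null(eps)) {
    ref <- if (any(m)) as.numeric(stats::quantile(pre$values[m], 0.99))
    else max(abs(pre$values))
    eps <- 1e-6 * ref
  }
  valid <- m & (pre$values > eps)
  ratio <- array(NA_real_, pre$grid$dims)
  ratio[valid] <- 100 * sub$values[valid] / pre$values[valid]
  structure(list(grid = pre$grid, ratio = ratio, valid = valid, eps = eps),
            class = "enhancement_map")
}

#' @export
print.enhancement_map <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("enhancement_map: %d valid voxel(s)", n))
  if (n > 0)
    cat(sprintf(", R%% range [%.1f, %.1f]",
                min(x$ratio[x$valid]), max(x$ratio[x$valid])))
  cat("\n")
  invisible(x)
}

#' Enhancing-voxel (BPE) mask at a cutoff
#'
#' Selects the valid fibroglandular voxels whose enhancement ratio is
#' greater than or equal to the cutoff (inclusive threshold). The result
#' is a subset of the FGT mask by construction.
#'
#' @param emap an [enhancement_ratio()] map.
#' @param fgt fibroglandular `binary_mask` on the same grid.
#' @param cutoff threshold in percent.
#' @return A `binary_mask` of enhancing voxels.
#' @export
bpe_mask <- function(emap, fgt, cutoff) {
  stopifnot(inherits(emap, "enhancement_map"), inherits(fgt, "binary_mask"))
  if (!same_grid(emap$grid, fgt$grid))
    stop_grid_mismatch("enhancement map and FGT mask")
  sel <- emap$valid & fgt$values
  out <- array(FALSE, emap$grid$dims)
  out[sel] <- emap$ratio[sel] >= cutoff
  binary_mask(out, emap$grid)
}

#' The default enhancement-ratio cutoff grid
#'
#' Cutoffs from 0% to 100% in steps of 10%, the sweep over which all BPE
#' measures are evaluated.
#' @return Numeric vector of cutoffs (percent).
#' @export
default_cutoffs <- function() seq(0, 100, by = 10)

#' Quantify one scan: |Breast|, |FGT|, FGT%, |BPE|, BPE%
#'
#' Runs the full single-scan pipeline: breast segmentation and FGT
#' segmentation on the structural T1 volume, rigid registration of the
#' T1 volume to the DCE pre-contrast frame, transfer of the masks onto
#' the DCE grid, then enhancement-ratio maps and enhancing-voxel volumes
#' for each requested subtraction time point over the cutoff grid.
#'
#' `|Breast|` and `|FGT|` are measured on the T1 grid where they are
#' segmented; `|BPE|` is measured on the DCE grid where enhancement
#' lives. All are in cm^3, so `FGT% = 100 |FGT| / |Breast|` and
#' `BPE% = 100 |BPE| / |Breast|` are well defined across grids.
#'
#' @param t1 structural `volume_image`.
#' @param study a [dce_study()].
#' @param sub_indices post-contrast time points to evaluate (default the
#'   early and delayed points, 1 and 3).
#' @param cutoffs ascending cutoff grid in percent.
#' @param params list of per-stage settings, see [quantify_params()].
#' @return An object of class `bpe_quant` with fields `breast_cc`,
#'   `fgt_cc`, `fgt_pct`, `bpe` (data frame: `sub_index`, `cutoff`,
#'   `bpe_cc`, `bpe_pct`), `transform`, and the masks (`breast`, `fgt`,
#'   `fgt_dce`).
#' @export
quantify_scan <- function(t1, study, sub_indices = c(1L, 3L),
                          cutoffs = default_cutoffs(),
                          params = quantify_params()) {
  stopifnot(inherits(t1, "volume_image"), inherits(study, "dce_study"))
  sub_indices <- sort(unique(as.integer(sub_indices)))
  if (any(sub_indices < 1L | sub_indices > length(study$posts)))
    stop(sprintf("requested SUB %s but the study has %d post-contrast time point(s)",
                 paste(sub_indices[sub_indices > length(study$posts) |
                                     sub_indices < 1L], collapse = ", "),
                 length(study$posts)))
  if (is.unsorted(cutoffs)) stop("'cutoffs' must be ascending")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  breast <- stage("segment_breast", segment_breast(t1, params$breast))
  fgt <- stage("segment_fgt", segment_fgt(t1, breast, params$fgt))
  breast_cc <- mask_volume_cc(breast)
  fgt_cc <- mask_volume_cc(fgt)

  if (params$skip_registration) {
    if (!same_grid(t1$grid, study$pre$grid))
      stop("skip_registration requires the T1 and DCE grids to coincide")
    tf <- rigid_transform(center = grid_phys_center(study$pre$grid))
  } else {
    tf <- stage("rigid_register",
                rigid_register(study$pre, t1, params$registration))
  }
  fgt_dce <- stage("resample_mask",
                   resample_mask(fgt, tf, study$pre$grid))

  rows <- list()
  for (k in sub_indices) {
    sub <- stage("derive_subtraction", derive_subtraction(study, k))
    emap <- stage("enhancement_ratio",
                  enhancement_ratio(study$pre, sub, fgt_dce,
                                    eps = params$eps))
    for (ct in cutoffs) {
      bm <- bpe_mask(emap, fgt_dce, ct)
      bpe_cc <- mask_volume_cc(bm)
      rows[[length(rows) + 1L]] <- data.frame(
        sub_index = k, cutoff = ct, bpe_cc = bpe_cc,
        bpe_pct = if (breast_cc > 0) 100 * bpe_cc / breast_cc else NA_real_)
    }
  }
  bpe <- do.call(rbind, rows)
  structure(list(
    breast_cc = breast_cc, fgt_cc = fgt_cc,
    fgt_pct = if (breast_cc > 0) 100 * fgt_cc / breast_cc else NA_real_,
    bpe = bpe, transform = tf,
    breast = breast, fgt = fgt, fgt_dce = fgt_dce,
    sub_indices = sub_indices, cutoffs = cutoffs),
    class = "bpe_quant")
}

#' Per-scan pipeline settings
#'
#' @param breast see [breast_params()].
#' @param fgt see [fgt_params()].
#' @param registration see [registration_params()].
#' @param skip_registration if `TRUE`, require coincident T1/DCE grids
#'   and use the identity transform.
#' @param eps enhancement-ratio division guard (`NULL`: percentile
#'   default, see [enhancement_ratio()]).
#' @return A named list of settings.
#' @export
quantify_params <- function(breast = breast_params(), fgt = fgt_params(),
                            registration = registration_params(),
                            skip_registration = FALSE, eps = NULL) {
  list(breast = breast, fgt = fgt, registration = registration,
       skip_registration = isTRUE(skip_registration), eps = eps)
}

#' @export
print.bpe_quant <- function(x, ...) {
  cat("Breast MRI quantification\n")
  cat(sprintf("  |Breast| = %.2f cm^3\n", x$breast_cc))
  cat(sprintf("  |FGT|    = %.2f cm^3   FGT%% = %.2f%%\n",
              x$fgt_cc, x$fgt_pct))
  cat(sprintf("  BPE over %d SUB time point(s) x %d cutoff(s)\n",
              length(x$sub_indices), length(x$cutoffs)))
  invisible(x)
}

#' @export
summary.bpe_quant <- function(object, cutoff = 30, ...) {
  cat(sprintf("|Breast| %.2f cm^3, |FGT| %.2f cm^3, FGT%% %.2f%%\n",
              object$breast_cc, object$fgt_cc, object$fgt_pct))
  b <- object$bpe[object$bpe$cutoff == cutoff, , drop = FALSE]
  if (nrow(b)) {
    cat(sprintf("At R%%_cutoff = %g%%:\n", cutoff))
    for (i in seq_len(nrow(b)))
      cat(sprintf("  SUB %d: |BPE| %.2f cm^3, BPE%% %.2f%%\n",
                  b$sub_index[i], b$bpe_cc[i], b$bpe_pct[i]))
  }
  invisible(object)
}

#' @export
as.data.frame.bpe_quant <- function(x, ...) {
  df <- x$bpe
  df$breast_cc <- x$breast_cc
  df$fgt_cc <- x$fgt_cc
  df$fgt_pct <- x$fgt_pct
  df[, c("breast_cc", "fgt_cc", "fgt_pct", "sub_index", "cutoff",
         "bpe_cc", "bpe_pct")]
}
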