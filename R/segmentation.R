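#' Breast segmentation on a non-fat-suppressed T1 volume
#'
#' Separates the breast from the air background and the chest wall. The
#' recipe: (1) body-vs-air separation by intensity clustering (3-class
#' fuzzy C-means on a deterministic subsample; the lowest-centroid class
#' is air) or, optionally, a global Otsu threshold; (2) a gradient
#' edge map along the anterior-posterior axis; (3) the chest wall taken
#' as the posterior-most strong edge in each anterior-posterior column,
#' smoothed slice-wise by a running median; (4) morphological closing and
#' the largest anterior connected component.
#'
#' Axis convention: axis 2 (`y`) is anterior-posterior with the chest
#' wall at high `y`. `|Breast|` follows as
#' `mask_volume_cc(segment_breast(t1))`.
#'
#' @param t1 non-fat-suppressed T1-weighted `volume_image`.
#' @param params list of settings, see [breast_params()].
#' @return A `binary_mask` of the breast, with attribute `chest_cut`
#'   (per-column posterior cut index, `dims[1] x dims[3]`).
#' @export
segment_breast <- function(t1, params = breast_params()) {
  stopifnot(inherits(t1, "volume_image"))
  v <- t1$values
  if (diff(range(v)) == 0)
    stop("constant-intensity volume: no foreground/background separation")
  d <- dim(v)

  # --- body vs air -------------------------------------------------------
  # threshold at the half-height of the air-to-fat step so the skin
  # surface lands on the true tissue boundary; darker interior tissue
  # (gland, muscle partial volume) is recovered by hole filling
  if (params$air_method == "fcm") {
    # fit centroids on a deterministic subsample, classify every voxel
    idx <- seq(1L, length(v), by = max(1L, length(v) %/% 100000L))
    fit <- fcm_cluster(v[idx], n_clusters = 3L, fuzziness = 2,
                       tol = 1e-4, max_iter = 100L)
    ctr <- fit$centroids
    thr <- (ctr[1] + ctr[length(ctr)]) / 2   # air vs brightest tissue
  } else {
    thr <- otsu_threshold(v)
  }
  body <- v > thr
  if (!any(body)) stop("no foreground voxels found (air-only volume?)")
  body <- fill_holes(body)

  # --- chest wall: posterior-most strong edge per (x, z) column ----------
  gy <- gradient_axis(v, 2L)
  ag <- abs(gy)
  strong <- ag >= params$edge_frac * as.numeric(stats::quantile(ag[body],
                                                                0.999))
  strong <- strong & (body | shift3(body, c(0, -1, 0), FALSE) |
                        shift3(body, c(0, 1, 0), FALSE))
  ycut <- matrix(d[2] + 1L, d[1], d[3])   # default: keep whole column
  yidx <- array(rep(seq_len(d[2]), each = d[1]), d)
  ymat <- apply(ifelse(strong, yidx, 0L), c(1, 3), max)
  has_edge <- ymat > 0L
  ycut[has_edge] <- ymat[has_edge]
  # slice-wise smoothing of the cut surface
  k <- min(params$cut_smooth_k, d[1] - (d[1] + 1) %% 2)
  ycut <- apply(ycut, 2, stats::runmed, k = max(1L, k))
  ycut <- matrix(ycut, d[1], d[3])

  # keep everything up to and including the cut voxel: the intensity
  # threshold already places the fine boundary, the cut removes the bulk
  # of the chest
  lim <- array(aperm(array(ycut, c(d[1], d[3], d[2])), c(1, 3, 2)), d)
  keep <- yidx <= lim
  mask <- body & keep
  mask <- close6(mask, params$closing_radius)
  mask <- mask & keep
  if (!any(mask)) stop("breast segmentation produced an empty mask")
  mask <- largest_component(mask)
  out <- binary_mask(mask, t1$grid)
  attr(out, "chest_cut") <- ycut
  out
}

#' Breast-segmentation settings
#'
#' @param air_method `"fcm"` (3-class intensity clustering; robust when
#'   dark tissue and bright fat would straddle a single Otsu threshold)
#'   or `"otsu"`.
#' @param edge_frac strong-edge threshold as a fraction of the 99.9th
#'   percentile of the anterior-posterior gradient magnitude inside the
#'   body.
#' @param closing_radius morphological closing radius, voxels.
#' @param cut_smooth_k running-median window (odd) for the chest-wall cut.
#' @return A named list of settings.
#' @export
breast_params <- function(air_method = c("fcm", "otsu"), edge_frac = 0.25,
                          closing_radius = 3L, cut_smooth_k = 5L) {
  list(air_method = match.arg(air_method), edge_frac = edge_frac,
       closing_radius = as.integer(closing_radius),
       cut_smooth_k = as.integer(cut_smooth_k))
}

# global Otsu threshold from a 256-bin histogram
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (diff(r) == 0) stop("constant intensities: Otsu threshold undefined")
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), levels)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[levels]; tot_mu <- mu[levels]
  w0 <- w[-levels]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-levels] / w0
  m1 <- (tot_mu - mu[-levels]) / w1
  bc <- w0 * w1 * (m0 - m1)^2
  bc[!valid] <- -Inf
  mids[which.max(bc)]
}

#' Fibroglandular tissue segmentation within the breast
#'
#' Clusters T1 intensities inside the breast mask with fuzzy C-means and
#' assigns the lowest-centroid cluster to FGT by hard maximum
#' membership (FGT is dark on non-fat-suppressed T1; fat is bright).
#' Voxels within `posterior_margin` voxels of the detected chest-wall cut
#' are excluded from FGT candidacy to avoid pectoral partial-volume
#' voxels masquerading as dark glandular tissue. The result is always a
#' subset of the breast mask.
#'
#' @param t1 the T1 `volume_image` used for [segment_breast()].
#' @param breast breast `binary_mask` (from [segment_breast()]).
#' @param params list of settings, see [fgt_params()].
#' @return A `binary_mask` of the fibroglandular tissue. Attribute
#'   `degenerate` is `TRUE` when no FGT-like class was separable.
#' @export
segment_fgt <- function(t1, breast, params = fgt_params()) {
  stopifnot(inherits(t1, "volume_image"), inherits(breast, "binary_mask"))
  if (!same_grid(t1$grid, breast$grid))
    stop_grid_mismatch("T1 volume and breast mask")
  bm <- breast$values
  if (!any(bm)) stop("empty breast mask")
  inside <- t1$values[bm]
  if (length(unique(inside)) < params$n_clusters)
    stop("all-equal intensities inside the breast mask: cannot cluster")
  fit <- fcm_cluster(inside, n_clusters = params$n_clusters,
                     fuzziness = params$fuzziness, tol = params$tol,
                     max_iter = params$max_iter, seed = params$seed)
  cl <- fcm_assign(fit)
  fgt <- array(FALSE, dim(bm))
  fgt[bm] <- cl == 1L   # lowest (darkest) centroid = FGT
  degenerate <- FALSE
  # degenerate separation: clustering pure noise splits one Gaussian in
  # half, which gives a centroid gap of about 1.3 times the sum of the
  # within-cluster spreads; genuinely bimodal fat/gland intensities give
  # a far larger separation index
  gap <- fit$centroids[2] - fit$centroids[1]
  s1 <- stats::sd(inside[cl == 1L])
  s2 <- stats::sd(inside[cl == 2L])
  if (!is.finite(s1)) s1 <- 0
  if (!is.finite(s2)) s2 <- 0
  if (gap < params$min_separation * (s1 + s2)) {
    fgt[] <- FALSE
    degenerate <- TRUE
  }
  # keep a margin anterior to the chest-wall cut
  cut <- attr(breast, "chest_cut")
  if (!is.null(cut) && params$posterior_margin > 0) {
    d <- dim(bm)
    yidx <- array(rep(seq_len(d[2]), each = d[1]), d)
    lim <- array(aperm(array(cut, c(d[1], d[3], d[2])), c(1, 3, 2)), d)
    fgt <- fgt & (yidx < lim - params$posterior_margin)
  }
  # exclude the skin-line shell: partial-volume voxels on the breast
  # surface sit between the fat and gland intensities and would
  # otherwise be mislabelled as FGT
  if (params$boundary_margin > 0)
    fgt <- fgt & erode6(bm, params$boundary_margin)
  out <- binary_mask(fgt & bm, breast$grid)
  attr(out, "fcm") <- fit
  attr(out, "degenerate") <- degenerate
  out
}

#' Fibroglandular-tissue segmentation settings
#'
#' @param n_clusters number of intensity classes (2: fat vs FGT).
#' @param fuzziness FCM fuzzifier.
#' @param tol,max_iter FCM convergence controls.
#' @param seed seed (FCM initialisation is deterministic by default; kept
#'   for reproducibility of optional random initialisation).
#' @param posterior_margin voxels anterior to the chest-wall cut excluded
#'   from FGT candidacy.
#' @param boundary_margin thickness (voxels) of the skin-line shell of
#'   the breast mask excluded from FGT candidacy (partial-volume guard).
#' @param min_separation minimum centroid gap, in units of the summed
#'   within-cluster SDs, below which the dark class is declared
#'   degenerate (no true FGT present) and an empty mask is returned;
#'   clustering unimodal noise yields about 1.3, bimodal tissue far more.
#' @return A named list of settings.
#' @export
fgt_params <- function(n_clusters = 2L, fuzziness = 2, tol = 1e-5,
                       max_iter = 300L, seed = 1L, posterior_margin = 2L,
                       boundary_margin = 1L, min_separation = 1.5) {
  list(n_clusters = as.integer(n_clusters), fuzziness = fuzziness,
       tol = tol, max_iter = as.integer(max_iter), seed = as.integer(seed),
       posterior_margin = as.integer(posterior_margin),
       boundary_margin = as.integer(boundary_margin),
       min_separation = min_separation)
}
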