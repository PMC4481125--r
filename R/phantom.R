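#' Digital breast phantom specification
#'
#' Describes a ground-truthed digital phantom: a half-ellipsoid breast on
#' a chest-wall slab, fibroglandular tissue (FGT) as smooth random blobs
#' grown to a target volume fraction, a non-fat-suppressed T1 rendering
#' (bright fat, dark FGT, darker pectoral muscle), and a fat-suppressed
#' DCE study (low fat signal, brighter FGT) whose post-contrast frames
#' carry voxel-wise fractional enhancement concentrated in an enhancing
#' sub-region of the FGT, with delayed uptake exceeding early uptake.
#' The DCE frames are rigidly displaced from the T1 frame by a known
#' transform, so segmentation, registration and quantification can all be
#' scored against exact truth.
#'
#' Axis convention: axis 2 (`y`) is anterior-posterior; the chest-wall
#' slab occupies the posterior `chest_slab_mm` of the volume and the
#' breast protrudes anteriorly from it.
#'
#' @param dims grid size in voxels (default 96 x 96 x 64).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param breast_semi_axes ellipsoid semi-axes (mm).
#' @param chest_slab_mm thickness of the posterior chest-wall slab (mm).
#' @param fgt_fraction_target FGT volume fraction of the breast.
#' @param fgt_blob_count number of Gaussian bumps forming the FGT field.
#' @param t1_intensities named list: `fat`, `fgt`, `muscle`, `noise_sd`.
#' @param dce_intensities named list: `fgt_pre`, `fat_pre`, `muscle_pre`,
#'   `noise_sd` (fat-suppressed pre-contrast signal levels).
#' @param uptake named list `means`, `sds`: per-time-point true R%
#'   distribution of enhancing FGT voxels (percent); means must be
#'   non-decreasing (delayed >= early).
#' @param enhancing_fraction fraction of FGT voxels that enhance.
#' @param fat_uptake_mean mean true R% outside the enhancing region
#'   (approximately 0; exactly 0 by default).
#' @param inter_scan_transform [rigid_transform()] mapping DCE-frame
#'   physical points into the T1 frame (the motion between the two
#'   acquisitions); `NULL` for a small default offset.
#' @param render_sigma partial-volume smoothing of the rendered volumes,
#'   voxels.
#' @param seed integer seed; the phantom is bit-reproducible given the
#'   spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(96L, 96L, 64L), spacing = c(1, 1, 1),
                         breast_semi_axes = c(38, 45, 26),
                         chest_slab_mm = 26,
                         fgt_fraction_target = 0.15,
                         fgt_blob_count = 12L,
                         t1_intensities = list(fat = 200, fgt = 80,
                                               muscle = 60, noise_sd = 4),
                         dce_intensities = list(fgt_pre = 100, fat_pre = 20,
                                                muscle_pre = 40,
                                                noise_sd = 2),
                         uptake = list(means = c(40, 55, 70),
                                       sds = c(18, 21, 24)),
                         enhancing_fraction = 0.4,
                         fat_uptake_mean = 0,
                         inter_scan_transform = NULL,
                         render_sigma = 0.6,
                         seed = 42L) {
  if (fgt_fraction_target <= 0 || fgt_fraction_target >= 1)
    stop("'fgt_fraction_target' must be in (0, 1)")
  if (enhancing_fraction < 0 || enhancing_fraction > 1)
    stop("'enhancing_fraction' must be in [0, 1]")
  if (length(uptake$means) != length(uptake$sds))
    stop("'uptake' means and sds must have equal length")
  if (is.unsorted(uptake$means))
    stop("delayed uptake mean must be >= early uptake mean")
  if (any(unlist(t1_intensities) < 0) || any(unlist(dce_intensities) < 0))
    stop("intensities must be >= 0")
  grid <- volume_grid(dims, spacing)
  if (is.null(inter_scan_transform))
    inter_scan_transform <- rigid_transform(
      rotation = c(0, 0, 3), translation = c(2, -3, 1),
      center = grid_phys_center(grid))
  structure(list(grid = grid, breast_semi_axes = breast_semi_axes,
                 chest_slab_mm = chest_slab_mm,
                 fgt_fraction_target = fgt_fraction_target,
                 fgt_blob_count = as.integer(fgt_blob_count),
                 t1_intensities = t1_intensities,
                 dce_intensities = dce_intensities,
                 uptake = uptake,
                 enhancing_fraction = enhancing_fraction,
                 fat_uptake_mean = fat_uptake_mean,
                 inter_scan_transform = inter_scan_transform,
                 render_sigma = render_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth standard-normal-ish random field: white noise smoothed with a
# Gaussian kernel, then standardised
smooth_field <- function(dims, sigma_vox) {
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- smooth_gaussian3(f, rep(sigma_vox, 3))
  (f - mean(f)) / stats::sd(f)
}

#' Generate a ground-truthed digital breast phantom
#'
#' @param spec a [phantom_spec()].
#' @return List with `t1` (`volume_image`), `study` ([dce_study()] with
#'   pre + one post per uptake time point), and `truth`
#'   (`phantom_truth`): `breast_mask`, `fgt_mask` (T1 grid),
#'   `fgt_mask_dce`, `breast_mask_dce` (DCE grid), `true_ratio` (list of
#'   per-time-point arrays on the DCE grid, `NA` outside the FGT), and
#'   `transform` (the inter-scan transform).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid
  d <- g$dims
  sp <- g$spacing

  ix <- (seq_len(d[1]) - 1) * sp[1]
  iy <- (seq_len(d[2]) - 1) * sp[2]
  iz <- (seq_len(d[3]) - 1) * sp[3]
  y0_mm <- (d[2] - 1) * sp[2] - spec$chest_slab_mm   # chest-wall plane
  cx <- (d[1] - 1) * sp[1] / 2
  cz <- (d[3] - 1) * sp[3] / 2
  ax <- spec$breast_semi_axes[1]
  ay <- spec$breast_semi_axes[2]
  az <- spec$breast_semi_axes[3]

  X <- array(rep(ix, times = d[2] * d[3]), d)
  Y <- array(rep(rep(iy, each = d[1]), times = d[3]), d)
  Z <- array(rep(iz, each = d[1] * d[2]), d)
  ell <- ((X - cx) / ax)^2 + ((Y - y0_mm) / ay)^2 + ((Z - cz) / az)^2
  breast <- ell <= 1 & Y <= y0_mm
  slab <- Y > y0_mm
  n_breast <- sum(breast)
  if (n_breast == 0) stop("breast ellipsoid does not intersect the grid")

  # --- FGT blobs ---------------------------------------------------------
  # Gaussian bumps at random interior centres; threshold the summed field
  # at the quantile that hits the target fraction exactly (in voxels)
  interior <- ell <= 0.8^2 & Y <= y0_mm - 6
  if (!any(interior)) stop("no interior region available for FGT blobs")
  allowed <- ell <= 0.9^2 & Y <= y0_mm - 4
  target_n <- round(spec$fgt_fraction_target * n_breast)
  if (target_n > sum(allowed))
    stop("FGT fraction target unreachable within the blob region budget")
  centers_idx <- sample(which(interior), spec$fgt_blob_count)
  field <- array(0, d)
  for (ci in centers_idx) {
    pos <- arrayInd(ci, d)
    s <- stats::runif(1, 4, 9)       # bump width, mm
    w <- stats::runif(1, 0.6, 1.4)   # bump weight
    field <- field + w * exp(-(((X - ix[pos[1]]))^2 + ((Y - iy[pos[2]]))^2 +
                                 ((Z - iz[pos[3]]))^2) / (2 * s^2))
  }
  field[!allowed] <- -Inf
  thr <- sort(field[allowed], decreasing = TRUE)[target_n]
  fgt <- field >= thr & allowed
  # exact count (ties at the threshold are broken arbitrarily but
  # deterministically)
  if (sum(fgt) != target_n) {
    ord <- order(field, decreasing = TRUE)
    fgt <- array(FALSE, d)
    fgt[ord[seq_len(target_n)]] <- TRUE
    fgt <- fgt & allowed
  }

  # --- enhancing sub-region and latent uptake field ----------------------
  K <- length(spec$uptake$means)
  enh_field <- smooth_field(d, 6 / mean(sp))
  n_enh <- round(spec$enhancing_fraction * sum(fgt))
  enh <- array(FALSE, d)
  if (n_enh > 0) {
    vals <- enh_field[fgt]
    thr_e <- sort(vals, decreasing = TRUE)[n_enh]
    sel <- which(fgt)[vals >= thr_e]
    enh[sel[seq_len(min(n_enh, length(sel)))]] <- TRUE
  }
  # latent uptake field: spatially smooth, but rank-normalised within the
  # enhancing region so the per-voxel ratio distribution is exactly the
  # declared normal (a raw smooth field restricted to a few blobs can
  # have an arbitrarily thin upper tail)
  u <- smooth_field(d, 8 / mean(sp))
  if (any(enh)) {
    ne <- sum(enh)
    qq <- rank(u[enh], ties.method = "first") / (ne + 1)
    # keep the exact median off 0.5: a voxel with u = 0 would have a true
    # ratio sitting knife-edge on the mean, which float round-trips
    # through the rendering can flip across an equal-valued cutoff
    qq[qq == 0.5] <- 0.5 + 0.25 / (ne + 1)
    u[enh] <- stats::qnorm(qq)
  }

  # --- T1 rendering ------------------------------------------------------
  t1c <- array(0, d)
  t1c[slab] <- spec$t1_intensities$muscle
  t1c[breast] <- spec$t1_intensities$fat
  t1c[fgt] <- spec$t1_intensities$fgt
  t1c <- smooth_gaussian3(t1c, rep(spec$render_sigma, 3))
  t1v <- t1c + stats::rnorm(length(t1c), 0, spec$t1_intensities$noise_sd)
  t1 <- volume_image(t1v, g)

  # --- DCE rendering on the displaced frame ------------------------------
  # the inter-scan transform maps DCE physical points into the T1 frame;
  # anatomy fields are sampled through it (masks nearest-neighbour,
  # smooth fields linearly)
  S <- spec$inter_scan_transform
  pre_field <- array(0, d)
  pre_field[slab] <- spec$dce_intensities$muscle_pre
  pre_field[breast] <- spec$dce_intensities$fat_pre
  pre_field[fgt] <- spec$dce_intensities$fgt_pre
  pre_field <- smooth_gaussian3(pre_field, rep(spec$render_sigma, 3))

  gp <- grid_points(g)
  tp <- transform_points(S, gp$phys)
  tidx <- phys_to_index(g, tp)
  pre_dce <- array(interp3(pre_field, tidx[, 1], tidx[, 2], tidx[, 3],
                           default = 0), d)
  fgt_dce <- array(nn3(fgt, tidx[, 1], tidx[, 2], tidx[, 3],
                       default = FALSE), d)
  breast_dce <- array(nn3(breast, tidx[, 1], tidx[, 2], tidx[, 3],
                          default = FALSE), d)
  enh_dce <- array(nn3(enh, tidx[, 1], tidx[, 2], tidx[, 3],
                       default = FALSE), d)
  u_dce <- array(interp3(u, tidx[, 1], tidx[, 2], tidx[, 3], default = 0),
                 d)

  ratio_dce <- vector("list", K)
  posts <- vector("list", K)
  nsd <- spec$dce_intensities$noise_sd
  for (k in seq_len(K)) {
    r <- array(spec$fat_uptake_mean, d)
    r[enh_dce] <- pmax(0, spec$uptake$means[k] +
                         spec$uptake$sds[k] * u_dce[enh_dce])
    post_clean <- pre_dce * (1 + r / 100)
    posts[[k]] <- volume_image(
      post_clean + stats::rnorm(length(post_clean), 0, nsd), g)
    rr <- array(NA_real_, d)
    rr[fgt_dce] <- r[fgt_dce]
    ratio_dce[[k]] <- rr
  }
  pre_img <- volume_image(pre_dce + stats::rnorm(length(pre_dce), 0, nsd),
                          g)
  study <- dce_study(pre_img, posts)

  truth <- structure(list(
    breast_mask = binary_mask(breast, g),
    fgt_mask = binary_mask(fgt, g),
    enhancing_mask = binary_mask(enh, g),
    breast_mask_dce = binary_mask(breast_dce, g),
    fgt_mask_dce = binary_mask(fgt_dce, g),
    true_ratio = ratio_dce,
    transform = S,
    grid = g), class = "phantom_truth")
  list(t1 = t1, study = study, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth: |Breast| %.2f cm^3, |FGT| %.2f cm^3 (FGT%% %.2f), %d time point(s)\n",
    mask_volume_cc(x$breast_mask), mask_volume_cc(x$fgt_mask),
    100 * mask_volume_cc(x$fgt_mask) / mask_volume_cc(x$breast_mask),
    length(x$true_ratio)))
  invisible(x)
}

#' Ground-truth enhancing volume at a cutoff
#'
#' Exact, noise-free oracle: the volume (cm^3) of fibroglandular voxels
#' whose true enhancement ratio at the given time point is greater than
#' or equal to the cutoff. Evaluated on the DCE frame, where the
#' enhancement lives.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param timepoint post-contrast time point (1-based).
#' @param cutoff threshold in percent.
#' @return Volume in cm^3.
#' @export
true_bpe_cc <- function(truth, timepoint, cutoff) {
  stopifnot(inherits(truth, "phantom_truth"))
  timepoint <- as.integer(timepoint)
  if (timepoint < 1L || timepoint > length(truth$true_ratio))
    stop(sprintf("unknown time point %d (truth has %d)", timepoint,
                 length(truth$true_ratio)))
  r <- truth$true_ratio[[timepoint]]
  m <- truth$fgt_mask_dce$values
  sum(r[m] >= cutoff, na.rm = TRUE) * voxel_volume_mm3(truth$grid) / 1000
}

#' Synthetic cohort specification
#'
#' Group structure for the paired pre/post cohort generator: per measure
#' and group, the pre-intervention mean and SD (lognormal marginals:
#' the measures are positive volumes with SDs comparable to their means,
#' which rules out normal marginals) and a post/pre change multiplier.
#' The default table encodes the study conditions: a post-intervention
#' decrease in the no-cancer group and essentially no change in the
#' cancer group, with pre-intervention moments matching the reference
#' group summaries at the representative 30% cutoff.
#'
#' @param n_no_cancer,n_cancer group sizes.
#' @param measures data frame with columns `measure`, `sub_index`,
#'   `pre_mean_g0`, `pre_sd_g0`, `mult_g0`, `pre_mean_g1`, `pre_sd_g1`,
#'   `mult_g1` (`g0` = no cancer, `g1` = cancer); `NULL` for the default.
#' @param correlation within-subject correlation of (log pre, log post)
#'   in `[0, 1)`.
#' @param cutoffs cutoff grid on which the BPE measures are expanded.
#' @param ref_cutoff the cutoff at which `measures` moments are anchored.
#' @param decay_cc e-folding constant (percent) of the per-subject
#'   BPE-versus-cutoff decay profile.
#' @param decay_jitter_sd lognormal jitter SD of the per-subject decay.
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_no_cancer = 44L, n_cancer = 6L, measures = NULL,
                        correlation = 0.8, cutoffs = default_cutoffs(),
                        ref_cutoff = 30, decay_cc = 40,
                        decay_jitter_sd = 0.15, seed = 7L) {
  if (n_no_cancer < 2 || n_cancer < 2)
    stop("each outcome group needs at least 2 subjects")
  if (correlation < 0 || correlation >= 1)
    stop("'correlation' must be in [0, 1)")
  if (is.null(measures)) measures <- default_cohort_measures()
  sds <- unlist(measures[, c("pre_sd_g0", "pre_sd_g1")])
  if (any(sds <= 0)) stop("pre SDs must be > 0")
  structure(list(n_no_cancer = as.integer(n_no_cancer),
                 n_cancer = as.integer(n_cancer),
                 measures = measures, correlation = correlation,
                 cutoffs = cutoffs, ref_cutoff = ref_cutoff,
                 decay_cc = decay_cc, decay_jitter_sd = decay_jitter_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# reference group moments at the representative 30% cutoff; the cancer
# group's default multiplier is 1 (no change), the no-cancer group's is
# the ratio of the reference post/pre means. |BPE| is not drawn: it is
# derived per subject as BPE% x |Breast| / 100, which reproduces the
# reference |BPE| moments because the summaries are self-consistent.
default_cohort_measures <- function() {
  data.frame(
    measure = c("FGTabs", "FGTpct", "BPEpct", "BPEpct"),
    sub_index = c(NA, NA, 1L, 3L),
    pre_mean_g0 = c(83.2, 11.3, 3.8, 6.0),
    pre_sd_g0 = c(63.8, 8.1, 4.5, 5.9),
    mult_g0 = c(60.4 / 83.2, 10.3 / 11.3, 2.3 / 3.8, 3.9 / 6.0),
    pre_mean_g1 = c(65.1, 11.6, 7.3, 8.2),
    pre_sd_g1 = c(60.2, 3.8, 4.6, 3.8),
    mult_g1 = rep(1, 4))
}

lognormal_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a synthetic paired pre/post cohort
#'
#' Draws per-subject pre values from group-specific lognormal marginals
#' (moment-matched to the spec), and post values as
#' `pre-correlated lognormal x group multiplier`. BPE measures are
#' expanded over the cutoff grid with a per-subject exponential decay
#' profile anchored at the reference cutoff, so |BPE| is non-increasing
#' in the cutoff for every subject and phase. BPE% is drawn at the
#' reference cutoff; the absolute |BPE| is derived from it and the
#' subject's breast volume (|Breast| = 100 |FGT| / FGT%), capped at
#' |FGT|, so all within-subject identities hold by construction.
#'
#' @param spec a [cohort_spec()].
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_no_cancer + spec$n_cancer
  outcome <- rep(c(0L, 1L), c(spec$n_no_cancer, spec$n_cancer))
  ids <- sprintf("S%03d", seq_len(n))
  rho <- spec$correlation
  ms <- spec$measures

  draw_pair <- function(m, s, mult, k) {
    lp <- lognormal_params(m, s)
    z1 <- stats::rnorm(k)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(k)
    list(pre = exp(lp$mu + lp$sigma * z1),
         post = mult * exp(lp$mu + lp$sigma * z2))
  }

  rows <- list()
  vals <- list()   # label -> list(pre, post)
  for (i in seq_len(nrow(ms))) {
    lab <- if (is.na(ms$sub_index[i])) ms$measure[i]
    else sprintf("%s_SUB%d", ms$measure[i], ms$sub_index[i])
    pre <- post <- numeric(n)
    for (gidx in 0:1) {
      sel <- outcome == gidx
      p <- if (gidx == 0)
        draw_pair(ms$pre_mean_g0[i], ms$pre_sd_g0[i], ms$mult_g0[i],
                  sum(sel))
      else
        draw_pair(ms$pre_mean_g1[i], ms$pre_sd_g1[i], ms$mult_g1[i],
                  sum(sel))
      pre[sel] <- p$pre
      post[sel] <- p$post
    }
    vals[[lab]] <- list(measure = ms$measure[i],
                        sub_index = ms$sub_index[i],
                        pre = pre, post = post)
  }

  # FGT rows (no cutoff axis)
  for (lab in c("FGTabs", "FGTpct")) {
    v <- vals[[lab]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = ids, outcome = outcome, measure = v$measure,
      sub_index = NA_integer_, cutoff = NA_real_,
      pre_value = v$pre, post_value = v$post)
  }

  # per-subject decay of |BPE| over the cutoff grid, shared pre/post
  lambda <- spec$decay_cc *
    exp(stats::rnorm(n, 0, spec$decay_jitter_sd))
  breast <- 100 * vals$FGTabs$pre / vals$FGTpct$pre
  breast_post <- 100 * vals$FGTabs$post / vals$FGTpct$post

  sub_ids <- unique(ms$sub_index[!is.na(ms$sub_index)])
  for (k in sub_ids) {
    vp <- vals[[sprintf("BPEpct_SUB%d", k)]]
    # |BPE| at the reference cutoff follows from BPE% and |Breast|
    abs_pre <- vp$pre * breast / 100
    abs_post <- vp$post * breast_post / 100
    for (ct in spec$cutoffs) {
      decay <- exp(-(ct - spec$ref_cutoff) / lambda)
      a_pre <- pmin(abs_pre * decay, vals$FGTabs$pre)
      a_post <- pmin(abs_post * decay, vals$FGTabs$post)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids, outcome = outcome, measure = "BPEabs",
        sub_index = k, cutoff = ct, pre_value = a_pre,
        post_value = a_post)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids, outcome = outcome, measure = "BPEpct",
        sub_index = k, cutoff = ct,
        pre_value = 100 * a_pre / breast,
        post_value = 100 * a_post / breast_post)
    }
  }
  cohort_table(do.call(rbind, rows))
}
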