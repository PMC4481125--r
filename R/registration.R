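#' Rigid (6 degree-of-freedom) transform
#'
#' Rotation angles are in degrees, applied as `R = Rz %*% Ry %*% Rx`
#' about `center`; a physical point `p` (mm) maps to
#' `R (p - center) + center + translation`. Used in the resampling
#' convention: the transform maps fixed-image physical points into the
#' moving image's physical space.
#'
#' @param rotation numeric length-3, angles about x, y, z in degrees.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, rotation centre in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "rigid_transform: rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm\n",
    x$rotation[1], x$rotation[2], x$rotation[3],
    x$translation[1], x$translation[2], x$translation[3]))
  if (isTRUE(attr(x, "warning")))
    cat("  [warning: registration failed to improve over identity]\n")
  invisible(x)
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

angles_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  } else {           # gimbal lock: fold everything into a
    a <- atan2(-R[2, 3], R[2, 2])
    c <- 0
  }
  c(a, b, c) * 180 / pi
}

#' Apply a rigid transform to physical points
#'
#' @param transform a [rigid_transform()].
#' @param pts numeric matrix, one point per row (mm), or length-3 vector.
#' @return Transformed points, same shape.
#' @export
transform_points <- function(transform, pts) {
  one <- is.null(dim(pts))
  if (one) pts <- matrix(pts, 1)
  R <- rotation_matrix(transform$rotation)
  out <- sweep(pts, 2, transform$center) %*% t(R)
  out <- sweep(out, 2, transform$center + transform$translation, "+")
  if (one) out[1, ] else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse transform (same centre).
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  Ri <- t(R)
  rigid_transform(rotation = angles_from_matrix(Ri),
                  translation = as.numeric(-Ri %*% transform$translation),
                  center = transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`p -> a(b(p))`), expressed about `a`'s centre.
#' @param a,b [rigid_transform()]s.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  Ra <- rotation_matrix(a$rotation)
  Rb <- rotation_matrix(b$rotation)
  R <- Ra %*% Rb
  # a(b(p)) = Ra(Rb(p - cb) + cb + tb - ca) + ca + ta; re-expressed
  # about cb: t_new = a(b(0)) - (R(0 - cb) + cb)
  ca <- a$center; cb <- b$center
  t_new <- as.numeric(Ra %*% (Rb %*% (-cb) + cb + b$translation - ca) +
                        ca + a$translation - (R %*% (-cb) + cb))
  rigid_transform(rotation = angles_from_matrix(R),
                  translation = t_new, center = cb)
}

is_identity_transform <- function(tf, tol = 1e-9) {
  all(abs(tf$rotation) <= tol) && all(abs(tf$translation) <= tol)
}

#' Serialise a rigid transform to a plain-text parameter file
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  lines <- c("# rigid transform parameters (degrees, mm)",
             sprintf("rotation: %.12g %.12g %.12g",
                     transform$rotation[1], transform$rotation[2],
                     transform$rotation[3]),
             sprintf("translation: %.12g %.12g %.12g",
                     transform$translation[1], transform$translation[2],
                     transform$translation[3]),
             sprintf("center: %.12g %.12g %.12g",
                     transform$center[1], transform$center[2],
                     transform$center[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rigid transform from a plain-text parameter file
#' @param path file written by [write_transform()].
#' @return A `rigid_transform`.
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  get3 <- function(key) {
    l <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(l) != 1) stop(sprintf("transform file missing '%s'", key))
    as.numeric(strsplit(trimws(sub(".*:", "", l)), "\\s+")[[1]])
  }
  rigid_transform(get3("rotation"), get3("translation"), get3("center"))
}

#' Physical centre of a voxel grid
#' @param grid a `volume_grid`.
#' @return Length-3 numeric, the grid centre in mm.
#' @export
grid_phys_center <- function(grid) {
  grid$origin + (grid$dims - 1) / 2 * grid$spacing
}

# physical coordinates of every voxel of a grid, one row per voxel in
# storage (x-fastest) order
grid_points <- function(grid, stride = 1L) {
  ix <- seq(1L, grid$dims[1], by = stride)
  iy <- seq(1L, grid$dims[2], by = stride)
  iz <- seq(1L, grid$dims[3], by = stride)
  pts <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  list(idx = pts,
       phys = sweep(sweep(pts - 1, 2, grid$spacing, "*"), 2,
                    grid$origin, "+"))
}

phys_to_index <- function(grid, phys) {
  sweep(sweep(phys, 2, grid$origin), 2, grid$spacing, "/") + 1
}

#' Resample a volume through a rigid transform
#'
#' Evaluates the moving image at `transform(p)` for each voxel centre `p`
#' of the target grid. Linear interpolation for images,
#' nearest-neighbour for masks (preserves binarity).
#'
#' @param img a `volume_image`.
#' @param transform [rigid_transform()] mapping target physical points
#'   into the moving image's space.
#' @param target a `volume_grid` to resample onto.
#' @param interp `"linear"` or `"nearest"`.
#' @param default value for points mapping outside the moving volume.
#' @return A `volume_image` on `target`.
#' @export
resample_volume <- function(img, transform, target,
                            interp = c("linear", "nearest"), default = 0) {
  interp <- match.arg(interp)
  stopifnot(inherits(img, "volume_image"), inherits(target, "volume_grid"))
  gp <- grid_points(target)
  mp <- transform_points(transform, gp$phys)
  mi <- phys_to_index(img$grid, mp)
  vals <- if (interp == "linear")
    interp3(img$values, mi[, 1], mi[, 2], mi[, 3], default = NA_real_)
  else nn3(img$values, mi[, 1], mi[, 2], mi[, 3], default = NA)
  vals[is.na(vals)] <- default
  volume_image(vals, target)
}

#' Resample a binary mask through a rigid transform
#'
#' Nearest-neighbour resampling; output stays boolean. Voxels mapping
#' outside the source mask's extent are background.
#'
#' @param mask a `binary_mask`.
#' @param transform [rigid_transform()] mapping target physical points
#'   into the mask's space.
#' @param target target `volume_grid`.
#' @return A `binary_mask` on `target`.
#' @export
resample_mask <- function(mask, transform, target) {
  stopifnot(inherits(mask, "binary_mask"))
  as_img <- volume_image(as.numeric(mask$values), mask$grid)
  res <- resample_volume(as_img, transform, target, interp = "nearest",
                         default = 0)
  binary_mask(res$values > 0.5, target)
}

mutual_information <- function(fv, mv, bins, frange, mrange) {
  fb <- pmin(pmax(floor((fv - frange[1]) / diff(frange) * bins) + 1L, 1L),
             bins)
  mb <- pmin(pmax(floor((mv - mrange[1]) / diff(mrange) * bins) + 1L, 1L),
             bins)
  h <- tabulate(fb + bins * (mb - 1L), bins * bins)
  p <- h / sum(h)
  px <- rowSums(matrix(p, bins))
  py <- colSums(matrix(p, bins))
  nz <- p > 0
  hxy <- -sum(p[nz] * log(p[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hx + hy - hxy
}

downsample_volume <- function(img, f) {
  if (f <= 1) return(img)
  v <- smooth_gaussian3(img$values, rep(f / 2, 3))
  ix <- seq(1L, dim(v)[1], by = f)
  iy <- seq(1L, dim(v)[2], by = f)
  iz <- seq(1L, dim(v)[3], by = f)
  g <- volume_grid(c(length(ix), length(iy), length(iz)),
                   img$grid$spacing * f, img$grid$origin)
  volume_image(v[ix, iy, iz], g)
}

#' Rigid registration by mutual-information maximisation
#'
#' Estimates the 6-DOF transform aligning `moving` to `fixed` (the
#' returned transform maps fixed physical points into moving space, ready
#' for [resample_volume()]/[resample_mask()]). Mutual information is used
#' as the similarity metric because the structural T1 and the
#' fat-suppressed DCE frames have inverted fat/gland contrast, which
#' defeats correlation-type metrics. Optimisation is multi-resolution
#' (Nelder-Mead per level) with an exhaustive translation pre-search at
#' the coarsest level. Fully deterministic: voxel subsampling uses a
#' fixed stride, so `seed` is recorded but does not alter the result.
#'
#' If the optimum fails to improve mutual information over the identity
#' transform by more than `params$min_gain`, the identity is returned
#' with attribute `warning = TRUE`.
#'
#' @param fixed,moving non-constant `volume_image`s.
#' @param params list of settings, see [registration_params()].
#' @return A [rigid_transform()] with attributes `metric` (final mutual
#'   information), `metric_identity` and `warning`.
#' @export
rigid_register <- function(fixed, moving, params = registration_params()) {
  stopifnot(inherits(fixed, "volume_image"), inherits(moving, "volume_image"))
  if (diff(range(fixed$values)) == 0 || diff(range(moving$values)) == 0)
    stop("cannot register constant-intensity volumes")
  center <- grid_phys_center(fixed$grid)
  frange <- range(fixed$values)
  mrange <- range(moving$values)
  bins <- params$bins

  # per-level sampling context: fixed values and physical points are
  # computed once, the metric only re-maps them per candidate transform
  level_ctx <- function(fx, stride) {
    gp <- grid_points(fx$grid, stride)
    list(fv = fx$values[gp$idx], phys = gp$phys)
  }
  metric_ctx <- function(ctx, par) {
    tf <- rigid_transform(par[1:3], par[4:6], center)
    mp <- transform_points(tf, ctx$phys)
    mi_idx <- phys_to_index(moving$grid, mp)
    mv <- interp3(moving$values, mi_idx[, 1], mi_idx[, 2], mi_idx[, 3])
    ok <- !is.na(mv)
    frac <- mean(ok)
    if (sum(ok) < 100) return(-frac)
    # down-weight low-overlap configurations: mutual information alone
    # rewards sliding one volume mostly off the other
    mutual_information(ctx$fv[ok], mv[ok], bins, frange, mrange) *
      min(1, frac / 0.5)
  }

  # centre-of-mass translation initialisation: with small rotations the
  # foreground mass centres of the two volumes differ by the translation
  com <- function(img) {
    w <- pmax(img$values - stats::median(img$values), 0)
    gp <- grid_points(img$grid)
    colSums(gp$phys * as.vector(w)) / sum(w)
  }
  t_init <- com(moving) - com(fixed)

  nm <- function(ctx, start, maxit) {
    stats::optim(start, function(p) -metric_ctx(ctx, p),
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8,
                                parscale = rep(2, 6)))
  }

  # drop pyramid levels that would leave too few voxels per axis
  levels <- params$levels[
    vapply(params$levels,
           function(f) f == 1L || all(fixed$grid$dims %/% f >= 12),
           logical(1))]
  # finest-level stride: auto-pick the smallest stride that keeps the
  # metric sample count near 150k (denser sampling on small volumes)
  fine_stride <- params$fine_stride
  if (is.null(fine_stride))
    fine_stride <- max(1L,
                       as.integer(ceiling((prod(fixed$grid$dims) /
                                             150000)^(1 / 3))))
  par <- c(rep(0, 3), t_init)
  ctx <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- downsample_volume(fixed, f)
    stride <- if (f > 1) 1L else fine_stride
    ctx <- level_ctx(fx, stride)
    if (li == 1L && params$search_range > 0) {
      # exhaustive translation pre-search at the coarsest level, around
      # the centre-of-mass initialisation (and around zero)
      steps <- seq(-params$search_range, params$search_range,
                   by = params$search_step)
      best <- metric_ctx(ctx, par)
      for (t0 in list(t_init, c(0, 0, 0)))
        for (tx in steps) for (ty in steps) for (tz in steps) {
          cand <- c(par[1:3], t0 + c(tx, ty, tz))
          m <- metric_ctx(ctx, cand)
          if (m > best) { best <- m; par <- cand }
        }
      # rotation multi-start: short Nelder-Mead runs from a coarse grid
      # of rotation offsets; the best few candidates are carried to the
      # next level rather than committing to one basin at the lowest
      # resolution
      rots <- params$rotation_starts
      cand <- list()
      for (rx in rots) for (ry in rots) for (rz in rots) {
        o <- nm(ctx, c(par[1:3] + c(rx, ry, rz), par[4:6]), maxit = 120L)
        cand[[length(cand) + 1L]] <- list(par = o$par, value = -o$value)
      }
      cand <- cand[order(-vapply(cand, `[[`, numeric(1), "value"))]
      carried <- lapply(cand[seq_len(min(3, length(cand)))], `[[`, "par")
      par <- carried[[1]]
    }
    if (li == 2L && exists("carried") && length(carried) > 1) {
      # re-rank the carried candidates at this finer resolution
      refined <- lapply(carried, function(p0) nm(ctx, p0, params$maxit))
      vals <- vapply(refined, function(o) -o$value, numeric(1))
      par <- refined[[which.max(vals)]]$par
      carried <- list(par)
    }
    # at the finest level a second Nelder-Mead run rebuilds the simplex
    # around the optimum and escapes premature stalls
    for (run in seq_len(if (li == length(levels)) 2L else 1L)) {
      opt <- nm(ctx, par, params$maxit)
      if (-opt$value > metric_ctx(ctx, par)) par <- opt$par
    }
  }

  m_final <- metric_ctx(ctx, par)
  m_id <- metric_ctx(ctx, rep(0, 6))
  if (!is.finite(m_final) || m_final <= m_id + params$min_gain) {
    # no real improvement over identity: report identity, flag it
    out <- rigid_transform(center = center)
    attr(out, "warning") <- !isTRUE(all.equal(par, rep(0, 6),
                                              tolerance = 1e-6))
    attr(out, "metric") <- m_id
    attr(out, "metric_identity") <- m_id
    return(out)
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "warning") <- FALSE
  attr(out, "metric") <- m_final
  attr(out, "metric_identity") <- m_id
  out
}

#' Registration settings
#'
#' @param levels downsampling factors, coarse to fine.
#' @param bins histogram bins per axis for mutual information.
#' @param maxit Nelder-Mead iteration cap per level.
#' @param search_range,search_step coarse translation pre-search extent
#'   and step (mm); range 0 disables the pre-search.
#' @param rotation_starts per-axis rotation offsets (degrees) for the
#'   coarse-level multi-start.
#' @param fine_stride voxel subsampling stride at the finest level;
#'   `NULL` picks the smallest stride keeping about 150k samples.
#' @param min_gain minimum mutual-information gain over identity before
#'   the estimate is trusted.
#' @param seed recorded for provenance; the algorithm is deterministic.
#' @return A named list of settings.
#' @export
registration_params <- function(levels = c(4L, 2L, 1L), bins = 32L,
                                maxit = 250L, search_range = 12,
                                search_step = 4, fine_stride = NULL,
                                rotation_starts = c(-8, 0, 8),
                                min_gain = 1e-4, seed = 1L) {
  list(levels = as.integer(levels), bins = as.integer(bins),
       maxit = as.integer(maxit), search_range = search_range,
       search_step = search_step,
       fine_stride = if (!is.null(fine_stride)) as.integer(fine_stride),
       rotation_starts = rotation_starts,
       min_gain = min_gain, seed = as.integer(seed))
}
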