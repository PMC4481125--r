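# Internal 3D array utilities: shifts, separable Gaussian smoothing,
# central-difference gradients, 6-neighbourhood morphology, connected
# components and trilinear interpolation. All operate on plain 3D arrays
# and are vectorised; nothing here allocates per-voxel R objects.

shift3 <- function(a, s, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - s[ax])
      dst[[ax]] <- seq_len(d[ax] - s[ax]) + s[ax]
    } else {
      src[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]
      dst[[ax]] <- seq_len(d[ax] + s[ax])
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# one dilation/erosion step over the 6-neighbourhood; r steps give the
# discrete (city-block) ball of radius r
dilate6 <- function(m, r = 1) {
  for (i in seq_len(r)) {
    m <- m | shift3(m, c(1, 0, 0), FALSE) | shift3(m, c(-1, 0, 0), FALSE) |
      shift3(m, c(0, 1, 0), FALSE) | shift3(m, c(0, -1, 0), FALSE) |
      shift3(m, c(0, 0, 1), FALSE) | shift3(m, c(0, 0, -1), FALSE)
  }
  m
}

erode6 <- function(m, r = 1) !dilate6(!m, r)

close6 <- function(m, r = 1) if (r <= 0) m else erode6(dilate6(m, r), r)

# breadth-first flood fill (6-connectivity) from seed linear indices;
# returns the logical array of reached mask voxels
flood_fill <- function(m, seeds) {
  d <- dim(m)
  n1 <- d[1]; n12 <- d[1] * d[2]
  n <- length(m)
  visited <- logical(n)
  frontier <- seeds[m[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  # x coordinate per linear index, to guard against wrap-around on +-1
  while (length(frontier)) {
    xs <- ((frontier - 1L) %% n1) + 1L
    ys <- (((frontier - 1L) %/% n1) %% d[2]) + 1L
    zs <- ((frontier - 1L) %/% n12) + 1L
    nb <- c(frontier[xs > 1L] - 1L, frontier[xs < n1] + 1L,
            frontier[ys > 1L] - n1, frontier[ys < d[2]] + n1,
            frontier[zs > 1L] - n12, frontier[zs < d[3]] + n12)
    nb <- unique(nb)
    nb <- nb[m[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, d)
}

# labels connected components (6-connectivity); 0 outside the mask
label_components <- function(m) {
  lab <- array(0L, dim(m))
  remaining <- m
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    comp <- flood_fill(remaining, which(remaining)[1])
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

largest_component <- function(m) {
  if (!any(m)) return(m & FALSE)
  lab <- label_components(m)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# fills cavities: anything not reachable from the volume faces through
# the background becomes foreground
fill_holes <- function(m) {
  d <- dim(m)
  bg <- !m
  face <- array(FALSE, d)
  face[c(1, d[1]), , ] <- TRUE
  face[, c(1, d[2]), ] <- TRUE
  face[, , c(1, d[3])] <- TRUE
  seeds <- which(bg & face)
  if (!length(seeds)) return(m | TRUE)
  outside <- flood_fill(bg, seeds)
  m | (!outside & bg)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution along one axis with edge replication
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  r <- (length(kern) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  # pad with edge replication
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(mp, kern, sides = 2)
  f <- f[(r + 1L):(r + nrow(m)), , drop = FALSE]
  out <- array(as.numeric(f), dp)
  aperm(out, order(perm))
}

smooth_gaussian3 <- function(a, sigma) {
  if (all(sigma <= 0)) return(a)
  sigma <- rep_len(sigma, 3)
  for (ax in 1:3)
    if (sigma[ax] > 0) a <- conv_axis(a, gauss_kernel(sigma[ax]), ax)
  a
}

# central differences in intensity units per voxel along one axis
gradient_axis <- function(a, axis) {
  s <- c(0, 0, 0); s[axis] <- 1L
  fwd <- shift3(a, -s)   # value at i+1
  bwd <- shift3(a, s)    # value at i-1
  g <- (fwd - bwd) / 2
  # one-sided at the faces
  d <- dim(a)
  g_first <- (fwd - a)
  g_last <- (a - bwd)
  pick <- slice_index(d, axis, 1L)
  g[pick] <- g_first[pick]
  pick <- slice_index(d, axis, d[axis])
  g[pick] <- g_last[pick]
  g
}

slice_index <- function(d, axis, i) {
  m <- array(FALSE, d)
  if (axis == 1) m[i, , ] <- TRUE
  else if (axis == 2) m[, i, ] <- TRUE
  else m[, , i] <- TRUE
  m
}

# vectorised trilinear interpolation at fractional 1-based voxel indices;
# coordinates outside the lattice return `default`
interp3 <- function(a, xi, yi, zi, default = NA_real_) {
  d <- dim(a)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3] &
    is.finite(xi) & is.finite(yi) & is.finite(zi)
  out <- rep(default, length(xi))
  if (!any(ok)) return(out)
  x <- xi[ok]; y <- yi[ok]; z <- zi[ok]
  x0 <- pmin(floor(x), d[1] - 1); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(y), d[2] - 1); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(z), d[3] - 1); z0 <- pmax(z0, 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (x0) + (y0 - 1) * n1 + (z0 - 1) * n12  # linear index of (x0,y0,z0)
  v000 <- a[base];            v100 <- a[base + 1]
  v010 <- a[base + n1];       v110 <- a[base + n1 + 1]
  v001 <- a[base + n12];      v101 <- a[base + n12 + 1]
  v011 <- a[base + n1 + n12]; v111 <- a[base + n1 + n12 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# nearest-neighbour lookup at fractional 1-based indices
nn3 <- function(a, xi, yi, zi, default = NA) {
  d <- dim(a)
  x <- round(xi); y <- round(yi); z <- round(zi)
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(default, length(xi))
  out[ok] <- a[cbind(x[ok], y[ok], z[ok])]
  out
}
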