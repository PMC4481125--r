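# Fixtures and independent oracles used across the test files. All data
# are generated in code; nothing is read from disk.

# small phantom for fast unit tests (half-size grid, same structure)
small_phantom_spec <- function(seed = 11L, ...) {
  phantom_spec(dims = c(48L, 48L, 32L), breast_semi_axes = c(19, 22, 13),
               chest_slab_mm = 13, fgt_blob_count = 6L, seed = seed, ...)
}

identity_small_spec <- function(seed = 11L, ...) {
  g <- volume_grid(c(48L, 48L, 32L))
  small_phantom_spec(
    seed = seed,
    inter_scan_transform = rigid_transform(center = grid_phys_center(g)),
    ...)
}

const_vol <- function(value, dims = c(4, 4, 4), spacing = c(1, 1, 1)) {
  volume_image(array(value, dims), volume_grid(dims, spacing))
}

# --- independent oracles -------------------------------------------------

# exhaustive Mann-Whitney pair counting (ties 0.5)
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Benjamini-Hochberg from the definition: p(i) * n / i with a running
# minimum from the largest rank down
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# balanced two-way ANOVA with interaction, from raw sums of squares
anova_ss_oracle <- function(values, group, phase) {
  group <- factor(group); phase <- factor(phase)
  gm <- mean(values)
  a_means <- tapply(values, group, mean)
  b_means <- tapply(values, phase, mean)
  cell_means <- tapply(values, list(group, phase), mean)
  n_cell <- table(group, phase)
  stopifnot(length(unique(as.vector(n_cell))) == 1)  # balanced
  nc <- n_cell[1, 1]
  ss_a <- sum(table(group) * (a_means - gm)^2)
  ss_b <- sum(table(phase) * (b_means - gm)^2)
  ss_cells <- sum(n_cell * (cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  fitted <- cell_means[cbind(group, phase)]
  ss_e <- sum((values - fitted)^2)
  df_ab <- (nlevels(group) - 1) * (nlevels(phase) - 1)
  df_e <- length(values) - nlevels(group) * nlevels(phase)
  f <- (ss_ab / df_ab) / (ss_e / df_e)
  list(F = f, p = stats::pf(f, df_ab, df_e, lower.tail = FALSE))
}

# cohort measure table with all change multipliers forced to 1 (null)
default_cohort_measures_null <- function() {
  ms <- bpequant:::default_cohort_measures()
  ms$mult_g0 <- 1
  ms$mult_g1 <- 1
  ms
}

# closed-form paired t (mean difference over its standard error)
paired_t_oracle <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}
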