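# Independent brute-force oracles used to pin down expected values.

# lattice-point count of an ellipsoid on the phantom's voxel-centre grid,
# by explicit enumeration (independent of the vectorized generator)
oracle_ellipsoid_count <- function(spec) {
  gs <- spec$grid_shape
  ctr <- (gs - 1) / 2 + spec$center_offset_vox
  g <- expand.grid(z = seq_len(gs[1]) - 1, y = seq_len(gs[2]) - 1,
                   x = seq_len(gs[3]) - 1)
  u2 <- ((g$z - ctr[1]) * spec$voxel_spacing_um[1] / spec$cell_radius_um[1])^2 +
    ((g$y - ctr[2]) * spec$voxel_spacing_um[2] / spec$cell_radius_um[2])^2 +
    ((g$x - ctr[3]) * spec$voxel_spacing_um[3] / spec$cell_radius_um[3])^2
  sum(u2 <= 1)
}

# sort-and-split shell partition by explicit data-frame ordering
oracle_shell_partition <- function(section, center, n_shells = 8,
                                   spacing = c(1, 1)) {
  nr <- nrow(section); nc <- ncol(section)
  df <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  df$lin <- df$row + (df$col - 1) * nr
  df$rm <- (df$row - 1) * nc + df$col
  df$d <- sqrt(((df$row - center[1]) * spacing[1])^2 +
                 ((df$col - center[2]) * spacing[2])^2)
  df <- df[order(df$d, df$rm), ]
  n <- nrow(df)
  sizes <- rep(n %/% n_shells, n_shells)
  r <- n %% n_shells
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  split(df$lin, rep(seq_len(n_shells), sizes))
}

# classical one-way ANOVA from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  ni <- tabulate(groups)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
}

# pooled-variance two-sample t from the textbook formula
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

# AUROC by explicit enumeration of all positive-negative pairs
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

with_seed <- tomoshell:::with_seed

# small fast phantom defaults shared across tests
tiny_spec <- function(...) {
  phantom_spec(cell_radius_um = 3, voxel_spacing_um = 0.3,
               grid_shape = c(32, 32, 32), ...)
}
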