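# Independent brute-force oracles and small fixtures used across the suite.
# Oracles deliberately use naive loops / direct counting so they share no
# code path with the implementation they check.

# trilinear interpolation of one point, scalar loop version
oracle_trilinear_point <- function(values, spacing, origin, p) {
  sh <- dim(values)
  t <- (p - origin) / spacing
  if (any(t < 0) || any(t > sh - 1)) return(0)
  i0 <- pmin(floor(t), sh - 2); i0 <- pmax(i0, 0)
  f <- t - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# ellipsoidal-distance mask expansion by exhaustive pairwise check
oracle_expand <- function(mask, margin) {
  g <- mask$geometry
  if (length(margin) == 1L) margin <- rep(margin, 3)
  ctrs <- voxel_centers(g)
  members <- ctrs[as.vector(mask$values), , drop = FALSE]
  out <- logical(nrow(ctrs))
  for (i in seq_len(nrow(ctrs))) {
    for (j in seq_len(nrow(members))) {
      d <- ctrs[i, ] - members[j, ]
      r2 <- 0
      for (a in 1:3) {
        r2 <- r2 + if (margin[a] > 0) (d[a] / margin[a])^2 else
          if (abs(d[a]) > 1e-12) Inf else 0
      }
      if (r2 <= 1 + 1e-9) { out[i] <- TRUE; break }
    }
  }
  binary_mask(g, array(out, dim = g$shape))
}

# exact two-sided signed-rank p by full 2^n enumeration
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# small random dose volume on a random <= 20^3 grid
random_dose <- function(seed, max_dim = 20L) {
  set.seed(seed)
  sh <- sample(3:max_dim, 3, replace = TRUE)
  g <- grid_geometry(sh, spacing = runif(3, 0.8, 3))
  scalar_volume(g, array(runif(prod(sh), 0, 70), dim = sh), kind = "dose")
}

random_mask <- function(geometry, seed, p = 0.4) {
  set.seed(seed)
  vals <- array(runif(prod(geometry$shape)) < p, dim = geometry$shape)
  if (!any(vals)) vals[1] <- TRUE
  binary_mask(geometry, vals)
}

# compact phantom for fast end-to-end tests (coarser grid, smaller body)
small_phantom <- function(gtv_radius = 8, spacing = 4) {
  n <- round(c(200, 160, 200) / spacing * 0.6)
  phantom_spec(
    geometry = grid_geometry(n, spacing = rep(spacing, 3)),
    gtv_center = c(30, -15, 0), gtv_radius = gtv_radius,
    body_semiaxes = c(60, 48, 60), lung_semiaxes = c(26, 36, 50),
    lung_offset_x = 30)
}
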