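# Small, fast phantom used by the unit tests (coarser grid than the
# package defaults; noise off unless a test turns it on).
small_spec <- function(noise_sigma_hu = 0,
                       lung_semi_axes = list(c(14, 55, 38), c(14, 55, 38)),
                       lung_centers = list(c(0, 0, -46), c(0, 0, 46)),
                       ...) {
  phantom_spec(
    grid_shape = c(24L, 96L, 96L), voxel_spacing = c(1.5, 3, 3),
    body_semi_axes = c(90, 120),
    lung_semi_axes = lung_semi_axes, lung_centers = lung_centers,
    cluster_radius_mm = 9, noise_sigma_hu = noise_sigma_hu, ...)
}

# lung-free water phantom: body ellipse of the given semi-axes at 0 HU
water_spec <- function(semi_axes, spacing_mm = 1, slices = 3L) {
  fov <- 2 * ceiling(max(semi_axes) / spacing_mm) + 20L
  phantom_spec(
    grid_shape = c(slices, fov, fov),
    voxel_spacing = c(1, spacing_mm, spacing_mm),
    body_semi_axes = semi_axes, body_hu = 0,
    lung_semi_axes = list(), lung_centers = list(),
    emphysema_fraction = 0, noise_sigma_hu = 0, vnc_offset_hu = 0)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force enumeration oracles for the exact rank tests ------------

enum_wilcoxon <- function(x, y) {
  d <- y - x
  dz <- d[d != 0]
  n <- length(dz)
  r <- rank(abs(dz))
  w <- sum(r[dz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  cl <- sum(ws <= w)
  cg <- sum(ws >= w)
  list(statistic = w, p = min(1, 2 * min(cl, cg) / 2^n))
}

enum_mann_whitney <- function(a, b) {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  u_of <- function(aa, bb)
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  ua_obs <- u_of(a, b)
  comb <- utils::combn(m + n, m)
  uas <- apply(comb, 2, function(idx) u_of(pool[idx], pool[-idx]))
  cl <- sum(uas <= ua_obs)
  cg <- sum(uas >= ua_obs)
  list(U_a = ua_obs, U = min(ua_obs, m * n - ua_obs),
       p = min(1, 2 * min(cl, cg) / choose(m + n, m)))
}
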