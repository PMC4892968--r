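# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# Small phantom (3.84 mm box) for unit tests: fast to generate and register.
small_phantom_config <- function(seed = 42L, ...) {
  phantom_config(grid_size = 32L, r_inner = 0.8, r_outer = 1.4,
                 section_spacing = 0.24, n_areas = 6L,
                 n_injections = 2L, n_cells_per_injection = 60L,
                 injection_radius = 0.2, seed = seed, ...)
}

small_template <- function() cached("small_template", make_template(small_phantom_config()))

# Clean (distortion-free) small phantom.
clean_phantom_config <- function(seed = 43L)
  small_phantom_config(seed = seed, jitter_trans_sd = 0, jitter_rot_sd = 0,
                       deform_amplitude = 0, affine_scale_range = c(1, 1),
                       affine_shear_max = 0, affine_rot_max = 0,
                       affine_trans_max = 0)

# The full default-conditions phantom study (expensive; computed once and
# reused by the acceptance tests).
full_phantom_study <- function() {
  cached("full_study", run_phantom_study(phantom_config(seed = 7L)))
}

# Spherical-shell label fixture with analytic cortex between r_inner and
# r_outer (full sphere), used by the depth oracles.
shell_labels <- function(n = 64L, spacing = 0.1, r_inner = 2, r_outer = 3) {
  ax <- (seq_len(n) - 1) * spacing
  ctr <- rep((n - 1) * spacing / 2, 3)
  dx <- rep(ax - ctr[1], times = n * n)
  dy <- rep(rep(ax - ctr[2], each = n), times = n)
  dz <- rep(ax - ctr[3], each = n * n)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  lab <- numeric(n^3)
  lab[r >= r_inner & r <= r_outer] <- 1
  lab[r < r_inner] <- 2
  tm_volume(array(lab, c(n, n, n)), rep(spacing, 3), c(0, 0, 0), kind = "label")
}

# Flat slab: cortex 5 voxels thick between outside (below) and white matter
# (above) along the z axis.
slab_labels <- function(nxy = 16L, spacing = 0.1) {
  lab <- array(0, c(nxy, nxy, 11))
  lab[, , 4:8] <- 1
  lab[, , 9:11] <- 2
  tm_volume(lab, rep(spacing, 3), c(0, 0, 0), kind = "label")
}

# Test-local bilinear/trilinear samplers, independent of the package's
# interpolation code, for stage-by-stage transform oracles.
oracle_interp2 <- function(arr, spacing, origin, p) {
  cx <- (p[1] - origin[1]) / spacing[1]
  cy <- (p[2] - origin[2]) / spacing[2]
  d <- dim(arr)
  cx <- min(max(cx, 0), d[1] - 1); cy <- min(max(cy, 0), d[2] - 1)
  i0 <- floor(cx); j0 <- floor(cy)
  i1 <- min(i0 + 1, d[1] - 1); j1 <- min(j0 + 1, d[2] - 1)
  fx <- cx - i0; fy <- cy - j0
  v0 <- arr[i0 + 1, j0 + 1] * (1 - fx) + arr[i1 + 1, j0 + 1] * fx
  v1 <- arr[i0 + 1, j1 + 1] * (1 - fx) + arr[i1 + 1, j1 + 1] * fx
  v0 * (1 - fy) + v1 * fy
}

oracle_interp3 <- function(arr, spacing, origin, p) {
  cc <- (p - origin) / spacing
  d <- dim(arr)
  cc <- pmin(pmax(cc, 0), d - 1)
  i0 <- floor(cc); i1 <- pmin(i0 + 1, d - 1)
  f <- cc - i0
  v <- 0
  for (a in 0:1) for (b in 0:1) for (cz in 0:1) {
    idx <- c(if (a) i1[1] else i0[1], if (b) i1[2] else i0[2],
             if (cz) i1[3] else i0[3]) + 1
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    v <- v + w * arr[idx[1], idx[2], idx[3]]
  }
  v
}
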