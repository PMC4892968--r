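test_that("world/voxel conversion round-trips for arbitrary geometries", {
  set.seed(1)
  for (i in 1:20) {
    vol <- tm_volume(array(0, c(4, 5, 6)),
                     spacing = runif(3, 0.01, 2),
                     origin = runif(3, -20, 20))
    v <- matrix(runif(60, -3, 10), ncol = 3)
    w <- voxel_to_world(vol, v)
    expect_lt(max(abs(world_to_voxel(vol, w) - v)), 1e-9)
  }
})

test_that("volume invariants are enforced", {
  expect_error(tm_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  expect_error(tm_volume(array(-1, c(2, 2, 2)), spacing = rep(1, 3), kind = "label"),
               "non-negative")
  expect_error(sample_volume(tm_volume(array(1, c(2, 2, 2)), rep(1, 3), kind = "label"),
                             c(0, 0, 0), interp = "linear"), "ContractViolation")
})

test_that("identity and pure-translation chains map section points directly", {
  st <- tm_stack(rep(list(matrix(0, 8, 8)), 5), in_plane_spacing = 0.5,
                 section_spacing = 0.2, origin_axis = -1.0)
  ch <- identity_chain(st)
  # section 3 lies at AP = -1.0 + 2 * 0.2 = -0.6
  expect_equal(as.vector(map_point_through_chain(ch, 3, c(1.0, 2.0))),
               c(1.0, -0.6, 2.0))
  ch$to_template_affine <- affine3d(diag(3), c(0.5, 0, 0))
  expect_equal(as.vector(map_point_through_chain(ch, 3, c(1.0, 2.0))),
               c(1.5, -0.6, 2.0))
  expect_error(map_point_through_chain(ch, 6, c(0, 0)), "MissingTransform")
})

random_smooth_field2 <- function(d, spacing, origin, amp) {
  comps <- lapply(1:2, function(a) {
    m <- matrix(rnorm(prod(d)), d[1], d[2])
    m <- array(tracemap:::cpp_gauss2(as.double(m), d, c(3, 3)), d)
    m / max(abs(m)) * amp
  })
  displacement_field(comps, rep(spacing, 2), origin)
}

random_smooth_field3 <- function(d, spacing, origin, amp) {
  comps <- lapply(1:3, function(a) {
    m <- array(rnorm(prod(d)), d)
    m <- array(tracemap:::cpp_gauss3(as.double(m), d, c(3, 3, 3)), d)
    m / max(abs(m)) * amp
  })
  displacement_field(comps, rep(spacing, 3), origin)
}

test_that("chain mapping matches an independent stage-by-stage composition", {
  set.seed(2)
  n_sec <- 4
  d2 <- c(20, 20)
  sp2 <- 0.2
  fields <- replicate(n_sec, random_smooth_field2(d2, sp2, c(0, 0), 0.15),
                      simplify = FALSE)
  rigids <- replicate(n_sec, rigid2d(rnorm(1, 0, 0.05), rnorm(1, 0, 0.15),
                                     rnorm(1, 0, 0.15), 1.9, 1.9),
                      simplify = FALSE)
  A1 <- affine3d(diag(3) + matrix(rnorm(9, 0, 0.02), 3, 3), rnorm(3, 0, 0.2))
  A2 <- affine3d(diag(3) + matrix(rnorm(9, 0, 0.02), 3, 3), rnorm(3, 0, 0.2))
  # 3D field domain comfortably contains every composed point
  f3 <- random_smooth_field3(c(20, 20, 20), 0.3, c(-1, -1, -1), 0.1)
  ch <- transform_chain(
    per_section = lapply(1:n_sec, function(s) list(rigid = rigids[[s]],
                                                   field = fields[[s]])),
    section_positions = seq(0.3, by = 0.4, length.out = n_sec),
    reconstruction_affine = A1, to_template_affine = A2, to_template_field = f3)
  secs <- sample(1:n_sec, 1000, replace = TRUE)
  pts <- cbind(runif(1000, 0.8, 3.0), runif(1000, 0.8, 3.0))
  got <- map_point_through_chain(ch, secs, pts)
  # independent per-point, per-stage composition written out longhand
  for (i in seq_len(50)) {
    s <- secs[i]
    p <- pts[i, ]
    rg <- rigids[[s]]
    R <- matrix(c(cos(rg$theta), sin(rg$theta), -sin(rg$theta), cos(rg$theta)), 2, 2)
    q <- as.vector(R %*% (p - rg$center)) + rg$center + rg$t
    fq <- c(oracle_interp2(fields[[s]]$components[[1]], rep(sp2, 2), c(0, 0), q),
            oracle_interp2(fields[[s]]$components[[2]], rep(sp2, 2), c(0, 0), q))
    q <- q + fq
    P <- c(q[1], ch$section_positions[s], q[2])
    P <- as.vector(A1$A %*% P) + A1$t
    P <- as.vector(A2$A %*% P) + A2$t
    dP <- vapply(1:3, function(a)
      oracle_interp3(f3$components[[a]], f3$spacing, f3$origin, P), numeric(1))
    expect_lt(max(abs(got[i, ] - (P + dP))), 1e-6)
  }
})

test_that("chain JSON serialization round-trips mapped points bit-for-bit", {
  set.seed(3)
  d2 <- c(12, 12)
  ch <- transform_chain(
    per_section = list(
      list(rigid = rigid2d(0.123456789, 0.1, -0.2, 1, 1),
           field = random_smooth_field2(d2, 0.3, c(0, 0), 0.1)),
      list(rigid = rigid2d(-0.05, 0.01, 0.02, 1, 1), field = NULL)),
    section_positions = c(0.15, 0.45),
    reconstruction_affine = affine3d(diag(3) + matrix(rnorm(9, 0, 0.02), 3, 3),
                                     rnorm(3)),
    to_template_affine = affine3d(diag(3), c(1 / 3, sqrt(2), pi)),
    to_template_field = random_smooth_field3(c(8, 8, 8), 0.5, c(0, 0, 0), 0.2))
  pts <- cbind(runif(100, 0.4, 3), runif(100, 0.4, 3))
  secs <- sample(1:2, 100, replace = TRUE)
  before <- map_point_through_chain(ch, secs, pts)
  path <- withr::local_tempfile(fileext = ".json")
  write_chain_json(ch, path)
  ch2 <- read_chain_json(path)
  after <- map_point_through_chain(ch2, secs, pts)
  expect_identical(before, after)
})

test_that("resample is exact for identity and integer-voxel shifts", {
  set.seed(4)
  vol <- tm_volume(array(runif(8^3), c(8, 8, 8)), rep(0.5, 3), c(1, 2, 3))
  out <- resample(vol, vol, t = NULL, interp = "linear")
  expect_identical(out$data, vol$data)
  # integer-voxel translation, nearest: content shifts exactly
  sh <- affine3d(diag(3), c(0.5, 0, 0))  # +1 voxel along x
  out <- resample(vol, vol, t = sh, interp = "nearest", background = -1)
  expect_equal(out$data[2:8, , ], vol$data[1:7, , ])
  expect_true(all(out$data[1, , ] == -1))
})

test_that("resample matches the analytic result for a 90-degree rotation", {
  set.seed(5)
  vol <- tm_volume(array(runif(8^3), c(8, 8, 8)), rep(1, 3), c(0, 0, 0))
  ctr <- rep(3.5, 3)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # x -> y
  t <- affine3d(Rz, ctr - as.vector(Rz %*% ctr))
  out <- resample(vol, vol, t = t, interp = "nearest")
  expected <- array(0, c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expected[i, j, k] <- vol$data[j, 8 - i + 1, k]
  expect_equal(out$data, expected)
})

test_that("nearest-interp resampling never invents labels", {
  set.seed(6)
  lab <- tm_volume(array(sample(c(0, 3, 7, 11), 10^3, replace = TRUE), c(10, 10, 10)),
                   rep(0.3, 3), c(0, 0, 0), kind = "label")
  expect_identical(resample(lab, lab, interp = "nearest")$data, lab$data)
  t <- affine3d(diag(3) * 1.07 + matrix(rnorm(9, 0, 0.02), 3, 3), c(0.1, -0.2, 0.05))
  out <- resample(lab, lab, t = t, interp = "nearest")
  expect_true(all(unique(as.vector(out$data)) %in% c(0, 3, 7, 11)))
  expect_error(resample(lab, lab, t = t, interp = "linear"), "ContractViolation")
})

test_that("displacement-field inversion meets its residual contract", {
  d <- c(20, 20, 20)
  geom_sp <- rep(0.25, 3)
  # zero field inverts to zero
  z <- zero_field(d, geom_sp, c(0, 0, 0))
  expect_equal(max(abs(unlist(invert_field(z)$components))), 0)
  # constant field inverts to its negation
  cst <- displacement_field(list(array(0.3, d), array(-0.2, d), array(0.1, d)),
                            geom_sp, c(0, 0, 0))
  inv <- invert_field(cst)
  interior <- as.matrix(expand.grid(seq(1, 3.5, 0.5), seq(1, 3.5, 0.5),
                                    seq(1, 3.5, 0.5)))
  expect_lt(max(abs(field_displacement(inv, interior) -
                    rep(c(-0.3, 0.2, -0.1), each = nrow(interior)))), 0.01 * 0.25)
  # smooth sinusoidal field: round-trip residual under 0.01 voxel
  ax <- (seq_len(d[1]) - 1) * geom_sp[1]
  s1 <- 0.3 * geom_sp[1] * sin(2 * pi * ax / max(ax))
  f <- displacement_field(list(array(rep(s1, times = d[2] * d[3]), d),
                               array(0, d), array(0, d)), geom_sp, c(0, 0, 0))
  fi <- invert_field(f, tol = 0.005)
  rt <- apply_field(f, apply_field(fi, interior))
  expect_lt(max(abs(rt - interior)), 0.01 * geom_sp[1])
})

test_that("volumes and stacks survive file round-trips", {
  set.seed(7)
  vol <- tm_volume(array(runif(6^3), c(6, 6, 6)), c(0.04, 0.5, 0.04), c(-1, -19, 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path)
  back <- read_volume_nifti(path)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  st <- tm_stack(list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8)),
                 in_plane_spacing = 0.04, section_spacing = 0.2,
                 origin_axis = -1)
  # PNG stores 8-bit grayscale; TIFF stores 32-bit float
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  st2 <- read_stack(dir)
  expect_lt(max(abs(st2$sections[[1]] - st$sections[[1]])), 1 / 255)
  expect_equal(st2$section_spacing, st$section_spacing)
  dir2 <- withr::local_tempdir()
  write_stack(st, dir2, format = "tiff")
  st3 <- read_stack(dir2)
  expect_lt(max(abs(st3$sections[[2]] - st$sections[[2]])), 1e-6)
})
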