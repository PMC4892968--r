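# default-size (64 px) clean sections: the working image size of the pipeline
clean_default_fixture <- function() {
  cached("clean_default", {
    cfg <- phantom_config(seed = 43L, jitter_trans_sd = 0, jitter_rot_sd = 0,
                          deform_amplitude = 0, affine_scale_range = c(1, 1),
                          affine_shear_max = 0, affine_rot_max = 0,
                          affine_trans_max = 0)
    tpl <- make_template(cfg)
    sl <- slice_and_distort(tpl, cfg)
    list(cfg = cfg, stack = sl$stack, sec = sl$stack$sections[[14]],
         sp = sl$stack$in_plane_spacing)
  })
}

test_that("2D rigid registration recovers known perturbations", {
  fx <- clean_default_fixture()
  d <- dim(fx$sec)
  sp <- fx$sp
  pts <- as.matrix(expand.grid(x = (seq_len(d[1]) - 1) * sp,
                               y = (seq_len(d[2]) - 1) * sp))
  ctr <- (d - 1) * sp / 2
  recover <- function(tr_true) {
    mv <- matrix(tracemap:::sample_image2(fx$sec, sp, c(0, 0),
                                          apply_rigid2d(tr_true, pts)), d[1], d[2])
    register_rigid_2d(mv, fx$sec, sp, c(0, 0))
  }
  # self-registration stays at identity
  rg <- recover(rigid2d(0, 0, 0, ctr[1], ctr[2]))
  expect_lt(abs(rg$theta), 0.01)
  expect_lt(max(abs(rg$t)), 0.05)
  # pure translation within 0.1 mm
  rg <- recover(rigid2d(0, 1.2, -0.8, ctr[1], ctr[2]))
  expect_lt(max(abs(rg$t - c(1.2, -0.8))), 0.1)
  # 10-degree rotation within 0.5 degrees
  rg <- recover(rigid2d(10 * pi / 180, 0, 0, ctr[1], ctr[2]))
  expect_lt(abs(rg$theta - 10 * pi / 180), 0.5 * pi / 180)
})

test_that("affine reconstruction leaves an undistorted stack alone", {
  cfg <- clean_phantom_config()
  tpl <- make_template(cfg)
  sl <- slice_and_distort(tpl, cfg)
  rcfg <- reconstruction_config(n_outer_iterations = 3L, max_eval = 250L)
  ar <- affine_reconstruction(sl$stack, tpl$intensity, rcfg)
  for (s in seq_along(ar$rigids)) {
    expect_lt(abs(ar$rigids[[s]]$theta), 0.5 * pi / 180)
    expect_lt(max(abs(ar$rigids[[s]]$t)), 0.1)
  }
  # mean MI never decreases across iterations (within tolerance)
  expect_true(all(diff(ar$mi_log) > -rcfg$tol))
})

test_that("affine reconstruction recovers rigid jitter against ground truth", {
  cfg <- small_phantom_config(seed = 50L, deform_amplitude = 0,
                              affine_scale_range = c(1, 1), affine_shear_max = 0,
                              affine_rot_max = 0, affine_trans_max = 0,
                              jitter_trans_sd = 0.5, jitter_rot_sd = 0.03)
  tpl <- make_template(cfg)
  sl <- slice_and_distort(tpl, cfg)
  ar <- affine_reconstruction(sl$stack, tpl$intensity,
                              reconstruction_config(n_outer_iterations = 5L,
                                                    max_eval = 300L))
  expect_gte(utils::tail(ar$mi_log, 1), ar$mi_log[1] - 1e-9)
  # composed recovered map vs composed ground truth at in-brain points
  sp <- sl$stack$in_plane_spacing
  d <- dim(sl$stack$sections[[1]])
  pts <- as.matrix(expand.grid(x = (seq_len(d[1]) - 1) * sp,
                               y = (seq_len(d[2]) - 1) * sp))
  errs <- vapply(seq_along(ar$rigids), function(s) {
    inb <- as.vector(sl$mask_stack$sections[[s]]) > 0
    if (sum(inb) < 20) return(NA_real_)
    p <- pts[inb, , drop = FALSE]
    q1 <- apply_rigid2d(ar$rigids[[s]], p)
    P1 <- apply_affine3d(ar$affine, cbind(q1[, 1], section_position(sl$stack, s), q1[, 2]))
    q2 <- apply_rigid2d(sl$chain$per_section[[s]]$rigid, p)
    P2 <- apply_affine3d(sl$chain$reconstruction_affine,
                         cbind(q2[, 1], section_position(sl$stack, s), q2[, 2]))
    stats::median(sqrt(rowSums((P1 - P2)^2)))
  }, numeric(1))
  expect_gte(mean(errs <= 0.2, na.rm = TRUE), 0.9)
})

test_that("deformable reconstruction is a no-op on smooth stacks", {
  # identical sections: no force anywhere, zero fields
  sec <- matrix(rep(sin(seq(0, 3, length.out = 24)), 24), 24, 24)
  dr <- deformable_reconstruction(rep(list(sec), 5), spacing = 0.1)
  expect_true(all(vapply(dr$fields, is.null, logical(1))))
  # a clean resliced phantom stays essentially untouched; only the sections
  # where the dome rim appears/disappears (fast genuine shape change between
  # neighbors) show displacement approaching the 0.05 mm scale
  fx <- clean_default_fixture()
  dr <- deformable_reconstruction(fx$stack$sections, fx$sp)
  mean_disp <- vapply(dr$fields, function(f) {
    if (is.null(f)) return(0)
    mean(sqrt(f$components[[1]]^2 + f$components[[2]]^2))
  }, numeric(1))
  expect_lt(stats::median(mean_disp), 0.02)
  expect_lt(max(mean_disp[11:22]), 0.05)
})

test_that("deformable reconstruction reduces between-section differences", {
  fx <- clean_default_fixture()
  secs <- fx$stack$sections[12:19]
  sp <- fx$sp
  d <- dim(secs[[1]])
  # alternate +/- bulge on even/odd sections, centered on the shell where
  # the image has structure
  ax <- (seq_len(d[1]) - 1) * sp
  bc <- c(fx$cfg$center[1] + (fx$cfg$r_inner + fx$cfg$r_outer) / 2,
          fx$cfg$center[3])
  g <- exp(-(outer((ax - bc[1])^2, rep(1, d[2])) +
             outer(rep(1, d[1]), (ax - bc[2])^2)) / (2 * 0.7^2))
  pts <- as.matrix(expand.grid(x = ax, y = ax))
  bulged <- lapply(seq_along(secs), function(s) {
    amp <- if (s %% 2 == 0) 0.3 else -0.3
    src <- pts + amp * cbind(as.vector(g), as.vector(g))
    matrix(tracemap:::sample_image2(secs[[s]], sp, c(0, 0), src), d[1], d[2])
  })
  dr <- deformable_reconstruction(bulged, sp,
                                  cfg = reconstruction_config(n_deformable_iterations = 8L))
  # monotone non-increasing MSD, and a large net reduction
  expect_true(all(diff(dr$msd_log) <= 1e-6))
  expect_lt(utils::tail(dr$msd_log, 1), 0.3 * dr$msd_log[1])
})
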