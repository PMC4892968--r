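test_that("template labels and geometry follow the configuration", {
  cfg <- small_phantom_config()
  tpl <- small_template()
  labs <- sort(unique(as.vector(tpl$labels$data)))
  expect_identical(labs, as.numeric(c(0, seq_len(cfg$n_areas), cfg$wm_label)))
  # every cortical voxel lies between the shell radii (exhaustive)
  vox <- which(tpl$labels$data %in% seq_len(cfg$n_areas))
  d <- dim(tpl$labels$data)
  ijk <- cbind((vox - 1) %% d[1], ((vox - 1) %/% d[1]) %% d[2],
               (vox - 1) %/% (d[1] * d[2]))
  r <- sqrt(rowSums(sweep(voxel_to_world(tpl$labels, ijk), 2, cfg$center)^2))
  expect_true(all(r >= cfg$r_inner - 1e-9 & r <= cfg$r_outer + 1e-9))
  # equal angular sectors have equal volumes up to discretization of the
  # wedge boundary planes (each sector within ~6% of the mean at 64^3)
  dtpl <- cached("default_template", make_template(phantom_config(seed = 42L)))
  dcounts <- table(dtpl$labels$data[dtpl$labels$data %in% seq_len(6)])
  expect_true(all(abs(dcounts / mean(dcounts) - 1) < 0.07))
  # at least 3 landmark sectors
  expect_gte(length(setdiff(unique(as.vector(tpl$landmarks$data)), 0)), 3)
  expect_error(phantom_config(r_inner = 2, r_outer = 1), "ConfigError")
})

test_that("zero-amplitude distortion reduces to plain reslicing", {
  cfg <- clean_phantom_config()
  tpl <- make_template(cfg)
  sl <- slice_and_distort(tpl, cfg)
  expect_identical(length(sl$stack$sections),
                   as.integer(ceiling(cfg$grid_size * cfg$spacing / cfg$section_spacing)))
  st <- sl$chain$per_section[[3]]
  expect_equal(st$rigid$theta, 0)
  expect_equal(st$rigid$t, c(0, 0))
  expect_null(st$field)
  expect_equal(sl$chain$reconstruction_affine$A, diag(3))
  # sections equal direct reslices of the template
  d <- dim(sl$stack$sections[[1]])
  pts <- as.matrix(expand.grid(x = (seq_len(d[1]) - 1) * cfg$spacing,
                               y = (seq_len(d[2]) - 1) * cfg$spacing))
  s <- 6L
  direct <- matrix(sample_volume(tpl$intensity,
                                 cbind(pts[, 1], section_position(sl$stack, s), pts[, 2])),
                   d[1], d[2])
  expect_equal(sl$stack$sections[[s]], direct)
})

test_that("ground-truth chain maps distorted points back onto the template", {
  cfg <- small_phantom_config(seed = 44L)
  tpl <- make_template(cfg)
  sl <- slice_and_distort(tpl, cfg)
  # take in-brain template points lying exactly on section planes, push them
  # into distorted-section coordinates, then map back through the chain
  set.seed(10)
  cells <- plant_cells(tpl, cfg, sl$chain)
  cells <- cells[cells$kind == "cell", ]
  mapped <- map_point_through_chain(sl$chain, cells$section,
                                    as.matrix(cells[, c("x_mm", "y_mm")]))
  # AP is quantized to the section plane by construction; the in-plane
  # round-trip must close to the inversion tolerance
  err_inplane <- sqrt((mapped[, 1] - cells$true_ml)^2 +
                      (mapped[, 3] - cells$true_dv)^2)
  expect_lt(stats::quantile(err_inplane, 0.99), 0.02)
  expect_lte(max(abs(mapped[, 2] - cells$true_ap)), cfg$section_spacing / 2 + 1e-9)
})

test_that("planted cells respect the requested distributions and determinism", {
  cfg <- small_phantom_config(seed = 45L)
  tpl <- make_template(cfg)
  sl <- slice_and_distort(tpl, cfg)
  cells <- plant_cells(tpl, cfg, sl$chain)
  cc <- cells[cells$kind == "cell", ]
  # normalized depths drawn uniform on [0.2, 0.8]: mean within 3 sigma of 0.5
  n <- nrow(cc)
  sd_mean <- sqrt(0.6^2 / 12 / n)
  expect_lt(abs(mean(cc$true_depth) - 0.5), 3 * sd_mean)
  expect_true(all(cc$true_depth >= 0.2 & cc$true_depth <= 0.8))
  # no cells planted in the injected area; injection voxels all inside it
  for (k in unique(paste(cells$animal, cells$tracer))) {
    g <- cells[paste(cells$animal, cells$tracer) == k, ]
    inj_area <- g$true_area[g$kind == "injection_voxel"][1]
    expect_true(all(g$true_area[g$kind == "cell"] != inj_area))
    expect_true(all(g$true_area[g$kind == "injection_voxel"] == inj_area))
  }
  # single-area planting
  cells_a2 <- plant_cells(tpl, cfg, sl$chain, areas = 2L)
  expect_true(all(cells_a2$true_area[cells_a2$kind == "injection_voxel"] == 2))
  # bit-for-bit determinism of the CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cells_csv(plant_cells(tpl, cfg, sl$chain), f1)
  write_cells_csv(plant_cells(tpl, cfg, sl$chain), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("phantom generation is a pure function of configuration and seed", {
  cfg <- small_phantom_config(seed = 46L)
  t1 <- make_template(cfg)
  t2 <- make_template(cfg)
  expect_identical(t1$intensity$data, t2$intensity$data)
  s1 <- slice_and_distort(t1, cfg)
  s2 <- slice_and_distort(t2, cfg)
  expect_identical(s1$stack$sections, s2$stack$sections)
  expect_identical(s1$chain$reconstruction_affine, s2$chain$reconstruction_affine)
  cfg_b <- small_phantom_config(seed = 47L)
  s3 <- slice_and_distort(t1, cfg_b)
  expect_false(identical(s1$stack$sections, s3$stack$sections))
})
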