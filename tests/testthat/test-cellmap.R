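test_that("area assignment uses labels, nearest fallback, and the tie rule", {
  tpl <- small_template()
  cfg <- small_phantom_config()
  labs <- tpl$labels
  # a voxel center inside area 3 keeps its label with zero fallback
  vox3 <- which(labs$data == 3)[10]
  d <- dim(labs$data)
  ijk <- c((vox3 - 1) %% d[1], ((vox3 - 1) %/% d[1]) %% d[2],
           (vox3 - 1) %/% (d[1] * d[2]))
  res <- assign_area(voxel_to_world(labs, ijk), labs, cfg$wm_label)
  expect_identical(res$area, 3L)
  expect_equal(res$fallback_mm, 0)
  expect_error(assign_area(c(0, 0, 0),
                           tm_volume(array(0, c(4, 4, 4)), rep(1, 3), kind = "label"),
                           wm_label = 1), "ConfigError")
})

test_that("nearest-structure fallback agrees with an exhaustive scan", {
  set.seed(40)
  lab <- array(0, c(10, 10, 10))
  lab[2:4, 2:4, 2:4] <- 2
  lab[7:9, 6:9, 3:6] <- 5
  lab[5, 5, 8] <- 9
  vol <- tm_volume(lab, rep(0.2, 3), c(0, 0, 0), kind = "label")
  pts <- cbind(runif(1000, 0, 1.8), runif(1000, 0, 1.8), runif(1000, 0, 1.8))
  got <- assign_area(pts, vol, wm_label = 99, max_fallback_mm = Inf)
  # exhaustive scan over every labeled voxel
  vox <- which(lab > 0)
  ijk <- cbind((vox - 1) %% 10, ((vox - 1) %/% 10) %% 10, (vox - 1) %/% 100)
  ctrs <- ijk * 0.2
  labs_v <- lab[vox]
  for (i in seq_len(200)) {
    dd <- sqrt(colSums((t(ctrs) - pts[i, ])^2))
    best <- min(dd)
    cands <- labs_v[dd <= best + 1e-12]
    expect_identical(as.integer(got$area[i]), as.integer(min(cands)))
  }
  # symmetric tie breaks to the smaller label: point equidistant between
  # label 4 at x=0 and label 2 at x=2 voxels
  lab2 <- array(0, c(3, 1, 1))
  lab2[1, 1, 1] <- 4
  lab2[3, 1, 1] <- 2
  vol2 <- tm_volume(lab2, rep(1, 3), c(0, 0, 0), kind = "label")
  expect_identical(assign_area(c(1, 0, 0), vol2, wm_label = 99)$area, 2L)
})

test_that("Laplace depth reproduces the analytic slab", {
  slab <- slab_labels()
  depth <- solve_depth(slab, wm_label = 2)
  vox <- which(slab$data == 1)
  th <- depth$thickness$data[vox]
  # 5 voxels at 0.1 mm: thickness 0.5 mm within 5%
  expect_true(all(abs(th - 0.5) / 0.5 < 0.05))
  # normalized depth ordering at the boundaries
  nd <- depth$norm_depth$data
  expect_true(all(nd[, , 4][slab$data[, , 4] == 1] < 0.2))
  expect_true(all(nd[, , 8][slab$data[, , 8] == 1] > 0.8))
})

test_that("Laplace depth reproduces the analytic spherical shell", {
  shell <- cached("shell_depth_fixture", {
    lab <- shell_labels()
    list(lab = lab, depth = solve_depth(lab, wm_label = 2))
  })
  lab <- shell$lab; depth <- shell$depth
  vox <- which(lab$data == 1)
  th <- depth$thickness$data[vox]
  # central estimate within 5%; per-voxel values carry up to a half-voxel
  # surface-placement error on each side of the curved shell (10% here)
  expect_lt(abs(median(th) - 1.0), 0.05)
  expect_gt(mean(abs(th - 1.0) < 0.10), 0.95)
  # mid-thickness voxels sit at radius 2.5 +/- 0.15 mm
  d <- dim(lab$data)
  mid <- which(depth$mid_mask)
  ijk <- cbind((mid - 1) %% d[1], ((mid - 1) %/% d[1]) %% d[2],
               (mid - 1) %/% (d[1] * d[2]))
  ctr <- rep((d[1] - 1) * 0.1 / 2, 3)
  r <- sqrt(rowSums(sweep(voxel_to_world(lab, ijk), 2, ctr)^2))
  expect_gt(length(r), 100)
  expect_true(all(abs(r - 2.5) <= 0.15))
  # normalized depth increases monotonically along a radial streamline
  dir <- c(1, 1, 1) / sqrt(3)
  radii <- seq(2.95, 2.05, by = -0.05)
  pts <- t(vapply(radii, function(rr) ctr + rr * dir, numeric(3)))
  nd <- depth_at_points(depth, lab, pts)$normalized_depth
  expect_true(all(diff(nd) > -1e-3))
})

test_that("depth rules for points outside the brain and in white matter", {
  shell <- cached("shell_depth_fixture", {
    lab <- shell_labels()
    list(lab = lab, depth = solve_depth(lab, wm_label = 2))
  })
  ctr <- rep((64 - 1) * 0.1 / 2, 3)
  outside <- matrix(ctr + c(3.6, 0, 0), 1)
  inside_wm <- matrix(ctr + c(1.0, 0, 0), 1)
  dd <- depth_at_points(shell$depth, shell$lab, rbind(outside, inside_wm))
  expect_equal(dd$normalized_depth, c(0, 1))
  expect_equal(dd$nominal_depth_mm[1], 0)
  expect_lt(abs(dd$nominal_depth_mm[2] - 1.0), 0.1)
})

test_that("records finalize with clamped depths and exact injection centroids", {
  tpl <- small_template()
  cfg <- small_phantom_config()
  depth <- cached("small_depth", solve_depth(tpl$labels, cfg$wm_label))
  # identity chain: stack axes coincide with template axes
  st <- tm_stack(rep(list(matrix(0, cfg$grid_size, cfg$grid_size)), 16),
                 in_plane_spacing = cfg$spacing,
                 section_spacing = cfg$section_spacing,
                 origin_axis = cfg$section_spacing / 2)
  ch <- identity_chain(st)
  ctr <- cfg$center
  # symmetric injection-voxel cloud around a mid-shell point + one point
  # planted outside the brain
  base <- ctr + c(0, 0, (cfg$r_inner + cfg$r_outer) / 2)
  offs <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0), c(0, 0, 0.1), c(0, 0, -0.1))
  cells <- data.frame(animal = "X", tracer = "FB",
                      kind = c(rep("injection_voxel", 4), "cell"),
                      section = 8,
                      x_mm = c(base[1] + offs[, 1], ctr[1] + 3.5),
                      y_mm = c(base[3] + offs[, 3], ctr[3]))
  # section 8 plane must be close to the cloud's AP plane
  cells$section <- which.min(abs(section_position(st, 1:16) - base[2]))
  fin <- finalize_records(cells, ch, tpl$labels, depth)
  outside_row <- fin$records[fin$records$kind == "cell", ]
  expect_equal(outside_row$normalized_depth, 0)
  expect_equal(outside_row$nominal_depth_mm, 0)
  inj <- fin$injections
  expect_identical(nrow(inj), 1L)
  expect_lt(abs(inj$ml - base[1]), 1e-9)
  expect_lt(abs(inj$dv - base[3]), 1e-9)
})

test_that("area summaries exclude intrinsic cells and honor grouping", {
  rec <- data.frame(kind = "cell", assigned = TRUE,
                    area = c(rep("A", 10), rep("B", 30), rep("C", 5)),
                    normalized_depth = 0.5, stringsAsFactors = FALSE)
  s <- summarize_areas(rec, injected_area = "C")
  expect_equal(s$percent[s$area == "A"], 25)
  expect_equal(s$percent[s$area == "B"], 75)
  expect_true(is.na(s$percent[s$area == "C"]))
  expect_equal(sum(s$percent, na.rm = TRUE), 100, tolerance = 1e-6)
  expect_equal(sum(s$n_cells), 45L)
  # grouping merges areas without changing the total count
  s2 <- summarize_areas(rec, injected_area = "C", grouping = list(G = c("A", "B")))
  expect_equal(s2$percent[s2$area == "G"], 100)
  expect_equal(sum(s2$n_cells), 45L)
})
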