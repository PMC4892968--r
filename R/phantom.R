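# Synthetic phantom: a parcellated hemispherical-shell "cortex" template, a
# distorted serial-section stack with known ground-truth transforms, and
# planted cells/injections. Every pipeline stage can be validated against it
# without real histology.

#' Phantom configuration
#'
#' The phantom emulates a Nissl-like template: a hemispherical shell of
#' "cortex" (between `r_inner` and `r_outer`) subdivided into equal
#' angular-sector areas around the AP axis, wrapped around a "white matter"
#' core, in an empty background. A section stack is cut coronally and
#' perturbed by per-section rigid jitter, smooth per-section deformations and
#' a global affine, mimicking the distortions that free-floating histological
#' sections suffer.
#'
#' @param grid_size voxels per axis of the cubic template grid.
#' @param spacing template voxel size in mm (isotropic).
#' @param r_inner,r_outer inner/outer shell radius in mm (gray/white border
#'   and pial surface).
#' @param n_areas number of equal angular-sector cortical areas.
#' @param n_landmarks number of landmark sectors (>= 3).
#' @param section_spacing apparent section thickness in mm.
#' @param jitter_trans_sd per-section rigid translation jitter SD, mm.
#' @param jitter_rot_sd per-section rotation jitter SD, radians.
#' @param deform_amplitude per-section smooth deformation RMS amplitude, mm.
#' @param deform_smoothness Gaussian smoothness of the deformation, mm.
#' @param affine_scale_range global affine per-axis scale range.
#' @param affine_shear_max global affine maximum shear coefficient.
#' @param affine_rot_max global affine maximum rotation, radians.
#' @param affine_trans_max global affine maximum translation, mm.
#' @param n_injections number of injections.
#' @param n_cells_per_injection labeled cells per injection.
#' @param injection_radius radius of the injected tracer deposit, mm.
#' @param seed integer seed; all phantom outputs are pure functions of the
#'   configuration (one RNG stream per generation stage, at fixed offsets
#'   from this seed).
#' @return list of class `tm_phantom_config`.
#' @export
phantom_config <- function(grid_size = 64L, spacing = 0.12,
                           r_inner = 1.9, r_outer = 2.8,
                           n_areas = 6L, n_landmarks = 3L,
                           section_spacing = 0.24,
                           jitter_trans_sd = 0.25, jitter_rot_sd = 0.03,
                           deform_amplitude = 0.12, deform_smoothness = 1.0,
                           affine_scale_range = c(0.95, 1.05),
                           affine_shear_max = 0.03, affine_rot_max = 0.05,
                           affine_trans_max = 0.3,
                           n_injections = 3L, n_cells_per_injection = 300L,
                           injection_radius = 0.25, seed = 1L) {
  if (!(r_outer > r_inner && r_inner > 0))
    stop("ConfigError: need r_outer > r_inner > 0")
  extent <- grid_size * spacing
  if (2 * r_outer > 0.95 * extent)
    stop("ConfigError: shell does not fit inside the grid")
  cfg <- list(grid_size = as.integer(grid_size), spacing = spacing,
              r_inner = r_inner, r_outer = r_outer,
              n_areas = as.integer(n_areas), n_landmarks = as.integer(n_landmarks),
              wm_label = as.integer(n_areas) + 1L,
              section_spacing = section_spacing,
              jitter_trans_sd = jitter_trans_sd, jitter_rot_sd = jitter_rot_sd,
              deform_amplitude = deform_amplitude,
              deform_smoothness = deform_smoothness,
              affine_scale_range = affine_scale_range,
              affine_shear_max = affine_shear_max,
              affine_rot_max = affine_rot_max, affine_trans_max = affine_trans_max,
              n_injections = as.integer(n_injections),
              n_cells_per_injection = as.integer(n_cells_per_injection),
              injection_radius = injection_radius, seed = as.integer(seed))
  # hemisphere center: laterally centered, low enough in DV for the dome to
  # fit; offset by a quarter voxel in ML and DV so no voxel center lies
  # exactly on the axis planes (which would park whole voxel planes on
  # azimuthal sector boundaries)
  cfg$center <- c(extent / 2 + spacing / 4, extent / 2,
                  max(0.05 * extent, extent / 2 - r_outer * 0.95) + spacing / 4)
  class(cfg) <- "tm_phantom_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

phantom_coords <- function(cfg) {
  n <- cfg$grid_size
  ax <- (seq_len(n) - 1) * cfg$spacing
  list(x = ax, n = n)
}

# Analytic shell parameterization: a point is (azimuth az in [0, pi] around
# the AP axis, latitude beta toward +/-AP, radius r). Areas are equal
# azimuthal sectors.
shell_point <- function(cfg, az, beta, r) {
  cbind(cfg$center[1] + r * cos(beta) * cos(az),
        cfg$center[2] + r * sin(beta),
        cfg$center[3] + r * cos(beta) * sin(az))
}

shell_area_of_az <- function(cfg, az) {
  pmin(cfg$n_areas, pmax(1L, 1L + floor(az / (pi / cfg$n_areas))))
}

#' Generate the phantom template
#'
#' Produces a Nissl-like intensity volume (area-dependent mean, a smooth
#' radial profile, and seeded smooth noise so registration metrics have
#' gradients to exploit), a co-registered label volume (background 0, areas
#' `1..n_areas`, white matter `n_areas + 1`), and a landmark label volume of
#' `n_landmarks` shell sectors.
#'
#' @param cfg a [phantom_config()].
#' @return list with `tm_volume` elements `intensity`, `labels`, `landmarks`.
#' @export
make_template <- function(cfg) {
  n <- cfg$grid_size
  ax <- (seq_len(n) - 1) * cfg$spacing
  dx <- rep(ax - cfg$center[1], times = n * n)
  dy <- rep(rep(ax - cfg$center[2], each = n), times = n)
  dz <- rep(ax - cfg$center[3], each = n * n)
  rho <- sqrt(dx^2 + dz^2)
  r <- sqrt(rho^2 + dy^2)
  upper <- dz >= 0
  az <- atan2(pmax(dz, 0), dx)            # [0, pi] on the upper half
  area <- shell_area_of_az(cfg, az)

  lab <- integer(n^3)
  cortex <- upper & r >= cfg$r_inner & r <= cfg$r_outer
  wm <- upper & r < cfg$r_inner
  lab[cortex] <- area[cortex]
  lab[wm] <- cfg$wm_label

  # intensity: per-area mean + radial profile + seeded smooth noise
  area_means <- 70 + 18 * ((seq_len(cfg$n_areas) * 3L) %% cfg$n_areas)
  inten <- numeric(n^3)
  depth_frac <- (cfg$r_outer - r) / (cfg$r_outer - cfg$r_inner)
  inten[cortex] <- area_means[lab[cortex]] +
    25 * cos(pi * pmin(pmax(depth_frac[cortex], 0), 1))
  inten[wm] <- 40
  noise <- with_seed(cfg$seed + 1L, stats::rnorm(n^3))
  noise <- cpp_gauss3(noise, c(n, n, n), rep(1.2, 3))
  noise <- noise / stats::sd(noise) * 8
  inten[lab > 0] <- inten[lab > 0] + noise[lab > 0]
  inten <- cpp_gauss3(inten, c(n, n, n), rep(0.6, 3))

  beta <- asin(pmin(pmax(ifelse(r > 0, dy / r, 0), -1), 1))
  lm <- integer(n^3)
  # landmark sectors: shell patches at fixed azimuth windows, central latitudes
  lm_w <- pi / (2 * cfg$n_landmarks)
  for (l in seq_len(cfg$n_landmarks)) {
    a0 <- (l - 0.6) * pi / cfg$n_landmarks
    sel <- cortex & az >= a0 & az < a0 + lm_w & abs(beta) < 0.9
    lm[sel] <- l
  }

  spacing <- rep(cfg$spacing, 3)
  list(intensity = tm_volume(array(inten, dim = c(n, n, n)), spacing, c(0, 0, 0)),
       labels = tm_volume(array(as.double(lab), dim = c(n, n, n)), spacing,
                          c(0, 0, 0), kind = "label"),
       landmarks = tm_volume(array(as.double(lm), dim = c(n, n, n)), spacing,
                             c(0, 0, 0), kind = "label"))
}

draw_affine_distortion <- function(cfg) {
  # forward map: aligned stack space -> template space (the chain's
  # reconstruction affine); drawn small and invertible
  sc <- stats::runif(3, cfg$affine_scale_range[1], cfg$affine_scale_range[2])
  sh <- stats::runif(3, -cfg$affine_shear_max, cfg$affine_shear_max)
  th <- stats::runif(3, -cfg$affine_rot_max, cfg$affine_rot_max)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  S <- diag(sc)
  S[1, 2] <- sh[1]; S[1, 3] <- sh[2]; S[2, 3] <- sh[3]
  A <- Rx %*% Ry %*% Rz %*% S
  tr <- stats::runif(3, -cfg$affine_trans_max, cfg$affine_trans_max)
  ctr <- cfg$center
  affine3d(A, as.vector(ctr - A %*% ctr) + tr)
}

draw_section_field <- function(cfg, d2, spacing2, origin2, amplitude) {
  if (amplitude <= 0) return(NULL)
  sig_vox <- cfg$deform_smoothness / spacing2
  for (attempt in 1:10) {
    comps <- lapply(1:2, function(a) {
      w <- stats::rnorm(prod(d2))
      w <- cpp_gauss2(w, d2, rep(sig_vox, 2))
      array(w, dim = d2)
    })
    rms <- sqrt(mean(comps[[1]]^2 + comps[[2]]^2))
    comps <- lapply(comps, function(m) m / rms * amplitude)
    # invertibility: displacement gradient magnitude < 0.5
    g <- max(vapply(comps, function(m) {
      gx <- abs(diff(m)) / spacing2
      gy <- abs(t(diff(t(m)))) / spacing2
      max(gx, gy)
    }, numeric(1)))
    if (g < 0.5) return(displacement_field(comps, rep(spacing2, 2), origin2))
    message("redrawing section deformation (gradient ", signif(g, 3), " >= 0.5)")
  }
  stop("could not draw an invertible section deformation")
}

#' Cut and distort the template into a section stack
#'
#' Reslices the template coronally at the configured section spacing, then
#' perturbs it with the drawn global affine, per-section rigid jitter and
#' smooth per-section deformations. The returned ground-truth chain is the
#' *forward* map from distorted-section coordinates into template space, so
#' applying it to any distorted-stack point recovers the original template
#' coordinates (self-consistency of the generator).
#'
#' @param template output of [make_template()].
#' @param cfg a [phantom_config()].
#' @return list with `stack` (`tm_stack`), `mask_stack` (`tm_stack` of
#'   brain-mask sections), and `chain` (ground-truth `tm_chain`).
#' @export
slice_and_distort <- function(template, cfg) {
  n <- cfg$grid_size
  extent <- n * cfg$spacing
  n_sections <- as.integer(ceiling(extent / cfg$section_spacing))
  sp2 <- cfg$spacing
  d2 <- c(n, n)
  origin2 <- c(0, 0)
  y0 <- cfg$section_spacing / 2
  ys <- y0 + (seq_len(n_sections) - 1) * cfg$section_spacing

  out <- with_seed(cfg$seed + 2L, {
    G <- if (cfg$affine_scale_range[1] == 1 && cfg$affine_scale_range[2] == 1 &&
             cfg$affine_shear_max == 0 && cfg$affine_rot_max == 0 &&
             cfg$affine_trans_max == 0) affine3d() else draw_affine_distortion(cfg)
    per_section <- vector("list", n_sections)
    secs <- vector("list", n_sections)
    msecs <- vector("list", n_sections)
    grid2 <- as.matrix(expand.grid(x = (seq_len(n) - 1) * sp2,
                                   y = (seq_len(n) - 1) * sp2))
    ctr2 <- c((n - 1) * sp2 / 2, (n - 1) * sp2 / 2)
    for (s in seq_len(n_sections)) {
      th <- stats::rnorm(1, 0, cfg$jitter_rot_sd)
      tv <- stats::rnorm(2, 0, cfg$jitter_trans_sd)
      rg <- rigid2d(th, tv[1], tv[2], ctr2[1], ctr2[2])
      fld <- draw_section_field(cfg, d2, sp2, origin2, cfg$deform_amplitude)
      per_section[[s]] <- list(rigid = rg, field = fld)
      q <- apply_rigid2d(rg, grid2)
      if (!is.null(fld)) q <- q + field_displacement(fld, q)
      P <- cbind(q[, 1], ys[s], q[, 2])
      X <- apply_affine3d(G, P)
      secs[[s]] <- matrix(sample_volume(template$intensity, X, "linear", 0), n, n)
      msecs[[s]] <- matrix(as.double(sample_volume(template$labels, X, "nearest", 0) > 0), n, n)
    }
    list(G = G, per_section = per_section, secs = secs, msecs = msecs)
  })

  chain <- transform_chain(out$per_section, ys, reconstruction_affine = out$G)
  list(stack = tm_stack(out$secs, sp2, cfg$section_spacing, origin2, y0),
       mask_stack = tm_stack(out$msecs, sp2, cfg$section_spacing, origin2, y0),
       chain = chain)
}

invert_point_field <- function(f, pts, iters = 40L) {
  v <- -field_displacement(f, pts)
  for (i in seq_len(iters)) v <- -field_displacement(f, pts + v)
  pts + v
}

# Inverse of the ground-truth chain: template point -> (section, x, y)
chain_inverse_points <- function(chain, pts, section_spacing_positions) {
  P <- apply_affine3d(invert_affine3d(chain$reconstruction_affine), rbind_pts(pts))
  pos <- chain$section_positions
  s <- vapply(P[, 2], function(y) which.min(abs(pos - y)), integer(1))
  out <- matrix(NA_real_, nrow(P), 2)
  for (si in unique(s)) {
    rows <- which(s == si)
    q <- cbind(P[rows, 1], P[rows, 3])
    st <- chain$per_section[[si]]
    if (!is.null(st$field)) q <- invert_point_field(st$field, q)
    out[rows, ] <- apply_rigid2d(invert_rigid2d(st$rigid), q)
  }
  list(section = s, xy = out)
}

#' Plant injections and labeled cells in the phantom
#'
#' Each injection is a tracer deposit at mid-depth of a chosen area (its
#' voxel neighborhood becomes `injection_voxel` points); its labeled cells
#' are drawn in the other areas with per-area counts from a multinomial
#' (weights decaying with angular distance from the injected area), uniform
#' azimuth within the area, latitude uniform in (-1.2, 1.2) rad, and
#' normalized depth uniform in [0.2, 0.8]. True template coordinates, areas,
#' depths and analytic flat-map (azimuth, latitude) coordinates are recorded;
#' plotted coordinates are expressed in distorted-section space through the
#' inverse of the ground-truth chain (cells are plotted on the nearest
#' section, as in real sectioning, so sub-section AP position is quantized).
#'
#' @param template output of [make_template()].
#' @param cfg a [phantom_config()].
#' @param chain ground-truth `tm_chain` from [slice_and_distort()].
#' @param areas optional integer vector of injected areas (default: evenly
#'   spread across the parcellation, deterministically).
#' @return data frame of point annotations with ground-truth columns
#'   (`true_ml/true_ap/true_dv`, `true_area`, `true_depth`, `flat_u/flat_v`).
#' @export
plant_cells <- function(template, cfg, chain, areas = NULL) {
  K <- cfg$n_areas
  if (is.null(areas))
    areas <- (round(seq(1, K, length.out = cfg$n_injections + 1L))[seq_len(cfg$n_injections)])
  if (any(areas < 1 | areas > K)) stop("injected area outside parcellation")
  tracers <- rep(c("FB", "DY", "FR", "FE"), length.out = cfg$n_injections)
  sec_w <- pi / K
  r_mid <- (cfg$r_inner + cfg$r_outer) / 2
  rows <- with_seed(cfg$seed + 3L, {
    all <- list()
    for (inj in seq_along(areas)) {
      a <- areas[inj]
      animal <- sprintf("PH%02d", inj)
      az_c <- (a - 0.5) * sec_w
      beta_c <- stats::runif(1, -0.5, 0.5)
      center <- shell_point(cfg, az_c, beta_c, r_mid)
      # injection voxel cloud: template voxels of area a near the center
      lab <- template$labels
      vox <- which(lab$data == a)
      dimv <- dim(lab$data)
      ijk <- cbind((vox - 1) %% dimv[1],
                   ((vox - 1) %/% dimv[1]) %% dimv[2],
                   (vox - 1) %/% (dimv[1] * dimv[2]))
      ctrs <- voxel_to_world(lab, ijk)
      near <- which(sqrt(colSums((t(ctrs) - as.vector(center))^2)) <= cfg$injection_radius)
      inj_pts <- ctrs[near, , drop = FALSE]
      # cells in the other areas: multinomial counts with decaying weights
      others <- setdiff(seq_len(K), a)
      dist_k <- pmin(abs(others - a), K - abs(others - a))
      w <- exp(-0.6 * dist_k)
      counts <- as.vector(stats::rmultinom(1, cfg$n_cells_per_injection, w / sum(w)))
      cell_area <- rep(others, counts)
      m <- length(cell_area)
      az <- (cell_area - 1) * sec_w + stats::runif(m, 0, sec_w)
      beta <- stats::runif(m, -1.2, 1.2)
      nd <- stats::runif(m, 0.2, 0.8)
      r <- cfg$r_outer - nd * (cfg$r_outer - cfg$r_inner)
      cell_pts <- shell_point(cfg, az, beta, r)
      pts <- rbind(inj_pts, cell_pts)
      kind <- c(rep("injection_voxel", nrow(inj_pts)), rep("cell", m))
      true_area <- c(rep(a, nrow(inj_pts)), cell_area)
      true_nd <- c(rep(NA_real_, nrow(inj_pts)), nd)
      fu <- c(rep(NA_real_, nrow(inj_pts)), az)
      fv <- c(rep(NA_real_, nrow(inj_pts)), beta)
      all[[inj]] <- data.frame(animal = animal, tracer = tracers[inj],
                               kind = kind, true_ml = pts[, 1], true_ap = pts[, 2],
                               true_dv = pts[, 3], true_area = true_area,
                               true_depth = true_nd, flat_u = fu, flat_v = fv,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, all)
  })
  inv <- chain_inverse_points(chain, as.matrix(rows[, c("true_ml", "true_ap", "true_dv")]))
  rows$section <- inv$section
  rows$x_mm <- inv$xy[, 1]
  rows$y_mm <- inv$xy[, 2]
  rows[, c("animal", "tracer", "kind", "section", "x_mm", "y_mm",
           "true_ml", "true_ap", "true_dv", "true_area", "true_depth",
           "flat_u", "flat_v")]
}

#' Generate the full phantom study
#'
#' Convenience orchestrator: template, distorted stack, ground-truth chain,
#' subject-side landmark volume (the template landmarks carried into stack
#' space through the ground-truth global affine, the phantom's analogue of
#' hand-drawn landmark sectors), and planted cells.
#'
#' @param cfg a [phantom_config()].
#' @return list with `template` (intensity/labels/landmarks), `stack`,
#'   `mask_stack`, `chain_gt`, `landmarks_subject`, `cells`.
#' @export
make_phantom <- function(cfg = phantom_config()) {
  tpl <- make_template(cfg)
  sl <- slice_and_distort(tpl, cfg)
  stack_geom <- vol_geometry(stack_to_volume(sl$stack))
  lm_subj <- resample(tpl$landmarks, tm_geom_as_vol(stack_geom),
                      t = invert_affine3d(sl$chain$reconstruction_affine),
                      interp = "nearest")
  cells <- plant_cells(tpl, cfg, sl$chain)
  list(template = tpl, stack = sl$stack, mask_stack = sl$mask_stack,
       chain_gt = sl$chain, landmarks_subject = lm_subj, cells = cells,
       config = cfg)
}
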