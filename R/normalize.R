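# Stage 3: preprocessing and landmark-guided 3D affine + deformable
# coregistration of the reconstructed volume with the template.

#' Normalization configuration
#'
#' @param resolution working isotropic resolution in mm (default 0.075).
#' @param median_radius median filter radius in voxels.
#' @param cc_kernel_radius local cross-correlation window radius, voxels.
#' @param weights named weights for the deformable objective (`cc`
#'   intensity term, `pse` landmark term); equal by default.
#' @param deformable_iterations demons iterations per resolution level
#'   (coarse to fine).
#' @param levels multi-resolution levels for the deformable stage.
#' @param field_sigma Gaussian field regularization, voxels.
#' @param mi_bins MI histogram bins for the affine stage.
#' @param max_eval optimizer budget per affine level.
#' @param use_landmarks enable the landmark (PSE) force.
#' @export
normalization_config <- function(resolution = 0.075, median_radius = 1L,
                                 cc_kernel_radius = 5L,
                                 weights = c(cc = 1, pse = 1),
                                 deformable_iterations = c(60L, 40L, 20L),
                                 levels = 3L, field_sigma = 2,
                                 mi_bins = 32L, max_eval = 500L,
                                 use_landmarks = TRUE) {
  stopifnot(resolution > 0, median_radius >= 1, cc_kernel_radius >= 1)
  list(resolution = resolution, median_radius = as.integer(median_radius),
       cc_kernel_radius = as.integer(cc_kernel_radius), weights = weights,
       deformable_iterations = as.integer(rep_len(deformable_iterations, levels)),
       levels = as.integer(levels), field_sigma = field_sigma,
       mi_bins = as.integer(mi_bins), max_eval = as.integer(max_eval),
       use_landmarks = isTRUE(use_landmarks))
}

#' Preprocess a volume for registration
#'
#' Resamples to the working isotropic resolution and applies one pass of a
#' median filter with the stated radius. Label volumes are resampled with
#' nearest-neighbour interpolation and not filtered.
#'
#' @param vol a `tm_volume`.
#' @param cfg a [normalization_config()].
#' @return `tm_volume` with isotropic spacing `cfg$resolution`.
#' @export
preprocess_for_registration <- function(vol, cfg = normalization_config()) {
  res <- cfg$resolution
  d <- dim(vol$data)
  extent <- d * vol$spacing
  nd <- pmax(2L, as.integer(ceiling(extent / res)))
  geom <- list(dim = nd, spacing = rep(res, 3), origin = vol$origin)
  out <- resample(vol, tm_geom_as_vol(geom), t = NULL,
                  interp = if (vol$kind == "label") "nearest" else "linear")
  if (vol$kind == "intensity")
    out$data <- array(cpp_median3(as.double(out$data), nd, cfg$median_radius),
                      dim = nd)
  out
}

#' 12-parameter 3D affine registration by mutual information
#'
#' Multi-resolution Nelder-Mead search over the full affine group
#' (parameterized about the fixed image center). Returns the forward point
#' map from moving space into fixed space; on optimizer failure the identity
#' is returned with a `failure` attribute.
#'
#' @param moving,fixed `tm_volume`s (typically preprocessed).
#' @param cfg a [normalization_config()].
#' @param init optional initial forward `tm_affine3d`.
#' @return `tm_affine3d` (moving -> fixed) with attribute `mi`.
#' @export
register_affine_3d <- function(moving, fixed, cfg = normalization_config(),
                               init = NULL) {
  gf <- vol_geometry(fixed)
  ctr <- gf$origin + (gf$dim - 1) * gf$spacing / 2
  # optimize the pull map (fixed -> moving); forward is its inverse
  init_pull <- if (is.null(init)) affine3d() else invert_affine3d(init)
  mk_pts <- function(stride) {
    g <- as.matrix(expand.grid(
      x = gf$origin[1] + (seq(1, gf$dim[1], by = stride) - 1) * gf$spacing[1],
      y = gf$origin[2] + (seq(1, gf$dim[2], by = stride) - 1) * gf$spacing[2],
      z = gf$origin[3] + (seq(1, gf$dim[3], by = stride) - 1) * gf$spacing[3]))
    storage.mode(g) <- "double"
    list(pts = g, fixed = sample_volume(fixed, g, "linear", 0))
  }
  # cap MI sample counts: ~50k voxels at the finest level is ample
  base_stride <- max(1L, as.integer(ceiling((prod(gf$dim) / 5e4)^(1 / 3))))
  strides <- rev(base_stride * 2^(seq_len(max(1L, cfg$levels)) - 1))
  strides <- pmin(strides, pmax(1L, min(gf$dim) %/% 8))
  levels_pts <- lapply(unique(strides), mk_pts)
  par <- tryCatch({
    optim_affine_mi(function(src) sample_volume(moving, src, "linear", 0),
                    par_from_affine(init_pull, ctr), ctr, cfg$max_eval,
                    levels_pts, cfg$mi_bins)
  }, error = function(e) NULL)
  if (is.null(par)) {
    out <- affine3d()
    attr(out, "failure") <- TRUE
    return(out)
  }
  pull <- affine_from_par(par, ctr)
  out <- invert_affine3d(pull)
  lp <- levels_pts[[length(levels_pts)]]
  vals <- sample_volume(moving, apply_affine3d(pull, lp$pts), "linear", 0)
  attr(out, "mi") <- tryCatch(suppressWarnings(
    mutual_information(lp$fixed, vals, cfg$mi_bins)), error = function(e) NA_real_)
  out
}

max_field_gradient3 <- function(m, spacing) {
  d <- dim(m)
  max(max(abs(m[2:d[1], , ] - m[1:(d[1] - 1), , ])) / spacing[1],
      max(abs(m[, 2:d[2], ] - m[, 1:(d[2] - 1), ])) / spacing[2],
      max(abs(m[, , 2:d[3]] - m[, , 1:(d[3] - 1)])) / spacing[3])
}

gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- list(array(0, d), array(0, d), array(0, d))
  g[[1]][2:(d[1] - 1), , ] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) / (2 * spacing[1])
  g[[2]][, 2:(d[2] - 1), ] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) / (2 * spacing[2])
  g[[3]][, , 2:(d[3] - 1)] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) / (2 * spacing[3])
  g
}

downsample_vol <- function(vol, factor, nearest = FALSE) {
  if (factor == 1) return(vol)
  d <- dim(vol$data)
  nd <- pmax(2L, as.integer(ceiling(d / factor)))
  geom <- list(dim = nd, spacing = vol$spacing * d / nd, origin = vol$origin)
  v <- vol
  if (!nearest && vol$kind == "intensity") {
    v$data <- array(cpp_gauss3(as.double(vol$data), d, rep(factor / 2, 3)), d)
  }
  resample(v, tm_geom_as_vol(geom), t = NULL,
           interp = if (vol$kind == "label") "nearest" else "linear")
}

# Additive demons update of a 3D pull field toward `fixed`, with optional
# landmark attraction. u is a list of 3 arrays on the fixed grid (mm).
demons_step3 <- function(moving, fixed, u, geom, sigma, lm_force = NULL,
                         weights = c(cc = 1, pse = 1), pts = NULL) {
  d <- geom$dim
  if (is.null(pts)) pts <- voxel_centers(tm_geom_as_vol(geom))
  src <- pts + cbind(as.vector(u[[1]]), as.vector(u[[2]]), as.vector(u[[3]]))
  w <- array(sample_volume(moving, src, "linear", 0), d)
  diffv <- fixed$data - w
  g <- gradient3(w, geom$spacing)
  denom <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2 + (diffv / min(geom$spacing))^2
  denom[denom < 1e-12] <- Inf
  wsum <- sum(weights[c("cc", "pse")])
  du <- lapply(1:3, function(a) diffv * g[[a]] / denom * (weights[["cc"]] / wsum * 2))
  if (!is.null(lm_force)) {
    cap <- min(geom$spacing)
    for (a in 1:3) {
      f <- pmin(cap, pmax(-cap, lm_force[[a]])) * (weights[["pse"]] / wsum * 2)
      du[[a]] <- du[[a]] + f
    }
  }
  lapply(1:3, function(a)
    array(cpp_gauss3(as.double(u[[a]] + du[[a]]), d, rep(sigma, 3)), d))
}

# Landmark attraction force on the pull field: at each fixed-landmark voxel,
# the residual vector from its current pulled position to the nearest
# same-label moving landmark point.
landmark_force <- function(u, geom, lm_fixed_pts, lm_moving_pts) {
  d <- geom$dim
  f <- list(array(0, d), array(0, d), array(0, d))
  cnt <- array(0, d)
  for (l in names(lm_fixed_pts)) {
    if (is.null(lm_moving_pts[[l]])) next
    x <- lm_fixed_pts[[l]]
    disp <- matrix(0, nrow(x), 3)
    for (a in 1:3)
      disp[, a] <- cpp_sample3(as.double(u[[a]]), d, geom$spacing, geom$origin,
                               x, TRUE, 0)
    p <- x + disp
    M <- lm_moving_pts[[l]]
    # residual toward the nearest moving point (nn index via labeled query)
    idx <- cpp_nn_label(p, M, seq_len(nrow(M)))$label
    resid <- M[idx, , drop = FALSE] - p
    vox <- round(sweep(sweep(x, 2, geom$origin, "-"), 2, geom$spacing, "/"))
    vox <- pmin(pmax(vox, 0), matrix(rep(d - 1, each = nrow(vox)), ncol = 3))
    lin <- 1 + vox[, 1] + d[1] * (vox[, 2] + d[2] * vox[, 3])
    for (a in 1:3) {
      acc <- tapply(resid[, a], lin, mean)
      f[[a]][as.integer(names(acc))] <- f[[a]][as.integer(names(acc))] + acc
    }
  }
  f
}

#' Deformable 3D registration with optional landmark constraints
#'
#' Multi-resolution additive-demons registration of `moving` (already
#' affinely aligned onto the fixed grid) to `fixed`, with Gaussian field
#' regularization. With landmarks enabled, a point-set attraction force pulls
#' each fixed landmark sector toward the corresponding moving sector
#' (weighted per `cfg$weights`), the practical counterpart of combining a
#' local correlation metric with a point-set expectation metric. The
#' returned field is the *pull* (resampling) map on the fixed grid; invert
#' with [invert_field()] to obtain the forward point map.
#'
#' @param moving,fixed intensity `tm_volume`s on the same geometry.
#' @param landmarks_m,landmarks_f optional landmark label `tm_volume`s
#'   (moving side already affine-resampled onto the fixed grid).
#' @param cfg a [normalization_config()].
#' @return `tm_field` (pull map) with attributes `cc` (final windowed CC)
#'   and `pse` (final landmark PSE, if landmarks were given).
#' @export
register_deformable_3d <- function(moving, fixed, landmarks_m = NULL,
                                   landmarks_f = NULL,
                                   cfg = normalization_config()) {
  use_lm <- cfg$use_landmarks && !is.null(landmarks_m) && !is.null(landmarks_f)
  if (use_lm) {
    pm <- labels_to_points(landmarks_m, 1000L)
    pf <- labels_to_points(landmarks_f, 1000L)
    if (!identical(sort(names(pm)), sort(names(pf))))
      stop("LandmarkMismatch: landmark label inventories differ")
  }
  factors <- 2^(seq(cfg$levels - 1, 0))
  u <- NULL
  geom <- NULL
  for (li in seq_along(factors)) {
    f <- factors[li]
    mv <- downsample_vol(moving, f)
    fx <- downsample_vol(fixed, f)
    geom_new <- vol_geometry(fx)
    if (is.null(u)) {
      u <- lapply(1:3, function(a) array(0, geom_new$dim))
    } else {
      pts <- voxel_centers(tm_geom_as_vol(geom_new))
      u <- lapply(1:3, function(a)
        array(cpp_sample3(as.double(u[[a]]), geom$dim, geom$spacing, geom$origin,
                          pts, TRUE, 0), geom_new$dim))
    }
    geom <- geom_new
    sigma <- cfg$field_sigma
    lm_f_pts <- if (use_lm) labels_to_points(downsample_vol(landmarks_f, f, TRUE), 600L)
    lm_m_pts <- if (use_lm) labels_to_points(downsample_vol(landmarks_m, f, TRUE), 600L)
    grid_pts <- voxel_centers(tm_geom_as_vol(geom))
    for (it in seq_len(cfg$deformable_iterations[li])) {
      lf <- if (use_lm) landmark_force(u, geom, lm_f_pts, lm_m_pts)
      u_new <- demons_step3(mv, fx, u, geom, sigma, lf, cfg$weights, pts = grid_pts)
      gmax <- max(vapply(u_new, max_field_gradient3, numeric(1),
                         spacing = geom$spacing))
      if (gmax >= 1) {
        sigma <- sigma * 1.5
        message("deformable field gradient ", signif(gmax, 3),
                " >= 1; regularization increased to sigma = ", sigma)
        next
      }
      u <- u_new
    }
  }
  field <- displacement_field(u, geom$spacing, geom$origin)
  pts <- voxel_centers(tm_geom_as_vol(geom))
  src <- pts + cbind(as.vector(u[[1]]), as.vector(u[[2]]), as.vector(u[[3]]))
  warped <- array(sample_volume(moving, src, "linear", 0), geom$dim)
  attr(field, "cc") <- windowed_cross_correlation(warped, fixed$data,
                                                  cfg$cc_kernel_radius)
  if (use_lm) {
    lm_warp <- resample(landmarks_m, fixed, t = pull_map(field), interp = "nearest")
    attr(field, "pse") <- tryCatch(
      point_set_expectation(labels_to_points(lm_warp, 1000L), pf),
      error = function(e) NA_real_)
  }
  field
}

#' Coregister a reconstructed volume with the template
#'
#' Runs the full normalization stage: preprocessing of both volumes to the
#' working resolution, 3D affine registration by MI, and deformable
#' registration driven by local correlation plus (optionally) landmark
#' sectors. Returns forward transforms suitable for the transform chain.
#'
#' @param recon reconstructed intensity `tm_volume` (stack space).
#' @param template template intensity `tm_volume`.
#' @param landmarks_subject,landmarks_template optional landmark label
#'   `tm_volume`s in subject (stack) and template space.
#' @param cfg a [normalization_config()].
#' @param init_affine optional initial forward affine (stack -> template).
#' @return list with `affine` (forward `tm_affine3d`), `field` (forward
#'   `tm_field`), `pull_field`, and diagnostics `pse_affine`, `pse_final`,
#'   `cc_final`.
#' @export
normalize_to_template <- function(recon, template, landmarks_subject = NULL,
                                  landmarks_template = NULL,
                                  cfg = normalization_config(),
                                  init_affine = NULL) {
  pre_m <- preprocess_for_registration(recon, cfg)
  pre_f <- preprocess_for_registration(template, cfg)
  aff <- register_affine_3d(pre_m, pre_f, cfg, init = init_affine)
  mov_aff <- resample(pre_m, pre_f, t = aff, interp = "linear")
  have_lm <- !is.null(landmarks_subject) && !is.null(landmarks_template)
  lm_m <- lm_f <- NULL
  pse_affine <- NA_real_
  pm <- pf_pts <- NULL
  if (have_lm) {
    lm_m <- resample(landmarks_subject, pre_f, t = aff, interp = "nearest")
    lm_f <- resample(landmarks_template, pre_f, t = NULL, interp = "nearest")
    pm <- labels_to_points(landmarks_subject, 1000L)
    pf_pts <- labels_to_points(lm_f, 1000L)
    pse_affine <- point_set_expectation(
      lapply(pm, function(x) apply_affine3d(aff, x)), pf_pts)
  }
  pull <- register_deformable_3d(mov_aff, pre_f,
                                 landmarks_m = if (cfg$use_landmarks) lm_m,
                                 landmarks_f = if (cfg$use_landmarks) lm_f,
                                 cfg = cfg)
  fwd <- invert_field(pull)
  # landmark PSE after the full forward map (affine + field)
  pse_of <- function(f) point_set_expectation(
    lapply(pm, function(x) apply_field(f, apply_affine3d(aff, x))), pf_pts)
  pse_final <- NA_real_
  if (have_lm) {
    pse_final <- pse_of(fwd)
    if (cfg$use_landmarks && pse_final > pse_affine) {
      # trust-region safeguard: a deformable update is not allowed to worsen
      # the landmark alignment; scale the field back until it does not
      # (a zero field reproduces the affine-only alignment exactly)
      s <- 1
      while (pse_final > pse_affine && s > 1e-3) {
        s <- s / 2
        cand <- displacement_field(lapply(fwd$components, function(m) m * s),
                                   fwd$spacing, fwd$origin)
        pse_cand <- pse_of(cand)
        if (pse_cand <= pse_affine || s <= 1e-3) {
          if (pse_cand > pse_affine) {
            cand <- zero_field(dim(fwd$components[[1]]), fwd$spacing, fwd$origin)
            pse_cand <- pse_affine
          }
          message("deformable stage scaled back (factor ", signif(s, 3),
                  ") to preserve landmark alignment")
          fwd <- cand
          pse_final <- pse_cand
        }
      }
    }
  }
  list(affine = aff, field = fwd, pull_field = pull,
       pse_affine = pse_affine, pse_final = pse_final,
       cc_final = attr(pull, "cc"))
}
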