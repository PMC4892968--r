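# Stage 1-2 of the reconstruction: iterative affine reconstruction of the
# section stack against the reference volume, then section-wise deformable
# refinement toward neighbor averages.

#' Reconstruction configuration
#'
#' @param n_outer_iterations iterations of the alternating (3D affine /
#'   per-section 2D rigid) loop; the field-standard range is 8-12.
#' @param n_deformable_iterations neighbor-average deformable iterations.
#' @param neighbor_radius sections averaged on either side for the
#'   deformable target (1 = immediate neighbors).
#' @param tol convergence tolerance on the mean per-section MI improvement.
#' @param mi_bins histogram bins for the MI metric.
#' @param levels multi-resolution levels for rigid/affine optimization.
#' @param max_eval optimizer evaluation budget per level.
#' @param field_sigma Gaussian regularization of deformable fields, voxels.
#' @param demons_steps demons sub-steps per section per deformable iteration
#'   (each section-to-target warp is a short registration, not a single
#'   gradient step).
#' @export
reconstruction_config <- function(n_outer_iterations = 10L,
                                  n_deformable_iterations = 8L,
                                  neighbor_radius = 1L, tol = 1e-3,
                                  mi_bins = 32L, levels = 2L, max_eval = 400L,
                                  field_sigma = 2, demons_steps = 3L) {
  stopifnot(n_outer_iterations >= 1, n_outer_iterations <= 50, neighbor_radius >= 1)
  list(n_outer_iterations = as.integer(n_outer_iterations),
       n_deformable_iterations = as.integer(n_deformable_iterations),
       neighbor_radius = as.integer(neighbor_radius), tol = tol,
       mi_bins = as.integer(mi_bins), levels = as.integer(levels),
       max_eval = as.integer(max_eval), field_sigma = field_sigma,
       demons_steps = as.integer(demons_steps))
}

# keep joint histograms adequately populated on small images: about 8+
# samples per occupied row/column of the joint histogram
adaptive_bins <- function(n, cap) max(8L, min(cap, as.integer(floor(sqrt(n / 8)))))

# Deterministic compass (pattern) search: robust local refinement on the
# jagged fine-scale structure of sampled-MI objectives, where simplex methods
# tend to stall. Maximizes f.
compass_search <- function(f, par, scales, step0 = 0.5, step_min = 0.02,
                           max_eval = 500L) {
  best <- f(par)
  step <- step0
  evals <- 0L
  while (step >= step_min && evals < max_eval) {
    improved <- FALSE
    for (i in seq_along(par)) {
      for (sgn in c(1, -1)) {
        cand <- par
        cand[i] <- cand[i] + sgn * step * scales[i]
        v <- f(cand)
        evals <- evals + 1L
        if (v > best + 1e-12) {
          best <- v
          par <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  list(par = par, value = best)
}

sample_image2 <- function(img, spacing, origin, pts, linear = TRUE, bg = 0) {
  cpp_sample2(as.double(img), dim(img), rep(spacing, 2), origin, rbind_pts(pts),
              linear, bg)
}

downsample2 <- function(img, spacing, origin) {
  sm <- array(cpp_gauss2(as.double(img), dim(img), c(1, 1)), dim = dim(img))
  ii <- seq(1, nrow(img), by = 2); jj <- seq(1, ncol(img), by = 2)
  list(img = sm[ii, jj, drop = FALSE], spacing = spacing * 2, origin = origin)
}

grid2 <- function(d, spacing, origin) {
  g <- as.matrix(expand.grid(x = origin[1] + (seq_len(d[1]) - 1) * spacing,
                             y = origin[2] + (seq_len(d[2]) - 1) * spacing))
  storage.mode(g) <- "double"
  g
}

#' Register one 2D image to another with a rigid transform
#'
#' Finds the rigid transform (rotation + translation about the image center)
#' maximizing the mutual information between `fixed` and the resampled
#' `moving`, by Nelder-Mead search over a multi-resolution pyramid. The
#' returned transform is the forward map from moving space into fixed space,
#' and is never worse (in MI at full resolution) than the initialization; if
#' the optimizer fails to improve, the initialization is returned with a
#' `warning` attribute.
#'
#' @param moving,fixed 2D numeric matrices on the same grid geometry.
#' @param spacing mm per pixel.
#' @param origin length-2 mm origin of pixel (0, 0).
#' @param init initial `tm_rigid2d`.
#' @param cfg a [reconstruction_config()].
#' @return `tm_rigid2d` with attribute `mi` (achieved MI).
#' @export
register_rigid_2d <- function(moving, fixed, spacing, origin = c(0, 0),
                              init = NULL, cfg = reconstruction_config()) {
  d <- dim(moving)
  ctr <- origin + (d - 1) * spacing / 2
  if (is.null(init)) init <- rigid2d(0, 0, 0, ctr[1], ctr[2])
  pyr <- list(list(img_m = moving, img_f = fixed, spacing = spacing, origin = origin))
  for (l in seq_len(cfg$levels - 1L)) {
    prev <- pyr[[1]]
    if (min(dim(prev$img_m)) < 16) break
    dm <- downsample2(prev$img_m, prev$spacing, prev$origin)
    df <- downsample2(prev$img_f, prev$spacing, prev$origin)
    pyr <- c(list(list(img_m = dm$img, img_f = df$img, spacing = dm$spacing,
                       origin = dm$origin)), pyr)
  }
  # express init about ctr: f(p) = R(p - c0) + c0 + t0 = R(p - ctr) + ctr + t'
  R0 <- matrix(c(cos(init$theta), sin(init$theta), -sin(init$theta), cos(init$theta)), 2, 2)
  tprime <- as.vector(R0 %*% (ctr - init$center)) + init$center + init$t - ctr
  par <- c(init$theta, tprime)
  mi_of <- function(par, lev) {
    rg <- rigid2d(par[1], par[2], par[3], ctr[1], ctr[2])
    pts <- grid2(dim(lev$img_f), lev$spacing, lev$origin)
    src <- apply_rigid2d(invert_rigid2d(rg), pts)
    vals <- sample_image2(lev$img_m, lev$spacing, lev$origin, src)
    bins <- adaptive_bins(length(vals), cfg$mi_bins)
    tryCatch(suppressWarnings(
      mutual_information(as.vector(lev$img_f), vals, bins)),
      error = function(e) 0)
  }
  # coarse rotation sweep at the lowest resolution to escape local optima
  sweep_th <- seq(-0.26, 0.26, length.out = 27)
  mi_sweep <- vapply(sweep_th, function(th) mi_of(c(th, par[2], par[3]), pyr[[1]]),
                     numeric(1))
  best <- c(sweep_th[which.max(mi_sweep)], par[2], par[3])
  if (mi_of(best, pyr[[1]]) > mi_of(par, pyr[[1]])) par <- best
  for (lev in pyr) {
    res <- stats::optim(par, function(p) -mi_of(p, lev), method = "Nelder-Mead",
                        control = list(maxit = cfg$max_eval,
                                       parscale = c(0.05, 0.5, 0.5),
                                       reltol = 1e-9))
    par <- res$par
    par <- compass_search(function(p) mi_of(p, lev), par,
                          scales = c(0.05, lev$spacing, lev$spacing),
                          step0 = 1, step_min = 0.02,
                          max_eval = cfg$max_eval)$par
  }
  full <- pyr[[length(pyr)]]
  out <- rigid2d(par[1], par[2], par[3], ctr[1], ctr[2])
  mi_new <- mi_of(par, full)
  mi_init <- mi_of(c(init$theta, tprime), full)
  if (mi_new < mi_init) {
    out <- rigid2d(init$theta, tprime[1], tprime[2], ctr[1], ctr[2])
    attr(out, "warning") <- "optimizer failed to improve on init"
    mi_new <- mi_init
  }
  attr(out, "mi") <- mi_new
  out
}

# Apply current per-section rigids: aligned section s = I_s pulled through
# the inverse rigid.
aligned_sections <- function(stack, rigids) {
  d <- dim(stack$sections[[1]])
  pts <- grid2(d, stack$in_plane_spacing, stack$origin2d)
  lapply(seq_along(stack$sections), function(s) {
    src <- apply_rigid2d(invert_rigid2d(rigids[[s]]), pts)
    matrix(sample_image2(stack$sections[[s]], stack$in_plane_spacing,
                         stack$origin2d, src), d[1], d[2])
  })
}

sections_to_volume <- function(stack, sections) {
  st <- stack
  st$sections <- sections
  stack_to_volume(st)
}

# 12-parameter affine registration by MI, parameterized about a center.
optim_affine_mi <- function(sample_fun, par0, ctr, max_eval, levels_pts, mi_bins) {
  mi_of <- function(par, pts, fx) {
    A <- diag(3) + matrix(par[1:9], 3, 3)
    if (abs(det(A)) < 1e-6) return(0)
    tr <- par[10:12]
    src <- sweep(sweep(pts, 2, ctr, "-") %*% t(A), 2, ctr + tr, "+")
    vals <- sample_fun(src)
    bins <- adaptive_bins(length(vals), mi_bins)
    tryCatch(suppressWarnings(mutual_information(fx, vals, bins)),
             error = function(e) 0)
  }
  par <- par0
  for (lp in levels_pts) {
    res <- stats::optim(par, function(p) -mi_of(p, lp$pts, lp$fixed),
                        method = "Nelder-Mead",
                        control = list(maxit = max_eval,
                                       parscale = c(rep(0.02, 9), rep(0.2, 3)),
                                       reltol = 1e-9))
    par <- res$par
    par <- compass_search(function(p) mi_of(p, lp$pts, lp$fixed), par,
                          scales = c(rep(0.02, 9), rep(0.2, 3)),
                          step0 = 1, step_min = 0.05, max_eval = 3 * max_eval)$par
  }
  par
}

affine_from_par <- function(par, ctr) {
  A <- diag(3) + matrix(par[1:9], 3, 3)
  tr <- par[10:12]
  affine3d(A, as.vector(ctr + tr) - as.vector(A %*% ctr))
}

par_from_affine <- function(aff, ctr) {
  c(as.vector(aff$A - diag(3)),
    as.vector(apply_affine3d(aff, matrix(ctr, 1)) - ctr))
}

#' Iterative affine reconstruction of a section stack against a reference
#'
#' Alternates (i) 3D affine registration between the current stack volume and
#' the reference (yielding, for every section plane, a "virtual reference"
#' section: the reference resliced at that plane), and (ii) 2D rigid
#' registration of each experimental section to its virtual reference. The
#' loop stops after `n_outer_iterations` or when the mean per-section MI
#' improves by less than `tol`; a drop of more than 10% between iterations
#' aborts with a diagnostic error.
#'
#' @param stack a `tm_stack`.
#' @param reference reference `tm_volume` (template intensity).
#' @param cfg a [reconstruction_config()].
#' @return list with `rigids` (per-section forward `tm_rigid2d`), `affine`
#'   (`tm_affine3d`, stack space to reference space), `mi_log` (mean section
#'   MI per iteration), and `aligned` (list of rigidly aligned sections).
#' @export
affine_reconstruction <- function(stack, reference, cfg = reconstruction_config()) {
  n <- length(stack$sections)
  d <- dim(stack$sections[[1]])
  ctr2 <- stack$origin2d + (d - 1) * stack$in_plane_spacing / 2
  rigids <- rep(list(rigid2d(0, 0, 0, ctr2[1], ctr2[2])), n)
  vol_geom <- vol_geometry(stack_to_volume(stack))
  ctr3 <- vol_geom$origin + (vol_geom$dim - 1) * vol_geom$spacing / 2
  G <- affine3d()  # stack -> reference
  pts2 <- grid2(d, stack$in_plane_spacing, stack$origin2d)
  mi_log <- numeric(0)
  ref_sample <- function(src) sample_volume(reference, src, "linear", 0)

  for (it in seq_len(cfg$n_outer_iterations)) {
    aligned <- aligned_sections(stack, rigids)
    vol <- sections_to_volume(stack, aligned)
    # multi-resolution point sets over the stack grid
    mk_pts <- function(stride) {
      g <- as.matrix(expand.grid(
        x = vol$origin[1] + (seq(1, vol_geom$dim[1], by = stride) - 1) * vol$spacing[1],
        y = vol$origin[2] + (seq(1, vol_geom$dim[2], by = max(1L, stride %/% 2)) - 1) * vol$spacing[2],
        z = vol$origin[3] + (seq(1, vol_geom$dim[3], by = stride) - 1) * vol$spacing[3]))
      storage.mode(g) <- "double"
      list(pts = g, fixed = sample_volume(vol, g, "linear", 0))
    }
    base <- max(1L, as.integer(ceiling((prod(vol_geom$dim) / 4e4)^(1 / 3))))
    levels_pts <- if (cfg$levels >= 2) list(mk_pts(2L * base), mk_pts(base))
                  else list(mk_pts(base))
    par <- optim_affine_mi(ref_sample, par_from_affine(G, ctr3), ctr3,
                           cfg$max_eval, levels_pts, cfg$mi_bins)
    G <- affine_from_par(par, ctr3)
    # virtual reference sections: reference pulled into stack space at each plane
    mis <- numeric(n)
    for (s in seq_len(n)) {
      P <- cbind(pts2[, 1], section_position(stack, s), pts2[, 2])
      vr <- matrix(sample_volume(reference, apply_affine3d(G, P), "linear", 0),
                   d[1], d[2])
      rg <- register_rigid_2d(stack$sections[[s]], vr, stack$in_plane_spacing,
                              stack$origin2d, init = rigids[[s]], cfg = cfg)
      rigids[[s]] <- rg
      mis[s] <- attr(rg, "mi")
    }
    mi_log <- c(mi_log, mean(mis))
    if (it > 1) {
      if (mi_log[it] < mi_log[it - 1] * 0.9)
        stop(sprintf(paste0("reconstruction diverged: mean MI dropped from ",
                            "%.4f to %.4f at iteration %d"),
                     mi_log[it - 1], mi_log[it], it))
      if (mi_log[it] - mi_log[it - 1] < cfg$tol) break
    }
  }
  list(rigids = rigids, affine = G, mi_log = mi_log,
       aligned = aligned_sections(stack, rigids))
}

gradient2 <- function(img, spacing) {
  d <- dim(img)
  gx <- img; gy <- img
  gx[2:(d[1] - 1), ] <- (img[3:d[1], ] - img[1:(d[1] - 2), ]) / (2 * spacing)
  gx[c(1, d[1]), ] <- 0
  gy[, 2:(d[2] - 1)] <- (img[, 3:d[2]] - img[, 1:(d[2] - 2)]) / (2 * spacing)
  gy[, c(1, d[2])] <- 0
  list(gx = gx, gy = gy)
}

warp_image2 <- function(img, u, spacing, origin) {
  d <- dim(img)
  pts <- grid2(d, spacing, origin)
  src <- pts + cbind(as.vector(u[[1]]), as.vector(u[[2]]))
  matrix(sample_image2(img, spacing, origin, src), d[1], d[2])
}

# One additive-demons update of pull field u toward target, Gaussian-regularized.
demons_step2 <- function(img, target, u, spacing, origin, sigma) {
  w <- warp_image2(img, u, spacing, origin)
  diffv <- target - w
  g <- gradient2(w, spacing)
  denom <- g$gx^2 + g$gy^2 + (diffv / spacing)^2
  denom[denom < 1e-12] <- Inf
  dux <- diffv * g$gx / denom
  duy <- diffv * g$gy / denom
  d <- dim(img)
  list(array(cpp_gauss2(as.double(u[[1]] + dux), d, rep(sigma, 2)), d),
       array(cpp_gauss2(as.double(u[[2]] + duy), d, rep(sigma, 2)), d))
}

stack_msd <- function(imgs) {
  n <- length(imgs)
  sum(vapply(seq_len(n - 1), function(s) mean((imgs[[s + 1]] - imgs[[s]])^2),
             numeric(1)))
}

max_field_gradient2 <- function(u, spacing) {
  max(vapply(u, function(m) {
    gx <- abs(diff(m)) / spacing
    gy <- abs(t(diff(t(m)))) / spacing
    max(gx, gy)
  }, numeric(1)))
}

#' Deformable reconstruction by warping sections toward neighbor averages
#'
#' For each iteration, every section is warped a small demons step toward the
#' unweighted average of its neighbors within `neighbor_radius` on either
#' side (edge sections use their available neighbors); all sections are
#' updated simultaneously from the previous iteration's images. Accumulated
#' fields are Gaussian-regularized; if a field's displacement gradient ever
#' reaches 1, regularization is increased and the iteration repeated. The
#' between-section mean-squared intensity difference (summed over the stack)
#' is monitored and never allowed to increase beyond `tol` per iteration: an
#' increasing update is reverted and the procedure stops.
#'
#' @param sections list of (already affinely reconstructed) 2D sections.
#' @param spacing mm per pixel.
#' @param origin length-2 mm origin.
#' @param cfg a [reconstruction_config()].
#' @return list with `fields` (per-section *forward* `tm_field`s, i.e. the
#'   inverted accumulated pull maps; `NULL` where no deformation was needed),
#'   `warped` (smoothed sections), `msd_log`.
#' @export
deformable_reconstruction <- function(sections, spacing, origin = c(0, 0),
                                      cfg = reconstruction_config()) {
  n <- length(sections)
  d <- dim(sections[[1]])
  zero2 <- function() list(array(0, d), array(0, d))
  u <- rep(list(zero2()), n)
  sigma <- cfg$field_sigma
  warped <- sections
  msd_log <- stack_msd(warped)
  r <- cfg$neighbor_radius
  for (it in seq_len(cfg$n_deformable_iterations)) {
    u_new <- u
    for (s in seq_len(n)) {
      nb <- setdiff(max(1, s - r):min(n, s + r), s)
      target <- Reduce(`+`, warped[nb]) / length(nb)
      for (attempt in 1:4) {
        cand <- u[[s]]
        for (sub in seq_len(max(1L, cfg$demons_steps)))
          cand <- demons_step2(sections[[s]], target, cand, spacing, origin, sigma)
        if (max_field_gradient2(cand, spacing) < 1) break
        sigma <- sigma * 1.5
        message("increasing deformable regularization to sigma = ", sigma)
      }
      u_new[[s]] <- cand
    }
    warped_new <- lapply(seq_len(n), function(s)
      warp_image2(sections[[s]], u_new[[s]], spacing, origin))
    msd <- stack_msd(warped_new)
    if (msd > utils::tail(msd_log, 1) * (1 + 1e-6)) break
    u <- u_new
    warped <- warped_new
    msd_log <- c(msd_log, msd)
  }
  fields <- lapply(u, function(us) {
    # floating-point dust from exact-grid resampling is not a deformation
    if (max(abs(us[[1]]), abs(us[[2]])) < 1e-10) return(NULL)
    pull <- displacement_field(us, rep(spacing, 2), origin)
    invert_field(pull)
  })
  list(fields = fields, warped = warped, msd_log = msd_log)
}
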