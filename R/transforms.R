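# Transform types. Every transform is a *forward point map* from its input
# space into its output space; resampling internally uses the inverse.

#' 2D rigid transform
#'
#' Forward map `p' = R(theta) (p - c) + c + t` with rotation angle `theta`
#' (radians, counter-clockwise), translation `t` (mm) and rotation center `c`
#' (mm).
#'
#' @param theta rotation angle in radians.
#' @param tx,ty translation in mm.
#' @param cx,cy rotation center in mm.
#' @return object of class `tm_rigid2d`.
#' @export
rigid2d <- function(theta = 0, tx = 0, ty = 0, cx = 0, cy = 0) {
  stopifnot(is.finite(c(theta, tx, ty, cx, cy)))
  structure(list(theta = theta, t = c(tx, ty), center = c(cx, cy)),
            class = "tm_rigid2d")
}

#' Apply a 2D rigid transform to points
#' @param tr `tm_rigid2d`.
#' @param pts n x 2 matrix (mm).
#' @return n x 2 matrix.
#' @export
apply_rigid2d <- function(tr, pts) {
  pts <- rbind_pts(pts)
  R <- matrix(c(cos(tr$theta), sin(tr$theta), -sin(tr$theta), cos(tr$theta)), 2, 2)
  out <- sweep(pts, 2, tr$center, "-") %*% t(R)
  sweep(out, 2, tr$center + tr$t, "+")
}

#' Invert a 2D rigid transform
#' @param tr `tm_rigid2d`.
#' @return `tm_rigid2d` mapping output space back to input space.
#' @export
invert_rigid2d <- function(tr) {
  # p = R^-1 (p' - c - t) + c  =  R^-1 (p' - c') + c' + t2, with c' = c + t
  cth <- cos(-tr$theta); sth <- sin(-tr$theta)
  cp <- tr$center + tr$t
  # translation so that forward(cp) maps back to tr$center + ... solve directly:
  # inv(p') = R^-1 (p' - cp) + tr$center
  # rewrite in rigid2d form with center cp: R^-1 (p' - cp) + cp + t2 where
  # t2 = tr$center - cp = -tr$t
  rigid2d(-tr$theta, -tr$t[1], -tr$t[2], cp[1], cp[2])
}

#' 3D affine transform
#'
#' Forward map `p' = A p + t` with invertible 3x3 matrix `A` and translation
#' `t` in mm.
#'
#' @param A 3x3 matrix.
#' @param t length-3 translation (mm).
#' @return object of class `tm_affine3d`.
#' @export
affine3d <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) < 1e-12) stop("Affine3D matrix is not invertible")
  structure(list(A = A, t = as.numeric(t)), class = "tm_affine3d")
}

#' Apply a 3D affine to points
#' @param tr `tm_affine3d`.
#' @param pts n x 3 matrix (mm).
#' @return n x 3 matrix.
#' @export
apply_affine3d <- function(tr, pts) {
  pts <- rbind_pts(pts)
  sweep(pts %*% t(tr$A), 2, tr$t, "+")
}

#' Invert / compose 3D affines
#' @param tr,a,b `tm_affine3d` objects; `compose_affine3d(a, b)` returns the
#'   map "apply `b` first, then `a`".
#' @return `tm_affine3d`.
#' @export
invert_affine3d <- function(tr) {
  Ai <- solve(tr$A)
  affine3d(Ai, -as.vector(Ai %*% tr$t))
}

#' @rdname invert_affine3d
#' @export
compose_affine3d <- function(a, b) {
  affine3d(a$A %*% b$A, as.vector(a$A %*% b$t) + a$t)
}

#' Displacement field (2D or 3D)
#'
#' Vector grid of mm offsets on a stated geometry; the forward point map is
#' `p' = p + d(p)` with `d` interpolated linearly (zero outside the domain).
#'
#' @param components list of numeric arrays (2 for 2D, 3 for 3D), one per
#'   axis, all on the same grid.
#' @param spacing,origin geometry of the grid (mm).
#' @return object of class `tm_field`.
#' @export
displacement_field <- function(components, spacing, origin) {
  nd <- length(components)
  stopifnot(nd %in% c(2L, 3L))
  d <- dim(components[[1]])
  for (cmp in components) {
    stopifnot(identical(dim(cmp), d))
    if (!all(is.finite(cmp))) stop("DisplacementField must be finite everywhere")
  }
  structure(list(components = components, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), ndim = nd),
            class = "tm_field")
}

#' Zero displacement field on a geometry
#' @param dim,spacing,origin grid geometry.
#' @export
zero_field <- function(dim, spacing, origin) {
  displacement_field(rep(list(array(0, dim = dim)), length(dim)), spacing, origin)
}

#' Evaluate a displacement field at points
#' @param f `tm_field`.
#' @param pts n x ndim matrix (mm).
#' @return n x ndim matrix of mm offsets (zero outside the field's domain).
#' @export
field_displacement <- function(f, pts) {
  pts <- rbind_pts(pts)
  d <- dim(f$components[[1]])
  out <- matrix(0, nrow(pts), f$ndim)
  for (a in seq_len(f$ndim)) {
    out[, a] <- if (f$ndim == 3L)
      cpp_sample3(as.double(f$components[[a]]), d, f$spacing, f$origin, pts, TRUE, 0)
    else
      cpp_sample2(as.double(f$components[[a]]), d, f$spacing, f$origin, pts, TRUE, 0)
  }
  out
}

#' Apply a displacement field as a forward point map
#' @param f `tm_field`.
#' @param pts n x ndim matrix (mm).
#' @return displaced points.
#' @export
apply_field <- function(f, pts) {
  pts <- rbind_pts(pts)
  pts + field_displacement(f, pts)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `(id + u) o (id + v) = id` (to tolerance) via the iteration
#' `v_{k+1}(x) = -u(x + v_k(x))`, which converges for smooth fields whose
#' displacement-gradient magnitude is below 1. Deterministic (no randomness).
#'
#' @param f `tm_field` to invert.
#' @param tol convergence tolerance in voxels (default 0.01).
#' @param max_iter maximum iterations (default 50).
#' @return `tm_field` with the inverse displacements.
#' @export
invert_field <- function(f, tol = 0.01, max_iter = 50L) {
  d <- dim(f$components[[1]])
  grid <- if (f$ndim == 3L) {
    g <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
    sweep(sweep(g, 2, f$spacing, "*"), 2, f$origin, "+")
  } else {
    g <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1))
    sweep(sweep(g, 2, f$spacing, "*"), 2, f$origin, "+")
  }
  storage.mode(grid) <- "double"
  # clamp lookups to the field domain: outside it the displacement reads as
  # zero, which would break the fixed-point contraction at the border
  lo <- f$origin
  hi <- f$origin + (d - 1) * f$spacing
  clamp <- function(p) pmin(pmax(p, matrix(lo, nrow(p), f$ndim, byrow = TRUE)),
                            matrix(hi, nrow(p), f$ndim, byrow = TRUE))
  v <- -field_displacement(f, grid)
  tol_mm <- tol * min(f$spacing)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    vn <- -field_displacement(f, clamp(grid + v))
    resid <- max(abs(vn - v))
    v <- vn
    if (resid < tol_mm) break
  }
  if (resid >= tol_mm)
    stop(sprintf("InversionFailed: residual %.3g mm after %d iterations",
                 resid, max_iter))
  comps <- lapply(seq_len(f$ndim), function(a) array(v[, a], dim = d))
  displacement_field(comps, f$spacing, f$origin)
}

#' Transform chain: per-section 2D stages plus global 3D stages
#'
#' The full forward map from a section point to template space is
#' 2D rigid, then 2D displacement field, then lifting to 3D at the section's
#' nominal AP plane, then the reconstruction affine, the template affine, and
#' finally the template displacement field.
#'
#' @param per_section list (one entry per section) of
#'   `list(rigid = tm_rigid2d, field = tm_field or NULL)`.
#' @param section_positions mm position of each section plane along AP.
#' @param reconstruction_affine,to_template_affine `tm_affine3d`.
#' @param to_template_field `tm_field` (3D) or `NULL`.
#' @return object of class `tm_chain`.
#' @export
transform_chain <- function(per_section, section_positions,
                            reconstruction_affine = affine3d(),
                            to_template_affine = affine3d(),
                            to_template_field = NULL) {
  stopifnot(length(per_section) == length(section_positions))
  structure(list(per_section = per_section,
                 section_positions = as.numeric(section_positions),
                 reconstruction_affine = reconstruction_affine,
                 to_template_affine = to_template_affine,
                 to_template_field = to_template_field),
            class = "tm_chain")
}

#' Identity chain for a stack
#' @param stack a `tm_stack`.
#' @return `tm_chain` with identity stages.
#' @export
identity_chain <- function(stack) {
  n <- length(stack$sections)
  transform_chain(
    per_section = rep(list(list(rigid = rigid2d(), field = NULL)), n),
    section_positions = section_position(stack, seq_len(n)))
}

#' Map section points through a transform chain
#'
#' @param chain `tm_chain`.
#' @param section 1-based section index (scalar or vector of length n).
#' @param pts n x 2 matrix of in-plane section coordinates (mm).
#' @return n x 3 matrix of template-space (ML, AP, DV) coordinates in mm.
#' @export
map_point_through_chain <- function(chain, section, pts) {
  pts <- rbind_pts(pts)
  n <- nrow(pts)
  section <- rep_len(as.integer(section), n)
  if (any(section < 1L | section > length(chain$per_section)))
    stop("MissingTransform: section index outside the chain")
  out <- matrix(NA_real_, n, 3)
  for (s in unique(section)) {
    rows <- which(section == s)
    st <- chain$per_section[[s]]
    q <- apply_rigid2d(st$rigid, pts[rows, , drop = FALSE])
    if (!is.null(st$field)) q <- apply_field(st$field, q)
    P <- cbind(q[, 1], chain$section_positions[s], q[, 2])
    out[rows, ] <- P
  }
  out <- apply_affine3d(chain$reconstruction_affine, out)
  out <- apply_affine3d(chain$to_template_affine, out)
  if (!is.null(chain$to_template_field)) out <- apply_field(chain$to_template_field, out)
  if (!all(is.finite(out))) stop("MappingDiverged: non-finite template coordinates")
  colnames(out) <- c("ML", "AP", "DV")
  out
}

#' Resample a volume onto a target geometry through a forward transform
#'
#' `t` is the forward point map from the input volume's space into the target
#' space; intensities are pulled through its inverse (computed analytically
#' for affines, by [invert_field()] for displacement fields). Label volumes
#' require nearest interpolation.
#'
#' @param vol `tm_volume` to resample.
#' @param target `tm_volume` or geometry list (`dim`, `spacing`, `origin`).
#' @param t `tm_affine3d`, `tm_field`, `NULL` (identity), or an already
#'   inverted pull map wrapped with [pull_map()].
#' @param interp `"linear"` or `"nearest"`.
#' @param background fill for out-of-domain voxels.
#' @return `tm_volume` on the target geometry.
#' @export
resample <- function(vol, target, t = NULL, interp = c("linear", "nearest"),
                     background = 0) {
  interp <- match.arg(interp)
  if (vol$kind == "label" && interp != "nearest")
    stop("ContractViolation: label volumes require interp = 'nearest'")
  geom <- vol_geometry(if (inherits(target, "tm_volume")) target else
    tm_geom_as_vol(target))
  pts <- voxel_centers(list(data = NULL, dim = geom$dim, spacing = geom$spacing,
                            origin = geom$origin))
  src <- pull_points(t, pts)
  vals <- sample_volume(vol, src, interp = interp, background = background)
  tm_volume(array(vals, dim = geom$dim), spacing = geom$spacing,
            origin = geom$origin, kind = vol$kind, axis_meaning = vol$axis_meaning)
}

tm_geom_as_vol <- function(g) list(data = NULL, dim = g$dim, spacing = g$spacing,
                                   origin = g$origin)

#' Mark a transform as an already-inverted pull map
#'
#' Registration stages naturally produce resampling (pull) maps; wrap one
#' with `pull_map()` to hand it to [resample()] without inversion.
#' @param t `tm_affine3d` or `tm_field`.
#' @export
pull_map <- function(t) {
  attr(t, "tm_pull") <- TRUE
  t
}

# Map target-space points back into source space under forward transform t.
pull_points <- function(t, pts) {
  if (is.null(t)) return(pts)
  if (isTRUE(attr(t, "tm_pull"))) {
    if (inherits(t, "tm_affine3d")) return(apply_affine3d(t, pts))
    if (inherits(t, "tm_field")) return(apply_field(t, pts))
    if (is.function(t)) return(t(pts))
    stop("unsupported pull map")
  }
  if (inherits(t, "tm_affine3d")) return(apply_affine3d(invert_affine3d(t), pts))
  if (inherits(t, "tm_field")) return(apply_field(invert_field(t), pts))
  if (is.function(t)) return(t(pts))
  stop("unsupported transform")
}

# ---- JSON (de)serialization -------------------------------------------------

tr_to_list <- function(t) {
  if (is.null(t)) return(NULL)
  if (inherits(t, "tm_rigid2d"))
    return(list(type = "rigid2d", direction = "forward", theta = t$theta,
                t = t$t, center = t$center))
  if (inherits(t, "tm_affine3d"))
    return(list(type = "affine3d", direction = "forward", A = as.vector(t$A), t = t$t))
  if (inherits(t, "tm_field"))
    return(list(type = "field", direction = "forward", ndim = t$ndim,
                dim = dim(t$components[[1]]), spacing = t$spacing, origin = t$origin,
                components = lapply(t$components, as.vector)))
  stop("unsupported transform")
}

tr_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  switch(l$type,
    rigid2d = rigid2d(l$theta, l$t[1], l$t[2], l$center[1], l$center[2]),
    affine3d = affine3d(matrix(l$A, 3, 3), l$t),
    field = displacement_field(lapply(l$components, array, dim = l$dim),
                               l$spacing, l$origin),
    stop("unknown transform type"))
}

#' Write / read a transform chain as JSON
#'
#' All stages are stored with full floating-point precision and an explicit
#' `direction = "forward"` tag, so a reloaded chain maps points bit-for-bit
#' identically.
#'
#' @param chain `tm_chain`.
#' @param path JSON file path.
#' @export
write_chain_json <- function(chain, path) {
  obj <- list(
    format = "tracemap-chain-1",
    section_positions = chain$section_positions,
    per_section = lapply(chain$per_section, function(st)
      list(rigid = tr_to_list(st$rigid), field = tr_to_list(st$field))),
    reconstruction_affine = tr_to_list(chain$reconstruction_affine),
    to_template_affine = tr_to_list(chain$to_template_affine),
    to_template_field = tr_to_list(chain$to_template_field))
  # 17 significant digits: doubles survive the round-trip bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_chain_json
#' @export
read_chain_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  lst <- function(x) lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  # absent stages serialize as JSON null and parse back as empty lists
  fix <- function(l) if (is.null(l) || length(l) == 0) NULL else lst(l)
  per_section <- lapply(obj$per_section, function(st) {
    f <- st$field
    if (is.null(f) || length(f) == 0) f <- NULL
    if (!is.null(f)) {
      f <- list(type = f$type, ndim = f$ndim, dim = unlist(f$dim),
                spacing = unlist(f$spacing), origin = unlist(f$origin),
                components = lapply(f$components, unlist))
    }
    list(rigid = tr_from_list(fix(st$rigid)), field = tr_from_list(f))
  })
  tf <- obj$to_template_field
  if (!is.null(tf) && length(tf) == 0) tf <- NULL
  if (!is.null(tf))
    tf <- list(type = tf$type, ndim = tf$ndim, dim = unlist(tf$dim),
               spacing = unlist(tf$spacing), origin = unlist(tf$origin),
               components = lapply(tf$components, unlist))
  transform_chain(
    per_section = per_section,
    section_positions = unlist(obj$section_positions),
    reconstruction_affine = tr_from_list(fix(obj$reconstruction_affine)),
    to_template_affine = tr_from_list(fix(obj$to_template_affine)),
    to_template_field = tr_from_list(tf))
}
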