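# Mapping cells and injection sites into template space: cortical-area
# assignment, Laplace-equation cortical depth, record finalization and
# per-area summaries.

cortical_label_ids <- function(labels, wm_label) {
  ids <- sort(unique(as.vector(labels$data)))
  setdiff(ids, c(0, wm_label))
}

cortex_centers_cache <- function(labels, wm_label) {
  ids <- cortical_label_ids(labels, wm_label)
  if (length(ids) == 0) stop("ConfigError: empty cortex label set")
  d <- dim(labels$data)
  vox <- which(labels$data %in% ids)
  ijk <- cbind((vox - 1) %% d[1], ((vox - 1) %/% d[1]) %% d[2],
               (vox - 1) %/% (d[1] * d[2]))
  list(centers = voxel_to_world(labels, ijk),
       labels = as.integer(labels$data[vox]))
}

#' Assign template points to cortical areas
#'
#' A point inside a cortical label keeps it; a point outside the cortical
#' delineation is assigned to the nearest cortical voxel by Euclidean
#' distance in mm (ties broken toward the smaller label id), up to
#' `max_fallback_mm`, beyond which it is left unassigned (`NA`). The
#' distance to the fallback voxel is returned for the cell record.
#'
#' @param pts n x 3 matrix of template-space mm coordinates.
#' @param labels label `tm_volume` (parcellation).
#' @param wm_label integer label of white matter (excluded from "cortical").
#' @param max_fallback_mm fallback cap in mm (default 1.0).
#' @return data frame with `area` (integer or NA) and `fallback_mm`.
#' @export
assign_area <- function(pts, labels, wm_label, max_fallback_mm = 1.0) {
  pts <- rbind_pts(pts)
  ids <- cortical_label_ids(labels, wm_label)
  if (length(ids) == 0) stop("ConfigError: empty cortex label set")
  at <- as.integer(sample_volume(labels, pts, "nearest", 0))
  area <- ifelse(at %in% ids, at, NA_integer_)
  fallback <- numeric(nrow(pts))
  miss <- which(is.na(area))
  if (length(miss)) {
    cc <- cortex_centers_cache(labels, wm_label)
    nn <- cpp_nn_label(pts[miss, , drop = FALSE], cc$centers, cc$labels)
    ok <- nn$distance <= max_fallback_mm
    area[miss[ok]] <- nn$label[ok]
    fallback[miss] <- nn$distance
    fallback[miss[!ok]] <- NA_real_
  }
  data.frame(area = as.integer(area), fallback_mm = fallback)
}

#' Solve the Laplace cortical depth field
#'
#' Solves the Laplace equation for a potential `phi` on cortex voxels with
#' boundary conditions 0 at the pial side (non-cortex, non-white-matter
#' neighbors) and 1 at the white-matter side, by successive over-relaxation
#' to a stated residual. Streamlines of the potential gradient are then
#' integrated (RK2, 0.25-voxel steps) from every cortex voxel in both
#' directions; thickness is the total streamline length and normalized depth
#' the pial-side fraction. Voxels whose streamline fails (flat gradient near
#' sharp label corners) fall back to `phi` itself as normalized depth and
#' inherit the thickness of the nearest successful voxel; their count is
#' reported.
#'
#' @param labels label `tm_volume` with background 0, cortical areas, and a
#'   white-matter label.
#' @param wm_label integer white-matter label.
#' @param tol relaxation residual tolerance (default 1e-4).
#' @param max_iter relaxation iteration cap.
#' @param step_vox streamline step in voxels.
#' @return object of class `tm_depthfield`: volumes `phi`, `thickness`,
#'   `norm_depth`, logical `mid_mask` (mid-thickness voxel set) and
#'   `cortex_mask`, plus solver diagnostics.
#' @export
solve_depth <- function(labels, wm_label, tol = 1e-4, max_iter = 5000L,
                        step_vox = 0.25) {
  d <- dim(labels$data)
  ids <- cortical_label_ids(labels, wm_label)
  if (length(ids) == 0) stop("ConfigError: empty cortex label set")
  cortex <- labels$data %in% ids
  if (!any(cortex)) stop("ConfigError: no cortex voxels")
  wm <- labels$data == wm_label
  phi0 <- array(0, d)
  phi0[wm] <- 1
  phi0[cortex] <- 0.5
  free <- array(0L, d)
  free[cortex] <- 1L
  sol <- cpp_laplace(as.double(phi0), d, labels$spacing, as.integer(free),
                     as.integer(max_iter), tol, 1.9)
  if (sol$residual >= tol)
    stop(sprintf("SolverFailed: Laplace residual %.3g after %d iterations",
                 sol$residual, sol$iterations))
  phi <- array(sol$phi, d)
  vox <- which(cortex)
  ijk <- cbind((vox - 1) %% d[1], ((vox - 1) %/% d[1]) %% d[2],
               (vox - 1) %/% (d[1] * d[2]))
  seeds <- voxel_to_world(labels, ijk)
  cm <- array(0L, d)
  cm[cortex] <- 1L
  sl <- cpp_streamlines(as.double(phi), as.integer(cm), d, labels$spacing,
                        labels$origin, seeds, step_vox, 4000L)
  thick <- array(NA_real_, d)
  ndep <- array(NA_real_, d)
  ok <- sl[, 3] > 0 & (sl[, 1] + sl[, 2]) > 0
  thick[vox[ok]] <- sl[ok, 1] + sl[ok, 2]
  ndep[vox[ok]] <- sl[ok, 1] / (sl[ok, 1] + sl[ok, 2])
  n_fail <- sum(!ok)
  if (n_fail > 0) {
    message(n_fail, " cortex voxels fell back to the potential as depth")
    fail <- vox[!ok]
    ndep[fail] <- phi[fail]
    if (any(ok)) {
      nn <- cpp_nn_label(seeds[!ok, , drop = FALSE],
                         seeds[ok, , drop = FALSE], seq_len(sum(ok)))
      thick[fail] <- (sl[ok, 1] + sl[ok, 2])[nn$label]
    }
  }
  # mid-thickness voxels: normalized depth within half a voxel of 0.5
  half <- min(labels$spacing) / 2
  mid <- array(FALSE, d)
  mid[vox] <- abs(ndep[vox] - 0.5) <= half / pmax(thick[vox], 1e-9)
  thick_vol <- tm_volume(array(0, d), labels$spacing, labels$origin)
  thick_vol$data[] <- thick
  nd_vol <- tm_volume(array(0, d), labels$spacing, labels$origin)
  nd_vol$data[] <- ndep
  structure(list(
    phi = tm_volume(phi, labels$spacing, labels$origin),
    thickness = thick_vol, norm_depth = nd_vol, mid_mask = mid,
    cortex_mask = cm, wm_label = wm_label, step_vox = step_vox,
    iterations = sol$iterations, residual = sol$residual,
    n_streamline_fallback = n_fail), class = "tm_depthfield")
}

#' Nominal and normalized depth of arbitrary template points
#'
#' Points inside cortex get streamline-integrated depths; points outside the
#' brain get nominal and normalized depth 0; points in the subjacent white
#' matter get normalized depth 1 and a nominal depth equal to the thickness
#' at the nearest cortical voxel (the depth of the gray/white border).
#'
#' @param depth a `tm_depthfield` from [solve_depth()].
#' @param labels the label `tm_volume` used to solve it.
#' @param pts n x 3 matrix of template mm points.
#' @return data frame with `nominal_depth_mm` and `normalized_depth`.
#' @export
depth_at_points <- function(depth, labels, pts) {
  pts <- rbind_pts(pts)
  wm_label <- depth$wm_label
  lab <- as.integer(sample_volume(labels, pts, "nearest", 0))
  d <- dim(labels$data)
  nom <- numeric(nrow(pts))
  nd <- numeric(nrow(pts))
  in_ctx <- lab != 0 & lab != wm_label
  if (any(in_ctx)) {
    sl <- cpp_streamlines(as.double(depth$phi$data), as.integer(depth$cortex_mask),
                          d, labels$spacing, labels$origin,
                          pts[in_ctx, , drop = FALSE], depth$step_vox, 4000L)
    tot <- sl[, 1] + sl[, 2]
    ok <- sl[, 3] > 0 & tot > 0
    nom_c <- ifelse(ok, sl[, 1], NA_real_)
    nd_c <- ifelse(ok, sl[, 1] / tot, NA_real_)
    if (any(!ok)) {
      ph <- sample_volume(depth$phi, pts[in_ctx, , drop = FALSE][!ok, , drop = FALSE])
      th <- sample_volume(depth$thickness, pts[in_ctx, , drop = FALSE][!ok, , drop = FALSE],
                          interp = "nearest")
      nd_c[!ok] <- pmin(pmax(ph, 0), 1)
      nom_c[!ok] <- nd_c[!ok] * ifelse(is.finite(th) & th > 0, th, 0)
    }
    nom[in_ctx] <- nom_c
    nd[in_ctx] <- nd_c
  }
  is_wm <- lab == wm_label
  if (any(is_wm)) {
    nd[is_wm] <- 1
    cc <- cortex_centers_cache(labels, wm_label)
    # nominal depth = thickness at the nearest cortical voxel
    thick_at <- sample_volume(depth$thickness, cc$centers, interp = "nearest")
    nnidx <- cpp_nn_label(pts[is_wm, , drop = FALSE], cc$centers,
                          seq_len(nrow(cc$centers)))$label
    nom[is_wm] <- thick_at[nnidx]
  }
  data.frame(nominal_depth_mm = nom, normalized_depth = pmin(pmax(nd, 0), 1))
}

#' Finalize cell records in template space
#'
#' Maps every input point through the transform chain, assigns a cortical
#' area (with nearest-structure fallback), nominal and normalized depth, and
#' optional flat-map coordinates; computes each injection's center of mass as
#' the unweighted mean of its `injection_voxel` points. Unmappable points
#' (beyond the fallback cap) are retained with `assigned = FALSE` and
#' excluded from summaries. Output is deterministically sorted.
#'
#' @param cells data frame with columns `animal,tracer,kind,section,x_mm,y_mm`.
#' @param chain a `tm_chain`.
#' @param labels template parcellation `tm_volume`.
#' @param depth a `tm_depthfield`.
#' @param area_names optional named character vector (label id -> name).
#' @param flatmap optional function mapping an n x 3 mm matrix to n x 2
#'   flat-map coordinates.
#' @param max_fallback_mm nearest-structure fallback cap, mm.
#' @return list with `records` (one row per point) and `injections` (center
#'   of mass and area per animal x tracer).
#' @export
finalize_records <- function(cells, chain, labels, depth, area_names = NULL,
                             flatmap = NULL, max_fallback_mm = 1.0) {
  req <- c("animal", "tracer", "kind", "section", "x_mm", "y_mm")
  if (!all(req %in% names(cells))) stop("cells CSV missing required columns")
  mapped <- map_point_through_chain(chain, cells$section,
                                    as.matrix(cells[, c("x_mm", "y_mm")]))
  aa <- assign_area(mapped, labels, depth$wm_label, max_fallback_mm)
  dd <- depth_at_points(depth, labels, mapped)
  rec <- data.frame(cells[req], ml = mapped[, 1], ap = mapped[, 2],
                    dv = mapped[, 3], area = aa$area,
                    area_name = if (is.null(area_names)) paste0("area ", aa$area)
                                else unname(area_names[as.character(aa$area)]),
                    fallback_mm = aa$fallback_mm,
                    nominal_depth_mm = dd$nominal_depth_mm,
                    normalized_depth = dd$normalized_depth,
                    assigned = !is.na(aa$area),
                    stringsAsFactors = FALSE)
  if (!is.null(flatmap)) {
    fm <- flatmap(mapped)
    rec$flat_u <- fm[, 1]
    rec$flat_v <- fm[, 2]
  }
  keep_extra <- setdiff(names(cells), names(rec))
  for (k in keep_extra) rec[[k]] <- cells[[k]]
  o <- order(rec$animal, rec$tracer, rec$kind, rec$section, rec$x_mm, rec$y_mm)
  rec <- rec[o, , drop = FALSE]
  rownames(rec) <- NULL
  inj <- rec[rec$kind == "injection_voxel" & rec$assigned, , drop = FALSE]
  injections <- NULL
  if (nrow(inj)) {
    sp <- split(inj, paste(inj$animal, inj$tracer, sep = "/"))
    injections <- do.call(rbind, lapply(sp, function(g) {
      com <- colMeans(g[, c("ml", "ap", "dv")])
      a <- assign_area(matrix(com, 1), labels, depth$wm_label, max_fallback_mm)
      data.frame(animal = g$animal[1], tracer = g$tracer[1],
                 ml = com[1], ap = com[2], dv = com[3], area = a$area,
                 n_voxels = nrow(g), stringsAsFactors = FALSE)
    }))
    rownames(injections) <- NULL
  }
  n_unmapped <- sum(!rec$assigned)
  if (n_unmapped > 0) message(n_unmapped, " points beyond the fallback cap left unassigned")
  list(records = rec, injections = injections)
}

#' Summarize labeled cells per (possibly grouped) cortical area
#'
#' Counts cells per area, optionally merging areas into supergroups, and
#' computes the percentage of extrinsic cells: cells in the injected area
#' (intrinsic connections) are excluded from the denominator and the injected
#' area's percentage is flagged undefined (`NA`), as is conventional for
#' retrograde tracing counts.
#'
#' @param records record table from [finalize_records()] (cells only are
#'   counted; injection voxels and unassigned points are ignored).
#' @param injected_area integer label (or grouped name) of the injected area.
#' @param grouping optional named list: supergroup name -> vector of area ids
#'   or names to merge.
#' @return data frame with `area`, `n_cells`, `percent` (NA for the injected
#'   area), `mean_normalized_depth`.
#' @export
summarize_areas <- function(records, injected_area, grouping = NULL) {
  cells <- records[records$kind == "cell" & records$assigned, , drop = FALSE]
  key <- as.character(cells$area)
  inj_key <- as.character(injected_area)
  if (!is.null(grouping)) {
    for (g in names(grouping)) {
      members <- as.character(grouping[[g]])
      unknown <- setdiff(members, c(unique(key), inj_key, members))
      key[key %in% members] <- g
      if (inj_key %in% members) inj_key <- g
    }
  }
  agg <- tapply(cells$normalized_depth, key, mean)
  cnt <- table(key)
  out <- data.frame(area = names(cnt), n_cells = as.integer(cnt),
                    mean_normalized_depth = as.numeric(agg[names(cnt)]),
                    stringsAsFactors = FALSE)
  extr <- out$area != inj_key
  denom <- sum(out$n_cells[extr])
  out$percent <- ifelse(extr, 100 * out$n_cells / max(denom, 1), NA_real_)
  out[order(out$area), , drop = FALSE]
}

#' Analytic flat-map coordinates on the phantom shell
#'
#' Longitude (azimuth about the AP axis) and latitude (toward AP) of template
#' points on the phantom's hemispherical shell.
#'
#' @param pts n x 3 template mm points.
#' @param cfg the [phantom_config()] that generated the template.
#' @return n x 2 matrix (azimuth, latitude) in radians.
#' @export
shell_flatmap <- function(pts, cfg) {
  pts <- rbind_pts(pts)
  dx <- pts[, 1] - cfg$center[1]
  dy <- pts[, 2] - cfg$center[2]
  dz <- pts[, 3] - cfg$center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  cbind(atan2(pmax(dz, 0), dx), asin(pmin(pmax(ifelse(r > 0, dy / r, 0), -1), 1)))
}
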