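#' @useDynLib tracemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a 3D volume
#'
#' A volume is a scalar grid with physical geometry: millimetre spacing per
#' axis and the millimetre world position of voxel `(0, 0, 0)` (0-based voxel
#' indices, world coordinates taken at voxel centers). Axes are tagged with
#' their stereotaxic meaning, by default medio-lateral (ML), antero-posterior
#' (AP) and dorso-ventral (DV).
#'
#' @param data numeric 3D array indexed `[i, j, k]`.
#' @param spacing numeric length-3, mm per voxel per axis; must be positive.
#' @param origin numeric length-3, mm world coordinate of voxel `(0, 0, 0)`.
#' @param kind `"intensity"` or `"label"`. Label volumes must contain only
#'   non-negative integers.
#' @param axis_meaning character length-3 axis tags.
#' @return An object of class `tm_volume`.
#' @export
tm_volume <- function(data, spacing, origin = c(0, 0, 0), kind = c("intensity", "label"),
                      axis_meaning = c("ML", "AP", "DV")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  if (kind == "label") {
    v <- as.vector(data)
    if (any(v < 0) || any(v != round(v)))
      stop("label volumes contain only non-negative integers")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind,
                 axis_meaning = axis_meaning),
            class = "tm_volume")
}

#' @export
print.tm_volume <- function(x, ...) {
  cat(sprintf("<tm_volume %s> dims %s, spacing %s mm, origin %s mm, axes %s\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              paste(x$axis_meaning, collapse = "/")))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' `world(v) = origin + v * spacing`, an invertible affine map. Voxel indices
#' are 0-based and may be fractional.
#'
#' @param vol a `tm_volume`.
#' @param ijk,xyz matrix (n x 3) or length-3 vector of voxel indices / mm.
#' @return n x 3 matrix.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_pts(ijk)
  sweep(sweep(ijk, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_pts(xyz)
  sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  storage.mode(p) <- "double"
  p
}

#' Sample a volume at arbitrary world points
#'
#' Trilinear (`"linear"`) or nearest-neighbour (`"nearest"`) interpolation;
#' points outside the grid (beyond half a voxel past the border centers)
#' return `background`.
#'
#' @param vol a `tm_volume`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param interp `"linear"` or `"nearest"`.
#' @param background fill value outside the domain.
#' @return numeric vector of sampled values.
#' @export
sample_volume <- function(vol, pts, interp = c("linear", "nearest"), background = 0) {
  interp <- match.arg(interp)
  if (vol$kind == "label" && interp == "linear")
    stop("ContractViolation: linear interpolation on a label volume")
  cpp_sample3(as.double(vol$data), dim(vol$data), vol$spacing, vol$origin,
              rbind_pts(pts), interp == "linear", background)
}

#' Grid of all voxel-center world coordinates
#' @param vol a `tm_volume` (or a geometry list with `dim`, `spacing`, `origin`).
#' @return (prod(dim) x 3) matrix, fastest-varying first axis (R array order).
#' @export
voxel_centers <- function(vol) {
  d <- vol_dim(vol)
  g <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                             k = seq_len(d[3]) - 1))
  storage.mode(g) <- "double"
  sweep(sweep(g, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

vol_dim <- function(vol) if (!is.null(vol$data)) dim(vol$data) else vol$dim

#' Volume geometry descriptor
#' @param vol a `tm_volume`.
#' @return list with `dim`, `spacing`, `origin`.
#' @export
vol_geometry <- function(vol) list(dim = vol_dim(vol), spacing = vol$spacing,
                                   origin = vol$origin)

#' Read / write volumes as NIfTI-1
#'
#' Geometry (mm spacing, origin) is carried in the NIfTI sform. Label volumes
#' round-trip as integers.
#'
#' @param vol a `tm_volume`.
#' @param path file path, typically `.nii.gz`.
#' @param kind volume kind for reading.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  xf <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- c(sqrt(sum(xf[1:3, 1]^2)), sqrt(sum(xf[1:3, 2]^2)),
               sqrt(sum(xf[1:3, 3]^2)))
  origin <- xf[1:3, 4]
  data <- array(as.double(img), dim = dim(img))
  if (kind == "label") data <- array(as.double(round(data)), dim = dim(data))
  tm_volume(data, spacing = spacing, origin = origin, kind = kind)
}

#' Create a section stack
#'
#' An ordered list of 2D grayscale section images sharing one in-plane
#' spacing, with a fixed inter-section (apparent thickness) spacing along the
#' stacking axis. Sections are ordered rostrocaudally.
#'
#' @param sections list of 2D numeric matrices (all the same size).
#' @param in_plane_spacing mm per pixel.
#' @param section_spacing mm between consecutive sections (apparent thickness).
#' @param origin2d length-2 mm world coordinate of pixel `(0, 0)` in-plane.
#' @param origin_axis mm position of the first section along the stack axis.
#' @param index_axis which template axis the ordering follows (default `"AP"`).
#' @return An object of class `tm_stack`.
#' @export
tm_stack <- function(sections, in_plane_spacing, section_spacing,
                     origin2d = c(0, 0), origin_axis = 0, index_axis = "AP") {
  stopifnot(length(sections) >= 1, section_spacing > 0, in_plane_spacing > 0)
  d <- dim(sections[[1]])
  for (s in sections) stopifnot(identical(dim(s), d))
  structure(list(sections = sections, in_plane_spacing = in_plane_spacing,
                 section_spacing = section_spacing, origin2d = as.numeric(origin2d),
                 origin_axis = origin_axis, index_axis = index_axis),
            class = "tm_stack")
}

#' @export
print.tm_stack <- function(x, ...) {
  cat(sprintf("<tm_stack> %d sections %s px, %.3g mm/px in-plane, %.3g mm apart\n",
              length(x$sections), paste(dim(x$sections[[1]]), collapse = "x"),
              x$in_plane_spacing, x$section_spacing))
  invisible(x)
}

#' AP-axis position of a section plane
#' @param stack a `tm_stack`.
#' @param s 1-based section index (may be a vector).
#' @return mm position(s) along the stacking axis.
#' @export
section_position <- function(stack, s) stack$origin_axis + (s - 1) * stack$section_spacing

#' Assemble a stack into a 3D volume
#'
#' Axis order of the result is (in-plane x = ML, stack axis = AP,
#' in-plane y = DV).
#' @param stack a `tm_stack`.
#' @return a `tm_volume`.
#' @export
stack_to_volume <- function(stack) {
  d <- dim(stack$sections[[1]])
  n <- length(stack$sections)
  arr <- array(0, dim = c(d[1], n, d[2]))
  for (s in seq_len(n)) arr[, s, ] <- stack$sections[[s]]
  tm_volume(arr, spacing = c(stack$in_plane_spacing, stack$section_spacing,
                             stack$in_plane_spacing),
            origin = c(stack$origin2d[1], stack$origin_axis, stack$origin2d[2]))
}

#' Read / write a section stack as numbered grayscale PNG or TIFF files
#'
#' Images are written as 16-bit grayscale PNG (`format = "png"`) or 32-bit
#' float TIFF, one file per section (`section_0001.png`, ...), with geometry
#' in a sidecar `stack.json`.
#'
#' @param stack a `tm_stack`.
#' @param dir output directory.
#' @param format `"png"` or `"tiff"`.
#' @export
write_stack <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(unlist(lapply(stack$sections, range)))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  for (s in seq_along(stack$sections)) {
    img <- stack$sections[[s]]
    # png/tiff readers index rows from the top; transpose to row = y
    m <- t((img - rng[1]) / scale)
    f <- file.path(dir, sprintf("section_%04d.%s", s,
                                if (format == "png") "png" else "tif"))
    if (format == "png") png::writePNG(m, f) else tiff::writeTIFF(m, f, bits.per.sample = 32L)
  }
  meta <- list(n_sections = length(stack$sections),
               in_plane_spacing = stack$in_plane_spacing,
               section_spacing = stack$section_spacing,
               origin2d = stack$origin2d, origin_axis = stack$origin_axis,
               index_axis = stack$index_axis, format = format,
               intensity_range = rng)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  ext <- if (meta$format == "png") "png" else "tif"
  rng <- meta$intensity_range
  sections <- lapply(seq_len(meta$n_sections), function(s) {
    f <- file.path(dir, sprintf("section_%04d.%s", s, ext))
    m <- if (meta$format == "png") png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    t(m) * (rng[2] - rng[1]) + rng[1]
  })
  tm_stack(sections, in_plane_spacing = meta$in_plane_spacing,
           section_spacing = meta$section_spacing, origin2d = meta$origin2d,
           origin_axis = meta$origin_axis, index_axis = meta$index_axis)
}

#' Read / write point annotations (cells and injection voxels)
#'
#' CSV with columns `animal,tracer,kind,section,x_mm,y_mm` (`kind` is
#' `cell` or `injection_voxel`; `section` is the 1-based section index; x/y
#' are in-plane section coordinates in mm). Extra columns are preserved.
#'
#' @param cells data frame.
#' @param path CSV path.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
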