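# Image-similarity and landmark metrics driving the registrations.

#' Mutual information between two images
#'
#' Joint-histogram mutual information in bits:
#' `MI = sum p(i,j) log2( p(i,j) / (p(i) p(j)) )`, with `bins` equal-width
#' bins per image spanning each image's own range over the overlap (pairs
#' where either value is non-finite are dropped). No Parzen smoothing is
#' applied; for driving an optimizer only the ranking of values matters.
#'
#' @param a,b numeric arrays/vectors of identical length (2D or 3D images,
#'   or already-sampled voxel vectors).
#' @param bins number of histogram bins per image (>= 2, default 32).
#' @return mutual information in bits (>= 0). A constant image yields 0 with
#'   a warning (degenerate marginal).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("images must have the same shape")
  stopifnot(bins >= 2)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 1) stop("no overlapping voxels")
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) {
    warning("constant image: mutual information is 0 (degenerate marginal)")
    return(0)
  }
  bi <- pmin(bins, 1L + floor((a - ra[1]) / diff(ra) * bins))
  bj <- pmin(bins, 1L + floor((b - rb[1]) / diff(rb) * bins))
  joint <- tabulate(bi + bins * (bj - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log2(pm[nz] / outer(px, py)[nz]))
}

#' Windowed (local) cross-correlation
#'
#' Mean over voxels of the Pearson correlation between the two images within
#' the `(2r+1)^d` window centered at each voxel (windows clamped at the image
#' border), averaged over voxels whose window has positive variance in both
#' images.
#'
#' @param a,b numeric arrays of identical dimension (2D or 3D).
#' @param radius window radius in voxels (>= 1).
#' @return mean local correlation in `[-1, 1]`.
#' @export
windowed_cross_correlation <- function(a, b, radius = 5L) {
  stopifnot(radius >= 1)
  da <- dim(a)
  if (is.null(da)) stop("a and b must be arrays")
  if (!identical(da, dim(b))) stop("images must have the same shape")
  if (length(da) == 2L) da <- c(da, 1L)
  a3 <- as.double(a); b3 <- as.double(b)
  n <- cpp_box3(rep(1.0, length(a3)), da, radius)
  sa <- cpp_box3(a3, da, radius)
  sb <- cpp_box3(b3, da, radius)
  saa <- cpp_box3(a3 * a3, da, radius)
  sbb <- cpp_box3(b3 * b3, da, radius)
  sab <- cpp_box3(a3 * b3, da, radius)
  va <- saa - sa * sa / n
  vb <- sbb - sb * sb / n
  cov <- sab - sa * sb / n
  eps <- 1e-12 * max(1, max(abs(a3)))^2
  valid <- va > eps & vb > eps
  if (!any(valid)) stop("MetricUndefined: no windows with positive variance")
  mean(pmin(1, pmax(-1, cov[valid] / sqrt(va[valid] * vb[valid]))))
}

#' Point-set expectation (PSE) between labeled point sets
#'
#' For each landmark label, the mean distance from each point in one set to
#' the nearest same-label point in the other, symmetrized by averaging the
#' two directions; the total is the average over labels. It is a
#' pseudo-metric on labeled point multisets: symmetric, non-negative, and
#' zero exactly when the sets coincide as sets.
#'
#' @param A,B named lists mapping label -> (n x d) point matrix (mm). Both
#'   sides must carry the same label inventory, each set non-empty.
#' @return mean symmetric nearest-point distance in mm.
#' @export
point_set_expectation <- function(A, B) {
  la <- sort(names(A)); lb <- sort(names(B))
  if (!identical(la, lb))
    stop("LandmarkMismatch: label inventories differ (",
         paste(setdiff(union(la, lb), intersect(la, lb)), collapse = ", "), ")")
  per_label <- vapply(la, function(l) {
    pa <- rbind_pts(A[[l]]); pb <- rbind_pts(B[[l]])
    if (nrow(pa) == 0 || nrow(pb) == 0)
      stop("LandmarkMismatch: empty point set for label ", l)
    (mean(cpp_nn_dist(pa, pb)) + mean(cpp_nn_dist(pb, pa))) / 2
  }, numeric(1))
  mean(per_label)
}

#' Convert a landmark label volume into labeled point sets
#'
#' Takes the world coordinates of all labeled voxel centers, subsampled to at
#' most `max_points` per label with a deterministic stride.
#'
#' @param vol a label `tm_volume` of landmark sectors.
#' @param max_points per-label cap (default 2000).
#' @return named list label -> (n x 3) mm point matrix.
#' @export
labels_to_points <- function(vol, max_points = 2000L) {
  labs <- sort(setdiff(unique(as.vector(vol$data)), 0))
  d <- dim(vol$data)
  out <- list()
  for (l in labs) {
    vox <- which(vol$data == l)
    stride <- max(1L, ceiling(length(vox) / max_points))
    vox <- vox[seq(1L, length(vox), by = stride)]
    ijk <- cbind((vox - 1) %% d[1], ((vox - 1) %/% d[1]) %% d[2],
                 (vox - 1) %/% (d[1] * d[2]))
    out[[as.character(l)]] <- voxel_to_world(vol, ijk)
  }
  out
}

#' Metric configuration
#'
#' @param mi_bins joint-histogram bins for mutual information (>= 2).
#' @param cc_kernel_radius local cross-correlation window radius, voxels.
#' @param weights named metric weights (`cc`, `pse`); equal by default. The
#'   PSE term is rescaled by 1 / image diagonal before weighting so the two
#'   metrics are on comparable scales.
#' @export
metric_config <- function(mi_bins = 32L, cc_kernel_radius = 5L,
                          weights = c(cc = 1, pse = 1)) {
  stopifnot(mi_bins >= 2, cc_kernel_radius >= 1, all(weights >= 0),
            any(weights > 0))
  list(mi_bins = as.integer(mi_bins),
       cc_kernel_radius = as.integer(cc_kernel_radius), weights = weights)
}
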