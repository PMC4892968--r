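# Accuracy assessment: injection-site discrepancies, per-area percentage
# agreement, and sparse-connection concordance.

#' Euclidean discrepancy between two stereotaxic coordinate triples
#'
#' @param auto,expert length-3 (ML, AP, DV) mm triples, or n x 3 matrices.
#' @return Euclidean distance(s) in mm.
#' @export
euclidean_discrepancy <- function(auto, expert) {
  a <- rbind_pts(auto); e <- rbind_pts(expert)
  if (!all(is.finite(a)) || !all(is.finite(e))) stop("coordinates must be finite")
  sqrt(rowSums((a - e)^2))
}

#' Per-case injection-site discrepancy table
#'
#' Recomputes the Euclidean distance between automated and expert coordinate
#' triples for every row, and their arithmetic mean.
#'
#' @param rows data frame with columns `auto_ml, auto_ap, auto_dv,
#'   expert_ml, expert_ap, expert_dv` (other columns are carried through).
#' @return list with `table` (input plus `discrepancy_mm`) and `mean_mm`.
#' @export
discrepancy_table <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  d <- euclidean_discrepancy(as.matrix(rows[, c("auto_ml", "auto_ap", "auto_dv")]),
                             as.matrix(rows[, c("expert_ml", "expert_ap", "expert_dv")]))
  rows$discrepancy_mm <- d
  list(table = rows, mean_mm = mean(d))
}

#' Load the packaged injection-site coordinate fixture
#'
#' Seventeen tracer injections (nine animals) with the stereotaxic
#' coordinates of each injection center as estimated by the automated
#' mapping and by an expert neuroanatomist, and the recorded per-case
#' discrepancy. AP values are negative as recorded (rostral to the interaural
#' line under the atlas convention adopted here).
#'
#' @return data frame with one row per injection.
#' @export
load_injection_table <- function() {
  utils::read.csv(system.file("extdata", "table1.csv", package = "tracemap"),
                  stringsAsFactors = FALSE)
}

#' Load the example supergroup definitions
#'
#' Named list: supergroup -> member area abbreviations (an illustrative
#' "core and belt" auditory grouping; membership list is synthetic).
#' @return named list.
#' @export
load_supergroups <- function() {
  g <- jsonlite::read_json(system.file("extdata", "supergroups.json", package = "tracemap"),
                           simplifyVector = TRUE)
  g[!startsWith(names(g), "_")]
}

# Expert percentages for very sparse connections are sometimes reported as a
# range ("0.05-0.1"); such interval cells are scored at their midpoint.
parse_percent <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(v) {
    v <- trimws(v)
    if (grepl("^-?[0-9.]+\\s*-\\s*[0-9.]+$", v) && !grepl("^-?[0-9.]+$", v)) {
      parts <- as.numeric(strsplit(v, "\\s*-\\s*")[[1]])
      mean(parts)
    } else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

match_pairs <- function(expert, auto, grouping = NULL) {
  prep <- function(tab) {
    stopifnot(all(c("injection", "area", "percent") %in% names(tab)))
    tab$area <- as.character(tab$area)
    if (!is.null(grouping)) {
      known <- unique(tab$area)
      for (g in names(grouping)) {
        members <- as.character(grouping[[g]])
        tab$area[tab$area %in% members] <- g
      }
    }
    agg <- stats::aggregate(list(percent = parse_percent(tab$percent)),
                            by = list(injection = tab$injection, area = tab$area),
                            FUN = sum)
    agg
  }
  if (!is.null(grouping)) {
    all_areas <- unique(c(as.character(expert$area), as.character(auto$area)))
    for (g in names(grouping)) {
      unknown <- setdiff(as.character(grouping[[g]]), all_areas)
      if (length(unknown) == length(grouping[[g]]))
        stop("ConfigError: grouping '", g, "' references only unknown areas")
    }
  }
  e <- prep(expert); a <- prep(auto)
  m <- merge(e, a, by = c("injection", "area"), suffixes = c("_expert", "_auto"))
  m[order(m$injection, m$area), , drop = FALSE]
}

#' Agreement between expert and automated per-area cell percentages
#'
#' Pairs the two tables on (injection, area) keys after optional supergroup
#' merging, computes the Pearson correlation over the paired percentages
#' (both including and excluding pairs that are zero on both sides), and
#' lists outlier pairs above an absolute-difference threshold.
#'
#' @param expert,auto data frames with columns `injection`, `area`,
#'   `percent` (expert percentages may be interval strings like "0.05-0.1",
#'   scored at the midpoint).
#' @param grouping optional supergroup definition (named list).
#' @param outlier_threshold absolute percentage-point difference flagged as
#'   an outlier.
#' @return list of class `tm_agreement`: `n_pairs`, `pearson_r`,
#'   `pearson_r_nonzero` (zero-zero pairs dropped), `outliers`, `pairs`.
#' @export
percentage_agreement <- function(expert, auto, grouping = NULL,
                                 outlier_threshold = 5) {
  m <- match_pairs(expert, auto, grouping)
  if (nrow(m) < 3) stop("InsufficientData: fewer than 3 matched pairs")
  r <- stats::cor(m$percent_expert, m$percent_auto)
  nz <- !(m$percent_expert == 0 & m$percent_auto == 0)
  r_nz <- if (sum(nz) >= 3) stats::cor(m$percent_expert[nz], m$percent_auto[nz])
          else NA_real_
  diffs <- abs(m$percent_expert - m$percent_auto)
  structure(list(n_pairs = nrow(m), pearson_r = r, pearson_r_nonzero = r_nz,
                 outliers = m[diffs > outlier_threshold, , drop = FALSE],
                 pairs = m), class = "tm_agreement")
}

#' @export
print.tm_agreement <- function(x, ...) {
  cat(sprintf("<tm_agreement> %d pairs, Pearson r = %.3f (%.3f excluding zero-zero), %d outliers\n",
              x$n_pairs, x$pearson_r, x$pearson_r_nonzero, nrow(x$outliers)))
  invisible(x)
}

#' Concordance of sparse connections
#'
#' Counts connection pairs whose expert-based percentage is at or below a
#' threshold and, of those, how many the automated estimate also places at
#' or below it; likewise for connections with no labeled cells at all.
#'
#' @param expert,auto percentage tables as in [percentage_agreement()].
#' @param threshold sparse-connection percentage threshold (default 0.05).
#' @param grouping optional supergroup definition.
#' @return list with `n_expert_sparse`, `n_both_sparse`, `fraction_sparse`,
#'   `n_expert_zero`, `n_auto_zero`, `n_both_zero`, `fraction_zero`.
#' @export
sparse_concordance <- function(expert, auto, threshold = 0.05, grouping = NULL) {
  m <- match_pairs(expert, auto, grouping)
  sp <- m$percent_expert <= threshold
  both <- sp & m$percent_auto <= threshold
  ze <- m$percent_expert == 0
  za <- m$percent_auto == 0
  list(n_pairs = nrow(m),
       n_expert_sparse = sum(sp), n_both_sparse = sum(both),
       fraction_sparse = if (sum(sp)) sum(both) / sum(sp) else 1.0,
       n_expert_zero = sum(ze), n_auto_zero = sum(za),
       n_both_zero = sum(ze & za),
       fraction_zero = if (sum(ze)) sum(ze & za) / sum(ze) else 1.0)
}
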