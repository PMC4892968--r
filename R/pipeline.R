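# End-to-end orchestration: reconstruct a section stack, normalize it to the
# template, assemble the transform chain, and (for phantom studies) score the
# recovery against ground truth.

#' Run the full reconstruction and normalization pipeline
#'
#' Stage 1: iterative affine reconstruction of the stack against the
#' reference. Stage 2: deformable reconstruction toward neighbor averages.
#' Stage 3: affine + deformable coregistration of the reconstructed volume
#' with the template (optionally landmark-guided). The result is a transform
#' chain expressing any section point in template coordinates.
#'
#' @param stack a `tm_stack`.
#' @param template template intensity `tm_volume`.
#' @param landmarks_subject,landmarks_template optional landmark label
#'   `tm_volume`s (subject landmarks in stack space).
#' @param recon_cfg a [reconstruction_config()].
#' @param norm_cfg a [normalization_config()].
#' @return list with `chain` (`tm_chain`), `recon` (deformably reconstructed
#'   volume in stack space), and `diagnostics` (MI/MSD logs, landmark PSE
#'   before and after the deformable stage, final CC).
#' @export
run_pipeline <- function(stack, template, landmarks_subject = NULL,
                         landmarks_template = NULL,
                         recon_cfg = reconstruction_config(),
                         norm_cfg = normalization_config()) {
  ar <- affine_reconstruction(stack, template, recon_cfg)
  dr <- deformable_reconstruction(ar$aligned, stack$in_plane_spacing,
                                  stack$origin2d, recon_cfg)
  recon <- sections_to_volume(stack, dr$warped)
  tpl_geom <- vol_geometry(template)
  recon_tpl <- resample(recon, template, t = ar$affine, interp = "linear")
  lm_subj_tpl <- NULL
  if (!is.null(landmarks_subject))
    lm_subj_tpl <- resample(landmarks_subject, template, t = ar$affine,
                            interp = "nearest")
  nm <- normalize_to_template(recon_tpl, template,
                              landmarks_subject = lm_subj_tpl,
                              landmarks_template = landmarks_template,
                              cfg = norm_cfg)
  chain <- transform_chain(
    per_section = lapply(seq_along(ar$rigids), function(s)
      list(rigid = ar$rigids[[s]], field = dr$fields[[s]])),
    section_positions = section_position(stack, seq_along(stack$sections)),
    reconstruction_affine = ar$affine,
    to_template_affine = nm$affine,
    to_template_field = nm$field)
  list(chain = chain, recon = recon,
       diagnostics = list(mi_log = ar$mi_log, msd_log = dr$msd_log,
                          pse_affine = nm$pse_affine, pse_final = nm$pse_final,
                          cc_final = nm$cc_final))
}

#' Run and score a complete phantom study
#'
#' Generates the phantom (template, distorted stack, planted cells), runs the
#' full pipeline blind to the ground truth, maps the cells, and scores the
#' recovery: injection-center errors against the true deposit centers,
#' the fraction of cells assigned their true area, and the Pearson
#' correlation between recovered and true per-area extrinsic percentages
#' across injections.
#'
#' @param cfg a [phantom_config()].
#' @param recon_cfg,norm_cfg stage configurations.
#' @return list with the phantom, pipeline result, finalized records, and
#'   `scores` (`injection_errors_mm`, `median_injection_error_mm`,
#'   `max_injection_error_mm`, `cell_area_accuracy`, `percentage_r`,
#'   `n_cells`).
#' @export
run_phantom_study <- function(cfg = phantom_config(),
                              recon_cfg = reconstruction_config(),
                              norm_cfg = normalization_config()) {
  ph <- make_phantom(cfg)
  pipe <- run_pipeline(ph$stack, ph$template$intensity,
                       landmarks_subject = ph$landmarks_subject,
                       landmarks_template = ph$template$landmarks,
                       recon_cfg = recon_cfg, norm_cfg = norm_cfg)
  depth <- solve_depth(ph$template$labels, cfg$wm_label)
  fin <- finalize_records(ph$cells, pipe$chain, ph$template$labels, depth,
                          flatmap = function(p) shell_flatmap(p, cfg))
  rec <- fin$records

  # injection-center recovery
  injv <- rec[rec$kind == "injection_voxel", , drop = FALSE]
  keys <- unique(paste(injv$animal, injv$tracer, sep = "/"))
  inj_err <- vapply(keys, function(k) {
    g <- injv[paste(injv$animal, injv$tracer, sep = "/") == k, , drop = FALSE]
    truth <- colMeans(g[, c("true_ml", "true_ap", "true_dv")])
    est <- colMeans(g[, c("ml", "ap", "dv")])
    sqrt(sum((est - truth)^2))
  }, numeric(1))

  cells <- rec[rec$kind == "cell" & rec$assigned, , drop = FALSE]
  acc <- mean(cells$area == cells$true_area)

  # per-injection, per-area extrinsic percentage tables (auto vs truth)
  mk_tab <- function(col) {
    do.call(rbind, lapply(keys, function(k) {
      g <- cells[paste(cells$animal, cells$tracer, sep = "/") == k, , drop = FALSE]
      inj_area <- injv$true_area[paste(injv$animal, injv$tracer, sep = "/") == k][1]
      a <- g[[col]]
      a <- a[a != inj_area]
      cnt <- table(factor(a, levels = seq_len(cfg$n_areas)))
      data.frame(injection = k, area = names(cnt),
                 percent = 100 * as.numeric(cnt) / max(sum(cnt), 1),
                 stringsAsFactors = FALSE)
    }))
  }
  agr <- percentage_agreement(mk_tab("true_area"), mk_tab("area"),
                              outlier_threshold = 5)
  list(phantom = ph, pipeline = pipe, records = fin,
       scores = list(injection_errors_mm = unname(inj_err),
                     median_injection_error_mm = stats::median(inj_err),
                     max_injection_error_mm = max(inj_err),
                     cell_area_accuracy = acc,
                     percentage_r = agr$pearson_r,
                     n_pairs = agr$n_pairs,
                     n_cells = nrow(cells)))
}
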