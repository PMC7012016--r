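# End-to-end orchestration: reference region -> TACs -> model -> outputs,
# with a JSON run report capturing inputs, parameters, output paths and
# warnings for every stage (the file-level stand-in for a centralized
# results archive).

.report_new <- function(cfg, seed) {
  list(version = .pq_version(), seed = seed,
       config = unclass(cfg), stages = list())
}

.report_add <- function(report, stage, info) {
  report$stages[[stage]] <- info
  report
}

.report_write <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

.fit_to_json <- function(fit) {
  list(model = fit$model,
       params = lapply(fit$params, function(p) unname(p)),
       se = fit$se, rss = fit$rss, n_points = fit$n_points,
       t_star_used = fit$t_star_used)
}

# Fit the configured model for one target TAC.
.fit_model <- function(cfg, ct, cr, plasma = NULL) {
  mp <- cfg$model_params
  switch(cfg$model,
    srtm = srtm_fit(ct, cr),
    suvr = suvr(ct, cr, mp$suvr_window),
    logan_ref = logan_ref(ct, cr, mp$t_star, mp$k2prime),
    patlak_ref = patlak_ref(ct, cr, mp$t_star),
    logan_plasma = {
      if (is.null(plasma)) stop("model '", cfg$model, "' requires a plasma input")
      logan_plasma(ct, plasma, mp$t_star)
    },
    patlak_plasma = {
      if (is.null(plasma)) stop("model '", cfg$model, "' requires a plasma input")
      patlak_plasma(ct, plasma, mp$t_star)
    },
    fur = {
      if (is.null(plasma)) stop("model 'fur' requires a plasma input")
      fur(ct, plasma)
    },
    tcm2 = {
      if (is.null(plasma)) stop("model 'tcm2' requires a plasma input")
      tcm2_fit(ct, plasma, seed = cfg$seed)
    })
}

#' Run the full quantification pipeline
#'
#' Generates the automatic reference region, extracts the reference TAC
#' and one TAC per requested ROI, fits the configured kinetic model per
#' ROI, optionally computes voxelwise SRTM parametric maps, materializes
#' every intermediate to `out_dir`, and writes a JSON run report. The run
#' is deterministic given the config seed.
#'
#' @param pet a [dynamic_image()] (or NIfTI path, with `timing`).
#' @param labels a [label_volume()] (or NIfTI path).
#' @param cfg a [tracer_config()].
#' @param roi_codes integer label codes of the target ROIs.
#' @param out_dir output directory (created if missing).
#' @param timing timing file path when `pet` is a path.
#' @param plasma optional [plasma_input()] for plasma-input models.
#' @param parametric also compute SRTM basis-function parametric maps.
#' @return List of class `pipeline_result`: `refregion`
#'   (`refregion_trace`), `ref_tac`, `roi_tacs`, `fits`, `maps` (or NULL),
#'   `report_path`.
#' @export
run_pipeline <- function(pet, labels, cfg, roi_codes, out_dir,
                         timing = NULL, plasma = NULL, parametric = FALSE) {
  stopifnot(inherits(cfg, "tracer_config"))
  if (is.character(pet)) pet <- load_dynamic_image(pet, timing)
  if (is.character(labels)) labels <- load_labels(labels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- .report_new(cfg, cfg$seed)
  warn_log <- character()
  withCallingHandlers({
    trace <- generate_reference_region(labels, pet, cfg)
    write_mask(trace$mask_raw, file.path(out_dir, "refregion_raw.nii.gz"))
    write_mask(trace$mask_anat, file.path(out_dir, "refregion_anat.nii.gz"))
    write_mask(trace$mask_final, file.path(out_dir, "refregion_final.nii.gz"))
    report <- .report_add(report, "refregion", list(
      volumes_ml = as.list(trace$volumes_ml),
      intensity_bounds = trace$intensity_bounds,
      n_excluded_low = trace$n_excluded_low,
      n_excluded_high = trace$n_excluded_high))

    ref_tac <- extract_tac(pet, trace$mask_final)
    write_tac(ref_tac, file.path(out_dir, "ref_tac.tsv"))
    report <- .report_add(report, "reference_tac", list(
      n_frames = length(ref_tac),
      n_nan_dropped = attr(ref_tac, "n_nan_dropped")))

    missing <- setdiff(as.integer(roi_codes), unique(as.vector(labels$voxels)))
    if (length(missing))
      stop("run_pipeline: ROI code(s) absent from label volume: ",
           paste(missing, collapse = ", "))
    roi_tacs <- list(); fits <- list()
    for (code in as.integer(roi_codes)) {
      key <- as.character(code)
      roi_mask <- extract_label_mask(labels, code)
      ct <- extract_tac(pet, roi_mask)
      write_tac(ct, file.path(out_dir, sprintf("roi_%d_tac.tsv", code)))
      roi_tacs[[key]] <- ct
      fits[[key]] <- .fit_model(cfg, ct, ref_tac, plasma)
    }
    report <- .report_add(report, "model", list(
      model = cfg$model, fits = lapply(fits, .fit_to_json)))

    maps <- NULL
    if (parametric) {
      if (cfg$model != "srtm")
        stop("run_pipeline: parametric maps are implemented for the srtm model")
      brain <- voxel_mask(apply(pet$voxels, 1:3, function(v) any(v != 0)),
                          pet$affine)
      maps <- srtm_basis_fit(pet, ref_tac, brain)
      write_parametric_maps(maps, file.path(out_dir, "parametric"))
      report <- .report_add(report, "parametric", list(
        n_fitted = sum(maps$mask$voxels), n_failed = maps$n_failed))
    }
    report$warnings <- warn_log
    report_path <- file.path(out_dir, "run_report.json")
    .report_write(report, report_path)
    structure(list(refregion = trace, ref_tac = ref_tac, roi_tacs = roi_tacs,
                   fits = fits, maps = maps, report_path = report_path),
              class = "pipeline_result")
  }, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' Evaluate operator variability against an automatic result
#'
#' Given per-study automatic reference masks and per-study lists of manual
#' operator masks (with the PET images to extract TACs from), computes the
#' evaluation battery: mean pairwise manual-vs-manual overlap,
#' auto-vs-manual overlap, volume/AUC/outcome ICCs across operators,
#' Pearson r between automatic and manual-mean TACs, and relative bias of
#' the outcome measure. Emits a one-row-per-tracer summary table.
#'
#' @param studies list; one entry per study with elements `pet`
#'   ([dynamic_image()]), `auto_mask` ([voxel_mask()]), `manual_masks`
#'   (list of >= 2 [voxel_mask()]s, same operators in the same order across
#'   studies), and optionally `outcome_fn(tac_ref) -> numeric` computing
#'   the outcome measure from a reference TAC.
#' @param out optional path for the summary TSV.
#' @param tracer tracer name used in the summary row.
#' @return List of class `evaluation_report`.
#' @export
run_evaluation <- function(studies, out = NULL, tracer = "synthetic") {
  if (length(studies) < 2L) stop("run_evaluation: need >= 2 studies")
  n_ops <- unique(vapply(studies, function(s) length(s$manual_masks), 0L))
  if (length(n_ops) != 1L)
    stop("run_evaluation: studies have differing operator counts: ",
         paste(n_ops, collapse = ", "))
  if (n_ops < 2L) stop("run_evaluation: need >= 2 operators")

  study_ids <- names(studies) %||% as.character(seq_along(studies))
  vol <- auc <- outc <- NULL
  pair_overlap <- auto_overlap <- r_tac <- bias <- numeric(0)
  union_mean <- numeric(0)
  for (si in seq_along(studies)) {
    s <- studies[[si]]
    pair_overlap <- c(pair_overlap, pairwise_overlap_summary(s$manual_masks))
    auto_overlap <- c(auto_overlap, mean(vapply(
      s$manual_masks, function(m) spatial_overlap(s$auto_mask, m), 0)))
    union_vox <- Reduce(`|`, lapply(s$manual_masks, `[[`, "voxels"))
    union_tac <- extract_tac(s$pet, voxel_mask(union_vox, s$auto_mask$affine))
    union_mean[study_ids[si]] <- mean(union_tac$value)
    man_tacs <- lapply(s$manual_masks, function(m) extract_tac(s$pet, m))
    auto_tac <- extract_tac(s$pet, s$auto_mask)
    man_mean_tac <- Reduce(`+`, lapply(man_tacs, `[[`, "value")) / n_ops
    r_tac <- c(r_tac, pearson_r(auto_tac$value, man_mean_tac))
    for (oi in seq_len(n_ops)) {
      vol <- rbind(vol, data.frame(study = study_ids[si], operator = oi,
                                   value = sum(s$manual_masks[[oi]]$voxels)))
      auc <- rbind(auc, data.frame(study = study_ids[si], operator = oi,
                                   value = tac_auc(man_tacs[[oi]])))
      if (!is.null(s$outcome_fn))
        outc <- rbind(outc, data.frame(study = study_ids[si], operator = oi,
                                       value = s$outcome_fn(man_tacs[[oi]])))
    }
    if (!is.null(s$outcome_fn)) {
      manual_mean_out <- mean(vapply(man_tacs, s$outcome_fn, 0))
      bias <- c(bias, relative_bias(s$outcome_fn(auto_tac), manual_mean_out))
    }
  }
  vol_tab <- rater_table(vol$study, vol$operator, vol$value)
  auc_tab <- standardize_auc(rater_table(auc$study, auc$operator, auc$value),
                             union_mean)
  icc_safe <- function(tab) {
    if (var(tab$value) < 1e-24) {
      # no variance at all: every component share is ill-defined; by the
      # zero-operator-effect convention the studies are perfectly consistent
      return(structure(list(sigma2_study = 0, sigma2_operator = 0,
                            sigma2_residual = 0, icc_study = 1,
                            icc_operator = 0), class = "variance_components"))
    }
    icc_components(tab)
  }
  icc_vol <- icc_safe(vol_tab)
  icc_auc <- icc_safe(auc_tab)
  icc_out <- if (!is.null(outc))
    icc_safe(rater_table(outc$study, outc$operator, outc$value)) else NULL
  summary_row <- data.frame(
    tracer = tracer,
    overlap_pct = mean(pair_overlap),
    icc_volume = icc_vol$icc_study,
    icc_auc = icc_auc$icc_study,
    icc_outcome = if (!is.null(icc_out)) icc_out$icc_study else NA_real_)
  if (!is.null(out))
    write.table(summary_row, out, sep = "\t", row.names = FALSE, quote = FALSE)
  structure(list(summary = summary_row,
                 pairwise_overlap = pair_overlap,
                 auto_vs_manual_overlap = auto_overlap,
                 icc_volume = icc_vol, icc_auc = icc_auc, icc_outcome = icc_out,
                 pearson_r_tac = r_tac,
                 relative_bias_outcome = if (length(bias)) bias else NULL),
            class = "evaluation_report")
}
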