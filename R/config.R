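# Tracer configuration: which model, which reference region, which
# anatomical correction, and the label codes naming those regions in the
# parcellation. Label codes follow the FreeSurfer color-table convention
# (cerebellar cortex 8/47, lateral ventricles 4/43, aparc occipital parcels
# 1005/1011/1013/1021 and right-hemisphere counterparts) and are fully
# overridable in the config file.

.pq_models <- c("srtm", "suvr", "logan_ref", "patlak_ref",
                "logan_plasma", "patlak_plasma", "fur", "tcm2")
.pq_refregions <- c("cerebellar_cortex", "occipital_cortex")
.pq_corrections <- c("erode", "lateral_cut", "none")

.default_label_codes <- function(reference_region) {
  switch(reference_region,
    cerebellar_cortex = c(8L, 47L),
    occipital_cortex = c(1005L, 1011L, 1013L, 1021L,
                         2005L, 2011L, 2013L, 2021L))
}

#' Construct a validated tracer configuration
#'
#' @param tracer tracer name (free text; see [default_tracer_config()] for
#'   shipped defaults).
#' @param reference_region `"cerebellar_cortex"` or `"occipital_cortex"`.
#' @param model one of `r paste(.pq_models, collapse = ", ")`.
#' @param model_params named list; `suvr` requires `suvr_window` (minutes,
#'   length 2), graphical models require `t_star` (minutes).
#' @param tail_exclusion logical; apply FWHM-based intensity tail exclusion.
#' @param anatomical_correction `"erode"`, `"lateral_cut"` or `"none"`.
#' @param erosion_depth voxels to peel when `anatomical_correction="erode"`.
#' @param label_codes integer label codes of the reference region; defaults
#'   to the FreeSurfer convention for the named region.
#' @param ventricle_codes label codes of the lateral ventricles (used by
#'   `lateral_cut`).
#' @param seed integer seed recorded in run reports.
#' @return Object of class `tracer_config`.
#' @export
tracer_config <- function(tracer, reference_region, model,
                          model_params = list(), tail_exclusion = TRUE,
                          anatomical_correction = "erode",
                          erosion_depth = 1L,
                          label_codes = NULL,
                          ventricle_codes = c(4L, 43L),
                          seed = 1L) {
  if (!model %in% .pq_models)
    stop("tracer_config: unknown model '", model, "'; supported: ",
         paste(.pq_models, collapse = ", "))
  if (!reference_region %in% .pq_refregions)
    stop("tracer_config: unknown reference_region '", reference_region, "'")
  if (!anatomical_correction %in% .pq_corrections)
    stop("tracer_config: unknown anatomical_correction '",
         anatomical_correction, "'")
  if (model == "suvr") {
    w <- model_params$suvr_window
    if (is.null(w) || length(w) != 2L || w[1L] >= w[2L])
      stop("tracer_config: model 'suvr' requires model_params$suvr_window = c(t0, t1) minutes")
  }
  if (model %in% c("logan_ref", "patlak_ref", "logan_plasma", "patlak_plasma")) {
    if (is.null(model_params$t_star))
      stop("tracer_config: graphical model '", model,
           "' requires model_params$t_star (minutes)")
  }
  if (is.null(label_codes)) label_codes <- .default_label_codes(reference_region)
  structure(list(
    tracer = tracer, reference_region = reference_region, model = model,
    model_params = model_params, tail_exclusion = isTRUE(tail_exclusion),
    anatomical_correction = anatomical_correction,
    erosion_depth = as.integer(erosion_depth),
    label_codes = as.integer(label_codes),
    ventricle_codes = as.integer(ventricle_codes),
    seed = as.integer(seed)), class = "tracer_config")
}

#' Default configuration for a supported tracer
#'
#' Shipped defaults: `carfentanil` (mu-opioid) uses SRTM with an occipital
#' reference and the lateral-ventricle cut; `raclopride` (D2) and `madam`
#' (SERT) use SRTM with an eroded cerebellar reference; `pib` (amyloid)
#' uses the 60-90 min SUV ratio with an eroded cerebellar reference. Tail
#' exclusion is on for all.
#'
#' @param tracer one of `"carfentanil"`, `"raclopride"`, `"madam"`, `"pib"`.
#' @return A [tracer_config()].
#' @export
default_tracer_config <- function(tracer) {
  known <- c("carfentanil", "raclopride", "madam", "pib")
  if (!tracer %in% known)
    stop("default_tracer_config: unknown tracer '", tracer,
         "'; supported: ", paste(known, collapse = ", "))
  switch(tracer,
    carfentanil = tracer_config("carfentanil", "occipital_cortex", "srtm",
                                anatomical_correction = "lateral_cut"),
    raclopride = tracer_config("raclopride", "cerebellar_cortex", "srtm",
                               anatomical_correction = "erode"),
    madam = tracer_config("madam", "cerebellar_cortex", "srtm",
                          anatomical_correction = "erode"),
    pib = tracer_config("pib", "cerebellar_cortex", "suvr",
                        model_params = list(suvr_window = c(60, 90)),
                        anatomical_correction = "erode"))
}

.config_keys <- c("tracer", "reference_region", "model", "model_params",
                  "tail_exclusion", "anatomical_correction", "erosion_depth",
                  "label_codes", "ventricle_codes", "seed")

#' Save a tracer configuration (YAML or JSON by extension)
#' @param cfg a [tracer_config()].
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tracer_config"))
  x <- unclass(cfg)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else stop("save_config: extension must be .yaml/.yml/.json")
  invisible(path)
}

#' Load and validate a tracer configuration
#'
#' Unknown keys are rejected (with the offending key path named) so that
#' typos in hand-edited YAML fail loudly instead of silently using a
#' default.
#'
#' @param path `.yaml`/`.yml`/`.json` file written by [save_config()] or by
#'   hand.
#' @return A [tracer_config()].
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("load_config: extension must be .yaml/.yml/.json")
  unknown <- setdiff(names(x), .config_keys)
  if (length(unknown))
    stop("load_config: unknown config key(s): ", paste(unknown, collapse = ", "))
  mp <- x$model_params
  if (is.null(mp)) mp <- list()
  if (!is.null(mp$suvr_window)) mp$suvr_window <- as.numeric(unlist(mp$suvr_window))
  if (!is.null(mp$t_star)) mp$t_star <- as.numeric(mp$t_star)
  known_mp <- c("suvr_window", "t_star", "k2prime")
  bad_mp <- setdiff(names(mp), known_mp)
  if (length(bad_mp))
    stop("load_config: unknown config key(s): ",
         paste(paste0("model_params.", bad_mp), collapse = ", "))
  tracer_config(
    tracer = x$tracer %||% "custom",
    reference_region = x$reference_region,
    model = x$model,
    model_params = mp,
    tail_exclusion = x$tail_exclusion %||% TRUE,
    anatomical_correction = x$anatomical_correction %||% "erode",
    erosion_depth = x$erosion_depth %||% 1L,
    label_codes = x$label_codes,
    ventricle_codes = x$ventricle_codes %||% c(4L, 43L),
    seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
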