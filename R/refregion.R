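# Automatic reference-region generation: anatomical label extraction, an
# anatomical correction (morphological erosion for the cerebellar
# reference, a lateral-ventricle cut for the occipital reference), then
# exclusion of voxels in the tails of the radioactivity distribution, with
# bounds placed at the half-maximum of a kernel density estimate of the
# in-mask mean-PET intensities.

#' Extract the union mask of a set of label codes
#'
#' @param labels a [label_volume()].
#' @param codes non-empty integer vector of label codes.
#' @return A [voxel_mask()] of voxels whose label is in `codes`.
#' @export
extract_label_mask <- function(labels, codes) {
  stopifnot(inherits(labels, "label_volume"))
  if (length(codes) == 0L) stop("extract_label_mask: empty label code set")
  m <- array(labels$voxels %in% as.integer(codes), dim = dim(labels$voxels))
  if (!any(m))
    stop("extract_label_mask: no voxel matches label code(s) ",
         paste(codes, collapse = ", "))
  voxel_mask(m, labels$affine)
}

# One 6-connected erosion pass: a voxel survives iff all 6 face neighbors
# (grid boundary counts as background) and itself are foreground.
.erode_once <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(arr, axis, by) {
    res <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1L) }
    else { idx_dst[[axis]] <- 1:(n - 1L); idx_src[[axis]] <- 2:n }
    res[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
      arr[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
    res
  }
  for (axis in 1:3) for (by in c(1L, -1L)) out <- out & shift(m, axis, by)
  out
}

#' Anatomical correction: peel the outermost voxels of a mask
#'
#' Morphological erosion with a 6-connected structuring element, applied
#' `depth_voxels` times. Used to shave the surface of the cerebellar
#' reference where spill-in from occipital cortex and venous sinuses
#' concentrates.
#'
#' @param mask a [voxel_mask()].
#' @param depth_voxels erosion depth, voxels (>= 1).
#' @return Eroded [voxel_mask()]; always a subset of the input.
#' @export
anat_correct_erode <- function(mask, depth_voxels = 1L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (depth_voxels < 1L) stop("anat_correct_erode: depth_voxels must be >= 1")
  m <- mask$voxels
  for (i in seq_len(depth_voxels)) m <- .erode_once(m)
  if (!any(m))
    stop("anat_correct_erode: erosion emptied the mask; use a smaller depth")
  voxel_mask(m, mask$affine)
}

# World coordinates (mm) of the TRUE voxels of a 3D logical array.
.world_coords <- function(vox, affine) {
  idx <- which(vox, arr.ind = TRUE) - 1  # 0-based voxel indices
  t(affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

#' Anatomical correction: remove voxels lateral to the lateral ventricles
#'
#' Per hemisphere (world left-right axis from the RAS affine; x < 0 left,
#' x > 0 right), mask voxels whose |world x| strictly exceeds the maximum
#' |world x| of that hemisphere's ventricle voxels are removed. Used for
#' the occipital reference, whose lateral parts show specific binding for
#' the mu-opioid tracer.
#'
#' @param mask a [voxel_mask()] to correct.
#' @param ventricles a non-empty [voxel_mask()] of the lateral ventricles on
#'   the same grid.
#' @return Corrected [voxel_mask()].
#' @export
anat_correct_lateral_cut <- function(mask, ventricles) {
  stopifnot(inherits(mask, "voxel_mask"), inherits(ventricles, "voxel_mask"))
  .same_grid(dim(mask$voxels), mask$affine,
             dim(ventricles$voxels), ventricles$affine, "mask and ventricles")
  if (!any(ventricles$voxels))
    stop("anat_correct_lateral_cut: ventricle mask is empty")
  vx <- .world_coords(ventricles$voxels, ventricles$affine)[, 1L]
  lim_global <- max(abs(vx))
  lim_left <- if (any(vx < 0)) max(abs(vx[vx < 0])) else {
    warning("lateral_cut: no ventricle voxels in left hemisphere; using global max |x|")
    lim_global
  }
  lim_right <- if (any(vx > 0)) max(abs(vx[vx > 0])) else {
    warning("lateral_cut: no ventricle voxels in right hemisphere; using global max |x|")
    lim_global
  }
  mw <- .world_coords(mask$voxels, mask$affine)[, 1L]
  keep_flat <- ifelse(mw < 0, abs(mw) <= lim_left, abs(mw) <= lim_right)
  out <- array(FALSE, dim(mask$voxels))
  out[which(mask$voxels)[keep_flat]] <- TRUE
  if (!any(out))
    stop("anat_correct_lateral_cut: correction removed every mask voxel")
  voxel_mask(out, mask$affine)
}

#' Duration-weighted mean PET image
#'
#' Mean over frames weighted by frame duration (an unweighted mean over
#' frames of unequal length would over-represent short early frames).
#'
#' @param image a [dynamic_image()].
#' @return 3D numeric array on the image grid.
#' @export
mean_pet_image <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  dur <- frame_durations(image$schedule)
  w <- dur / sum(dur)
  d <- dim(image$voxels)
  out <- array(0, d[1:3])
  for (f in seq_along(w)) out <- out + w[f] * image$voxels[, , , f]
  out
}

# Shared KDE settings (also used by evalstats for mode/FWHM consistency):
# Gaussian kernel, Silverman bandwidth (bw.nrd0), 512 grid points spanning
# the sample range.
.pq_density <- function(x) stats::density(x, bw = "nrd0", n = 512,
                                          from = min(x), to = max(x))

# Half-max crossing: walking outward from the mode, the first grid point
# where the density drops below half-max; crossing located by linear
# interpolation. NULL if the density never falls below half on that side.
.halfmax_bound <- function(xs, ys, i_mode, half, side) {
  idx <- if (side == "lower") rev(seq_len(i_mode)) else i_mode:length(xs)
  below <- which(ys[idx] < half)
  if (length(below) == 0L) return(NULL)
  j <- below[1L]
  i1 <- idx[j - 1L]; i2 <- idx[j]  # density crosses half between i1 and i2
  xs[i1] + (xs[i2] - xs[i1]) * (half - ys[i1]) / (ys[i2] - ys[i1])
}

#' Radioactivity tail exclusion
#'
#' Estimates the distribution of in-mask mean-PET intensities with a kernel
#' density estimate, locates its mode and the intensities at which the
#' density first falls to half of its modal value on each side (the FWHM
#' bounds), and keeps only voxels inside the closed interval
#' `[lower, upper]`. Voxels outside — atypically cold (e.g. CSF) or hot
#' (e.g. spill-in from adjacent high-binding tissue) — are excluded.
#'
#' @param mask a [voxel_mask()]; if it holds fewer than `min_voxels` voxels
#'   the step is skipped with a warning and the input returned unchanged.
#' @param mean_pet 3D array of duration-weighted mean PET intensities (see
#'   [mean_pet_image()]).
#' @param min_voxels minimum mask size to attempt the KDE (default 100).
#' @return List with `mask` ([voxel_mask()]), `bounds` (lower, upper),
#'   `n_excluded_low`, `n_excluded_high`.
#' @export
tail_exclusion <- function(mask, mean_pet, min_voxels = 100L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!all(dim(mean_pet) == dim(mask$voxels)))
    stop("tail_exclusion: mean_pet grid does not match mask")
  idx <- which(mask$voxels)
  vals <- mean_pet[idx]
  if (length(idx) < min_voxels) {
    warning(sprintf("tail_exclusion: mask has %d voxels (< %d); skipping",
                    length(idx), min_voxels))
    return(list(mask = mask, bounds = range(vals),
                n_excluded_low = 0L, n_excluded_high = 0L))
  }
  if (diff(range(vals)) < .Machine$double.eps^0.5) {
    # constant intensity: degenerate bounds, nothing to exclude
    return(list(mask = mask, bounds = c(vals[1L], vals[1L]),
                n_excluded_low = 0L, n_excluded_high = 0L))
  }
  dens <- .pq_density(vals)
  i_mode <- which.max(dens$y)
  half <- dens$y[i_mode] / 2
  lo <- .halfmax_bound(dens$x, dens$y, i_mode, half, "lower")
  hi <- .halfmax_bound(dens$x, dens$y, i_mode, half, "upper")
  if (is.null(lo)) {
    warning("tail_exclusion: no lower half-max crossing; using distribution minimum")
    lo <- min(vals)
  }
  if (is.null(hi)) {
    warning("tail_exclusion: no upper half-max crossing; using distribution maximum")
    hi <- max(vals)
  }
  keep <- vals >= lo & vals <= hi  # ties at the bound are kept
  out <- array(FALSE, dim(mask$voxels))
  out[idx[keep]] <- TRUE
  list(mask = voxel_mask(out, mask$affine), bounds = c(lo, hi),
       n_excluded_low = sum(vals < lo), n_excluded_high = sum(vals > hi))
}

.mask_volume_ml <- function(mask) {
  sum(mask$voxels) * abs(det(mask$affine[1:3, 1:3])) / 1000
}

#' Generate the automatic reference region
#'
#' Chains the three stages of reference-region generation: label-code
#' extraction from the anatomical parcellation, the configured anatomical
#' correction (erosion for the cerebellar reference, ventricle-based
#' lateral cut for the occipital reference, or none), and FWHM tail
#' exclusion on the duration-weighted mean PET image.
#'
#' @param labels a [label_volume()] on the PET grid (a label volume on a
#'   different grid is rejected, not resampled).
#' @param pet a [dynamic_image()].
#' @param cfg a [tracer_config()].
#' @return Object of class `refregion_trace`: `mask_raw`, `mask_anat`,
#'   `mask_final` ([voxel_mask()]s), per-stage `volumes_ml`,
#'   `intensity_bounds`, `n_excluded_low`, `n_excluded_high`.
#' @export
generate_reference_region <- function(labels, pet, cfg) {
  stopifnot(inherits(labels, "label_volume"), inherits(pet, "dynamic_image"),
            inherits(cfg, "tracer_config"))
  .same_grid(dim(labels$voxels), labels$affine,
             dim(pet$voxels)[1:3], pet$affine, "labels and PET")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("reference region stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  mask_raw <- stage("label_extraction",
                    extract_label_mask(labels, cfg$label_codes))
  mask_anat <- stage("anatomical_correction", switch(cfg$anatomical_correction,
    erode = anat_correct_erode(mask_raw, cfg$erosion_depth),
    lateral_cut = anat_correct_lateral_cut(
      mask_raw, extract_label_mask(labels, cfg$ventricle_codes)),
    none = mask_raw))
  if (cfg$tail_exclusion) {
    te <- stage("tail_exclusion",
                tail_exclusion(mask_anat, mean_pet_image(pet)))
    mask_final <- te$mask
    bounds <- te$bounds
    n_lo <- te$n_excluded_low; n_hi <- te$n_excluded_high
  } else {
    mask_final <- mask_anat
    bounds <- c(NA_real_, NA_real_)
    n_lo <- 0L; n_hi <- 0L
  }
  structure(list(
    mask_raw = mask_raw, mask_anat = mask_anat, mask_final = mask_final,
    volumes_ml = c(raw = .mask_volume_ml(mask_raw),
                   anat = .mask_volume_ml(mask_anat),
                   final = .mask_volume_ml(mask_final)),
    intensity_bounds = bounds,
    n_excluded_low = n_lo, n_excluded_high = n_hi),
    class = "refregion_trace")
}
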