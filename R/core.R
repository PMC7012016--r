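#' Frame schedule of a dynamic PET acquisition
#'
#' Stores per-frame start and end times in seconds. Frames must be sorted,
#' non-overlapping (gaps allowed) and strictly positive in duration.
#'
#' @param start_s numeric vector of frame start times, seconds.
#' @param end_s numeric vector of frame end times, seconds.
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(start_s, end_s) {
  if (length(start_s) < 1L || length(start_s) != length(end_s))
    stop("frame_schedule: start_s and end_s must have equal length >= 1")
  if (!all(is.finite(start_s)) || !all(is.finite(end_s)))
    stop("frame_schedule: frame times must be finite")
  if (any(end_s <= start_s))
    stop("frame_schedule: frame_end must exceed frame_start for every frame")
  if (is.unsorted(start_s, strictly = TRUE) && length(start_s) > 1L)
    stop("frame_schedule: frames must be sorted by start time")
  n <- length(start_s)
  if (n > 1L && any(end_s[-n] > start_s[-1L] + 1e-9))
    stop("frame_schedule: frames overlap (end_i must be <= start_{i+1})")
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s)),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start_s)

#' Frame mid-times in minutes
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame midpoints `(start + end) / 2`, minutes.
#' @export
frame_midtimes <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$start_s + schedule$end_s) / 2 / 60
}

#' Frame durations in minutes
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame durations, minutes.
#' @export
frame_durations <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$end_s - schedule$start_s) / 60
}

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be invertible")
  storage.mode(affine) <- "double"
  affine
}

#' 4D dynamic PET image
#'
#' Radioactivity concentration volume (kBq/ml, decay-corrected) with a
#' voxel-to-world affine (mm, RAS) and a frame schedule. The 4th array
#' dimension must equal the number of frames.
#'
#' @param voxels 4D numeric array `(x, y, z, frame)`.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices to mm, RAS).
#' @param schedule a [frame_schedule()].
#' @return Object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, affine, schedule) {
  if (length(dim(voxels)) != 4L)
    stop("dynamic_image: voxels must be a 4D array")
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4L] != length(schedule))
    stop(sprintf("dynamic_image: 4th dimension (%d) != number of frames (%d)",
                 dim(voxels)[4L], length(schedule)))
  affine <- .check_affine(affine)
  structure(list(voxels = voxels, affine = affine, schedule = schedule),
            class = "dynamic_image")
}

#' Binary voxel mask on an image grid
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @param affine 4x4 voxel-to-world matrix, same convention as
#'   [dynamic_image()].
#' @return Object of class `voxel_mask`.
#' @export
voxel_mask <- function(voxels, affine) {
  if (length(dim(voxels)) != 3L)
    stop("voxel_mask: voxels must be a 3D array")
  v <- array(as.logical(voxels), dim = dim(voxels))
  if (anyNA(v)) stop("voxel_mask: mask values must be 0/1 without NA")
  structure(list(voxels = v, affine = .check_affine(affine)),
            class = "voxel_mask")
}

#' Integer anatomical label volume
#'
#' Parcellation sharing the PET grid; label codes follow the FreeSurfer
#' color-table convention unless overridden in the configuration.
#'
#' @param voxels 3D integer array of label codes.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(voxels, affine) {
  if (length(dim(voxels)) != 3L)
    stop("label_volume: voxels must be a 3D array")
  v <- array(as.integer(round(voxels)), dim = dim(voxels))
  structure(list(voxels = v, affine = .check_affine(affine)),
            class = "label_volume")
}

#' Injected dose and body mass of a subject
#'
#' @param injected_dose_MBq total injected dose, MBq (> 0).
#' @param body_mass_kg body mass, kg (> 0).
#' @return Object of class `subject_dose`.
#' @export
subject_dose <- function(injected_dose_MBq, body_mass_kg) {
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("subject_dose: injected_dose_MBq must be > 0")
  if (!is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("subject_dose: body_mass_kg must be > 0")
  structure(list(injected_dose_MBq = injected_dose_MBq,
                 body_mass_kg = body_mass_kg),
            class = "subject_dose")
}

#' Time-activity curve
#'
#' Regional mean activity per frame, tagged with its unit.
#'
#' @param t_mid frame mid-times, minutes, strictly increasing.
#' @param value activity per frame.
#' @param unit `"kBq/ml"` or `"SUV g/ml"`.
#' @param frame_dur frame durations, minutes.
#' @return Object of class `tac`.
#' @export
tac <- function(t_mid, value, unit = c("kBq/ml", "SUV g/ml"), frame_dur) {
  unit <- match.arg(unit)
  if (length(t_mid) != length(value) || length(t_mid) != length(frame_dur))
    stop("tac: t_mid, value and frame_dur must have equal length")
  if (length(t_mid) > 1L && any(diff(t_mid) <= 0))
    stop("tac: t_mid must be strictly increasing")
  structure(list(t_mid = as.numeric(t_mid), value = as.numeric(value),
                 unit = unit, frame_dur = as.numeric(frame_dur)),
            class = "tac")
}

#' @export
length.tac <- function(x) length(x$t_mid)

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames, %.2f-%.2f min, unit %s\n",
              length(x), x$t_mid[1L], x$t_mid[length(x)], x$unit))
  invisible(x)
}

# Grid compatibility: shapes exact, affines to tolerance 1e-4.
.same_grid <- function(a_dim, a_aff, b_dim, b_aff, what = "inputs") {
  if (!all(a_dim == b_dim))
    stop(sprintf("grid mismatch between %s: shapes (%s) vs (%s)", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  if (max(abs(a_aff - b_aff)) > 1e-4)
    stop(sprintf("grid mismatch between %s: affines differ by %.3g (tol 1e-4)",
                 what, max(abs(a_aff - b_aff))))
  invisible(TRUE)
}

#' Extract a regional time-activity curve
#'
#' Per frame, the arithmetic mean of voxel values inside the mask. NaN
#' voxels (allowed only outside the brain in the inputs) are dropped
#' per-frame; the dropped count is reported as an attribute.
#'
#' @param image a [dynamic_image()] in kBq/ml.
#' @param mask a non-empty [voxel_mask()] on the same grid.
#' @return A [tac()] in kBq/ml, with attribute `n_nan_dropped`.
#' @export
extract_tac <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"), inherits(mask, "voxel_mask"))
  .same_grid(dim(image$voxels)[1:3], image$affine,
             dim(mask$voxels), mask$affine, "image and mask")
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("extract_tac: mask is empty")
  nf <- length(image$schedule)
  nvox <- prod(dim(image$voxels)[1:3])
  vals <- numeric(nf)
  n_nan <- 0L
  for (f in seq_len(nf)) {
    v <- image$voxels[idx + (f - 1L) * nvox]
    bad <- !is.finite(v)
    if (all(bad))
      stop(sprintf("extract_tac: all mask voxels are NaN in frame %d", f))
    n_nan <- n_nan + sum(bad)
    vals[f] <- mean(v[!bad])
  }
  out <- tac(frame_midtimes(image$schedule), vals, "kBq/ml",
             frame_durations(image$schedule))
  attr(out, "n_nan_dropped") <- n_nan
  out
}

#' Convert activity to standardized uptake value (SUV)
#'
#' SUV (g/ml) = activity (kBq/ml) x body mass (kg) / injected dose (MBq).
#' The MBq/kg = kBq/g identity makes the ratio dimensionally a tissue
#' density. Refuses to convert an input already in SUV.
#'
#' @param x a [tac()] or [dynamic_image()] in kBq/ml.
#' @param dose a [subject_dose()].
#' @return Same type as `x`, values scaled, unit `"SUV g/ml"` for TACs.
#' @export
to_suv <- function(x, dose) {
  stopifnot(inherits(dose, "subject_dose"))
  fac <- dose$body_mass_kg / dose$injected_dose_MBq
  if (inherits(x, "tac")) {
    if (x$unit == "SUV g/ml")
      stop("to_suv: input is already in SUV units")
    return(tac(x$t_mid, x$value * fac, "SUV g/ml", x$frame_dur))
  }
  if (inherits(x, "dynamic_image")) {
    if (isTRUE(attr(x, "unit") == "SUV g/ml"))
      stop("to_suv: input is already in SUV units")
    out <- dynamic_image(x$voxels * fac, x$affine, x$schedule)
    attr(out, "unit") <- "SUV g/ml"
    return(out)
  }
  stop("to_suv: x must be a tac or dynamic_image")
}

# Cumulative trapezoidal integral of y over x, anchored at 0 at x[1].
.cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-n] + y[-1L]) / 2))
}

#' Area under a time-activity curve
#'
#' Trapezoidal integral over the TAC mid-times, optionally restricted to a
#' window whose endpoints are linearly interpolated when they fall between
#' samples.
#'
#' @param tac a [tac()].
#' @param window `NULL` for the full sampled range, else `c(t0, t1)` minutes
#'   with `t0 < t1`, both inside `[first, last]` mid-time.
#' @return Scalar integral, activity x min.
#' @export
tac_auc <- function(tac, window = NULL) {
  stopifnot(inherits(tac, "tac"))
  t <- tac$t_mid; v <- tac$value
  if (length(t) < 2L) stop("tac_auc: need at least 2 frames")
  if (is.null(window)) window <- c(t[1L], t[length(t)])
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("tac_auc: window must be c(t0, t1) with t0 < t1")
  if (window[1L] < t[1L] - 1e-9 || window[2L] > t[length(t)] + 1e-9)
    stop(sprintf("tac_auc: window [%g, %g] outside sampled range [%g, %g]",
                 window[1L], window[2L], t[1L], t[length(t)]))
  window <- pmin(pmax(window, t[1L]), t[length(t)])
  inside <- t > window[1L] & t < window[2L]
  xs <- c(window[1L], t[inside], window[2L])
  ys <- approx(t, v, xout = xs)$y
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Per-frame fitting weights
#'
#' @param schedule a [frame_schedule()].
#' @param tac a [tac()] (used by the `duration_over_activity` scheme).
#' @param scheme `"uniform"`, `"duration"`, or `"duration_over_activity"`.
#' @return Weights normalized to sum to the number of frames.
#' @export
weights_from_frames <- function(schedule, tac = NULL,
                                scheme = c("uniform", "duration",
                                           "duration_over_activity")) {
  scheme <- match.arg(scheme)
  dur <- frame_durations(schedule)
  n <- length(dur)
  w <- switch(scheme,
    uniform = rep(1, n),
    duration = dur,
    duration_over_activity = {
      stopifnot(inherits(tac, "tac"))
      a <- tac$value
      if (any(a <= 0)) {
        warning("weights_from_frames: nonpositive-activity frames; using duration-only weight there")
        wda <- dur
        ok <- a > 0
        wda[ok] <- dur[ok] / a[ok]
        wda
      } else dur / a
    })
  w * n / sum(w)
}
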