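# Ground-truth generator: triexponential bolus plasma input, forward
# kinetic models (frame-averaged to emulate scanner binning), 4D phantoms
# with a label geometry (reference sphere, target spheres, ventricle-proxy
# boxes), frame-duration-scaled Gaussian noise, and simulated multi-
# operator manual reference masks.

#' Triexponential bolus input model parameters
#'
#' `C_p(t) = (A1 (t - tau) - A2 - A3) e^{lam1 (t - tau)} +
#' A2 e^{lam2 (t - tau)} + A3 e^{lam3 (t - tau)}` for `t > tau`, else 0.
#' Defaults are the classic bolus-injection parameterisation widely used
#' for simulating arterial input functions.
#'
#' @param A1 kBq/ml/min; `A2`, `A3` kBq/ml; `lam1 < lam2 < lam3 < 0` 1/min;
#'   `tau` appearance delay, min.
#' @param A2,A3,lam1,lam2,lam3,tau see above.
#' @return Object of class `input_model_params`.
#' @export
input_model_params <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                               lam1 = -4.1339, lam2 = -0.1191,
                               lam3 = -0.0104, tau = 0.7) {
  if (!(lam1 < lam2 && lam2 < lam3 && lam3 < 0))
    stop("input_model_params: need lam1 < lam2 < lam3 < 0")
  structure(list(A1 = A1, A2 = A2, A3 = A3, lam1 = lam1, lam2 = lam2,
                 lam3 = lam3, tau = tau), class = "input_model_params")
}

#' Evaluate the bolus input model on a time grid
#'
#' @param params an [input_model_params()].
#' @param t minutes; must start at 0 and be strictly increasing.
#' @return A [plasma_input()].
#' @export
plasma_curve <- function(params, t) {
  stopifnot(inherits(params, "input_model_params"))
  s <- t - params$tau
  cp <- ifelse(s <= 0, 0,
               (params$A1 * s - params$A2 - params$A3) * exp(params$lam1 * s) +
                 params$A2 * exp(params$lam2 * s) +
                 params$A3 * exp(params$lam3 * s))
  if (any(cp < -1e-9))
    stop("plasma_curve: parameters produce negative plasma activity")
  plasma_input(t, pmax(cp, 0))
}

# Forward models on the fine grid; public wrappers frame-average.
.forward_2tcm_fine <- function(plasma, K1, k2, k3, k4, tf) {
  cpf <- .interp_fine(plasma$t, plasma$cp, tf)
  ir <- .tcm2_impulse(K1, k2, k3, k4)
  ir$phi[1L] * .exp_conv(cpf, .pq_fine_dt, ir$a[1L]) +
    ir$phi[2L] * .exp_conv(cpf, .pq_fine_dt, ir$a[2L])
}

.forward_1tcm_fine <- function(plasma, K1, k2, tf) {
  cpf <- .interp_fine(plasma$t, plasma$cp, tf)
  K1 * .exp_conv(cpf, .pq_fine_dt, k2)
}

.schedule_tac <- function(yf, tf, schedule, sampling) {
  s <- schedule$start_s / 60; e <- schedule$end_s / 60
  vals <- if (sampling == "average") .frame_average(tf, yf, s, e)
          else .sample_at(tf, yf, (s + e) / 2)
  tac((s + e) / 2, vals, "kBq/ml", e - s)
}

#' Forward one-tissue compartment model
#'
#' `dC_T/dt = K1 C_p - k2 C_T`, solved by exact piecewise-linear
#' convolution on a fine grid and averaged over each frame interval
#' (emulating scanner integration).
#'
#' @param plasma a [plasma_input()].
#' @param K1 ml/cm3/min; `k2` 1/min (both >= 0).
#' @param k2 see above.
#' @param schedule a [frame_schedule()].
#' @param sampling `"average"` (default, scanner-like) or `"midpoint"`.
#' @return A [tac()] in kBq/ml.
#' @export
forward_1tcm <- function(plasma, K1, k2, schedule,
                         sampling = c("average", "midpoint")) {
  sampling <- match.arg(sampling)
  if (K1 < 0 || k2 < 0) stop("forward_1tcm: rates must be >= 0")
  tf <- .fine_grid(schedule$end_s[length(schedule)] / 60)
  .schedule_tac(.forward_1tcm_fine(plasma, K1, k2, tf), tf, schedule, sampling)
}

#' Forward two-tissue compartment model
#'
#' Analytic biexponential impulse response convolved with the plasma
#' input; reduces exactly to the one-tissue model when `k3 = k4 = 0`.
#'
#' @param plasma a [plasma_input()].
#' @param K1,k2,k3,k4 rate constants (>= 0).
#' @param schedule a [frame_schedule()].
#' @param sampling `"average"` or `"midpoint"`.
#' @return A [tac()] in kBq/ml.
#' @export
forward_2tcm <- function(plasma, K1, k2, k3, k4, schedule,
                         sampling = c("average", "midpoint")) {
  sampling <- match.arg(sampling)
  if (any(c(K1, k2, k3, k4) < 0)) stop("forward_2tcm: rates must be >= 0")
  tf <- .fine_grid(schedule$end_s[length(schedule)] / 60)
  .schedule_tac(.forward_2tcm_fine(plasma, K1, k2, k3, k4, tf), tf,
                schedule, sampling)
}

#' Forward simplified reference tissue model
#'
#' `C_T = R1 C_R + (k2 - R1 k2a) C_R (x) exp(-k2a t)` with
#' `k2a = k2/(1+BP_ND)`, evaluated on the fine grid from the supplied
#' reference curve and frame-averaged.
#'
#' @param cr reference [tac()] covering the schedule.
#' @param R1,k2,BP_ND SRTM parameters.
#' @param schedule a [frame_schedule()].
#' @param sampling `"average"` or `"midpoint"`.
#' @return A [tac()] in the unit of `cr`.
#' @export
forward_srtm <- function(cr, R1, k2, BP_ND, schedule,
                         sampling = c("average", "midpoint")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(cr, "tac"))
  tf <- .fine_grid(schedule$end_s[length(schedule)] / 60)
  crf <- .interp_fine(cr$t_mid, cr$value, tf)
  k2a <- k2 / (1 + BP_ND)
  conv_tac <- .schedule_tac(.exp_conv(crf, .pq_fine_dt, k2a), tf, schedule,
                            sampling)
  # the R1 term is instantaneous: the reference frame values already are
  # the frame-domain representation of C_R, so they enter directly (the
  # same operational discretization the SRTM fit uses)
  vals <- R1 * cr$value + (k2 - R1 * k2a) * conv_tac$value
  tac(conv_tac$t_mid, vals, cr$unit, conv_tac$frame_dur)
}

#' Region kinetics specification for the phantom
#'
#' @param label integer label code of the region.
#' @param model `"srtm"`, `"1tcm"` or `"2tcm"`.
#' @param params named list of the model's true parameters.
#' @return Object of class `region_kinetics`.
#' @export
region_kinetics <- function(label, model = c("srtm", "1tcm", "2tcm"), params) {
  model <- match.arg(model)
  need <- switch(model, srtm = c("R1", "k2", "BP_ND"),
                 `1tcm` = c("K1", "k2"), `2tcm` = c("K1", "k2", "k3", "k4"))
  if (!all(need %in% names(params)))
    stop("region_kinetics: model '", model, "' needs params ",
         paste(need, collapse = ", "))
  structure(list(label = as.integer(label), model = model, params = params),
            class = "region_kinetics")
}

#' Default dynamic-PET frame schedule
#'
#' 97 min in 33 frames: 4 x 15 s, 2 x 30 s, 4 x 60 s, 4 x 120 s, 6 x 180 s,
#' 13 x 300 s. Short early frames track the bolus peak closely enough that
#' frame-interval averages and midpoint samples agree to < 0.5%.
#'
#' @return A [frame_schedule()].
#' @export
default_schedule <- function() {
  dur <- c(rep(15, 4), rep(30, 2), rep(60, 4), rep(120, 4), rep(180, 6),
           rep(300, 13))
  ends <- cumsum(dur)
  frame_schedule(c(0, head(ends, -1)), ends)
}

#' Phantom geometry and acquisition specification
#'
#' Default geometry: a 40x40x40 grid of 2 mm voxels (world origin at the
#' grid center, RAS) holding a reference-region sphere (label 8), two
#' target spheres (17, 18), and two ventricle-proxy boxes (4, 43) used by
#' lateral-cut tests.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_mm isotropic voxel size, mm.
#' @param regions list of region geometries; each a list with `label`,
#'   `shape` (`"sphere"`/`"box"`), `center_mm`, and `radius_mm` (sphere) or
#'   `half_mm` (box half-widths).
#' @param schedule a [frame_schedule()].
#' @param noise `list(type = "none")` or `list(type = "gaussian", scale = s)`;
#'   noise sd per voxel-frame is `s * sqrt(C / dt_frame)`.
#' @param seed integer seed (mandatory when noise is not `"none"`).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L), voxel_mm = 2,
                         regions = NULL, schedule = default_schedule(),
                         noise = list(type = "none"), seed = NULL) {
  if (is.null(regions)) {
    regions <- list(
      list(label = 8L, shape = "sphere", center_mm = c(0, -15, -10), radius_mm = 14),
      list(label = 17L, shape = "sphere", center_mm = c(-23, 14, 0), radius_mm = 8),
      list(label = 18L, shape = "sphere", center_mm = c(23, 14, 0), radius_mm = 8),
      list(label = 4L, shape = "box", center_mm = c(-8, 5, 14), half_mm = c(5, 9, 7)),
      list(label = 43L, shape = "box", center_mm = c(8, 5, 14), half_mm = c(5, 9, 7)))
  }
  if (noise$type != "none" && is.null(seed))
    stop("phantom_spec: seed is mandatory when noise is enabled")
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 regions = regions, schedule = schedule, noise = noise,
                 seed = seed), class = "phantom_spec")
}

# Centered RAS affine for the phantom grid.
.phantom_affine <- function(grid_shape, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  aff
}

.rasterize_regions <- function(spec) {
  d <- spec$grid_shape
  aff <- .phantom_affine(d, spec$voxel_mm)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  world <- t(aff %*% t(cbind(idx, 1)))[, 1:3]
  lab <- integer(prod(d))
  for (r in spec$regions) {
    inside <- if (r$shape == "sphere") {
      rowSums(sweep(world, 2, r$center_mm)^2) <= r$radius_mm^2
    } else {
      abs(world[, 1] - r$center_mm[1]) <= r$half_mm[1] &
        abs(world[, 2] - r$center_mm[2]) <= r$half_mm[2] &
        abs(world[, 3] - r$center_mm[3]) <= r$half_mm[3]
    }
    if (any(lab[inside] != 0L))
      stop("phantom regions overlap (label ", r$label, ")")
    lab[inside] <- r$label
  }
  list(labels = array(lab, d), affine = aff)
}

#' Build a ground-truth 4D phantom
#'
#' Rasterizes the region geometry, generates the reference-region TAC from
#' its kinetic model, generates each target region's TAC (SRTM targets use
#' the reference fine-grid curve; compartment models use the plasma
#' input), fills every in-region voxel with its region TAC (frame
#' averages), adds seeded Gaussian noise with per-voxel-frame sd
#' `scale * sqrt(C / dt_frame)`, and returns the image together with the
#' label volume, plasma input and full ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param ref_kinetics a [region_kinetics()] for the reference region
#'   (model `"1tcm"` or `"2tcm"`).
#' @param targets list of [region_kinetics()] for target regions.
#' @param input an [input_model_params()].
#' @return List with `image` ([dynamic_image()]), `labels`
#'   ([label_volume()]), `plasma` ([plasma_input()]), `truth` (per-region
#'   noiseless TACs and parameters, keyed by label).
#' @export
build_phantom <- function(spec, ref_kinetics, targets = list(),
                          input = input_model_params()) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(ref_kinetics, "region_kinetics"))
  if (ref_kinetics$model == "srtm")
    stop("build_phantom: the reference region cannot itself be SRTM-based")
  ras <- .rasterize_regions(spec)
  sched <- spec$schedule
  t_end <- sched$end_s[length(sched)] / 60
  tf <- .fine_grid(t_end)
  plasma <- plasma_curve(input, tf)

  fine_for <- function(rk, ref_fine) {
    p <- rk$params
    switch(rk$model,
      `1tcm` = .forward_1tcm_fine(plasma, p$K1, p$k2, tf),
      `2tcm` = .forward_2tcm_fine(plasma, p$K1, p$k2, p$k3, p$k4, tf),
      srtm = {
        k2a <- p$k2 / (1 + p$BP_ND)
        p$R1 * ref_fine + (p$k2 - p$R1 * k2a) * .exp_conv(ref_fine, .pq_fine_dt, k2a)
      })
  }
  ref_fine <- fine_for(ref_kinetics, NULL)
  region_list <- c(list(ref_kinetics), targets)
  truth <- list()
  d <- spec$grid_shape
  nf <- length(sched)
  vox <- array(0, c(d, nf))
  dur_min <- frame_durations(sched)
  for (rk in region_list) {
    yf <- if (rk$label == ref_kinetics$label) ref_fine else fine_for(rk, ref_fine)
    tc <- .schedule_tac(yf, tf, sched, "average")
    truth[[as.character(rk$label)]] <- list(model = rk$model,
                                            params = rk$params, tac = tc)
    idx <- which(ras$labels == rk$label)
    for (f in seq_len(nf)) vox[idx + (f - 1L) * prod(d)] <- tc$value[f]
  }
  if (spec$noise$type == "gaussian") {
    vox <- .with_seed(spec$seed, {
      for (f in seq_len(nf)) {
        sl <- vox[, , , f]
        sdv <- spec$noise$scale * sqrt(pmax(sl, 0) / dur_min[f])
        nz <- sdv > 0
        sl[nz] <- sl[nz] + rnorm(sum(nz), 0, sdv[nz])
        vox[, , , f] <- sl
      }
      vox
    })
  }
  list(image = dynamic_image(vox, ras$affine, sched),
       labels = label_volume(ras$labels, ras$affine),
       plasma = plasma, truth = truth,
       reference_label = ref_kinetics$label)
}

# 6-connected dilation (dual of .erode_once).
.dilate_once <- function(m) !.erode_once(!m)

#' Simulate manual operator reference masks
#'
#' Emulates the manual protocol of drawing the reference on a few
#' consecutive transaxial slices: each operator's mask is `slice_count`
#' consecutive z-slices chosen with seeded jitter around the region's
#' central slice, intersected with the true region eroded or dilated by a
#' seeded per-operator margin.
#'
#' @param true_region a [voxel_mask()]; must span more than `slice_count`
#'   transaxial slices.
#' @param n_operators number of simulated operators.
#' @param slice_count slices per mask (default 3).
#' @param jitter `list(slice_sd = , margin = )`: sd (slices) of the window
#'   jitter and max absolute erosion/dilation margin (voxels).
#' @param seed integer seed.
#' @return List of `n_operators` non-empty [voxel_mask()]s.
#' @export
simulate_operator_masks <- function(true_region, n_operators, slice_count = 3L,
                                    jitter = list(slice_sd = 1, margin = 1L),
                                    seed = 1L) {
  stopifnot(inherits(true_region, "voxel_mask"))
  zs <- which(apply(true_region$voxels, 3, any))
  if (length(zs) <= slice_count)
    stop(sprintf("simulate_operator_masks: region spans %d slices (need > %d)",
                 length(zs), slice_count))
  z_center <- round(mean(range(zs)))
  half <- (slice_count - 1L) %/% 2L
  .with_seed(seed, {
    lapply(seq_len(n_operators), function(i) {
      off <- if (jitter$slice_sd > 0) round(rnorm(1, 0, jitter$slice_sd)) else 0L
      z0 <- z_center + off - half
      # clamp the window into the region's z-span so all slices are populated
      z0 <- min(max(z0, min(zs)), max(zs) - slice_count + 1L)
      zwin <- z0:(z0 + slice_count - 1L)
      margin <- if (jitter$margin > 0)
        sample(seq(-jitter$margin, jitter$margin), 1L) else 0L
      base <- true_region$voxels
      if (margin < 0) for (k in seq_len(-margin)) base <- .erode_once(base)
      if (margin > 0) for (k in seq_len(margin)) base <- .dilate_once(base)
      m <- array(FALSE, dim(base))
      m[, , zwin] <- base[, , zwin]
      # margin-eroded slices can empty out near the poles; back-fill from
      # the true region so every window slice is populated
      for (z in zwin) if (!any(m[, , z])) m[, , z] <- true_region$voxels[, , z]
      if (!any(m)) stop("simulate_operator_masks: produced an empty mask")
      voxel_mask(m, true_region$affine)
    })
  })
}
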