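# Voxelwise SRTM via the basis-function method: for each candidate k2a on
# a fixed log-spaced grid, the model is linear in (R1, phi) with bases
# {C_R, C_R (x) exp(-k2a t)}, so every voxel is a 2-parameter linear
# least-squares solved for all voxels at once; the k2a minimizing the
# residual sum of squares wins.

#' Default log-spaced k2a basis grid
#'
#' @param n number of grid points (default 64).
#' @param range `c(min, max)` in 1/min (default `c(0.006, 0.6)`).
#' @return Numeric vector of k2a values.
#' @export
srtm_basis_grid <- function(n = 64L, range = c(0.006, 0.6)) {
  exp(seq(log(range[1L]), log(range[2L]), length.out = n))
}

#' Voxelwise SRTM by basis functions
#'
#' @param image a [dynamic_image()].
#' @param cr reference [tac()] on the image's frame grid.
#' @param brain_mask [voxel_mask()] of voxels to fit.
#' @param basis k2a grid, 1/min (see [srtm_basis_grid()]).
#' @return Object of class `parametric_maps`: 3D arrays `bp`, `r1`, `k2`
#'   (NaN outside the mask and at failed voxels), the fitted-voxel `mask`,
#'   and `n_failed`.
#' @export
srtm_basis_fit <- function(image, cr, brain_mask, basis = srtm_basis_grid()) {
  stopifnot(inherits(image, "dynamic_image"), inherits(cr, "tac"),
            inherits(brain_mask, "voxel_mask"))
  .same_grid(dim(image$voxels)[1:3], image$affine,
             dim(brain_mask$voxels), brain_mask$affine, "image and brain mask")
  t_mid <- frame_midtimes(image$schedule)
  if (length(cr) != length(t_mid) || max(abs(cr$t_mid - t_mid)) > 1e-9)
    stop("srtm_basis_fit: reference TAC frame grid does not match the image")
  idx <- which(brain_mask$voxels)
  if (length(idx) == 0L) stop("srtm_basis_fit: empty brain mask")
  nf <- length(t_mid)
  nvox_total <- prod(dim(image$voxels)[1:3])
  Y <- matrix(0, nf, length(idx))
  for (f in seq_len(nf)) Y[f, ] <- image$voxels[idx + (f - 1L) * nvox_total]

  s_min <- t_mid - cr$frame_dur / 2
  e_min <- t_mid + cr$frame_dur / 2
  tf <- .fine_grid(e_min[nf])
  crf <- .interp_fine(cr$t_mid, cr$value, tf)
  cr_fa <- cr$value  # measured frame averages of C_R

  best_rss <- rep(Inf, length(idx))
  best_r1 <- best_phi <- rep(NA_real_, length(idx))
  best_theta <- rep(NA_real_, length(idx))
  for (theta in basis) {
    B <- .frame_average(tf, .exp_conv(crf, .pq_fine_dt, theta), s_min, e_min)
    X <- cbind(cr_fa, B)
    XtX <- crossprod(X)
    coefs <- tryCatch(solve(XtX, crossprod(X, Y)), error = function(e) NULL)
    if (is.null(coefs)) next
    rss <- colSums((Y - X %*% coefs)^2)
    upd <- rss < best_rss
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      best_r1[upd] <- coefs[1L, upd]
      best_phi[upd] <- coefs[2L, upd]
      best_theta[upd] <- theta
    }
  }
  k2 <- best_phi + best_r1 * best_theta
  bp <- k2 / best_theta - 1
  ok <- is.finite(bp) & is.finite(best_r1) & best_r1 > 0
  n_failed <- sum(!ok)
  bp[!ok] <- NaN; best_r1[!ok] <- NaN; k2[!ok] <- NaN

  mk_map <- function(v) {
    m <- array(NaN, dim(image$voxels)[1:3])
    m[idx] <- v
    m
  }
  fitted_mask <- array(FALSE, dim(image$voxels)[1:3])
  fitted_mask[idx[ok]] <- TRUE
  structure(list(bp = mk_map(bp), r1 = mk_map(best_r1), k2 = mk_map(k2),
                 mask = voxel_mask(fitted_mask, image$affine),
                 affine = image$affine, n_failed = n_failed),
            class = "parametric_maps")
}

#' Write parametric maps to NIfTI files
#'
#' One file per parameter with the parameter name as filename suffix
#' (`<prefix>_bp.nii.gz`, `_r1.nii.gz`, `_k2.nii.gz`).
#'
#' @param maps a `parametric_maps` object from [srtm_basis_fit()].
#' @param prefix output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_parametric_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "parametric_maps"))
  paths <- c(bp = paste0(prefix, "_bp.nii.gz"),
             r1 = paste0(prefix, "_r1.nii.gz"),
             k2 = paste0(prefix, "_k2.nii.gz"))
  for (p in names(paths)) write_nifti(maps[[p]], maps$affine, paths[[p]])
  invisible(paths)
}
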