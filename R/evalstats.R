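# Operator-variability evaluation statistics: asymmetric spatial overlap,
# crossed two-way random-effects variance components (REML) and the ICCs
# derived from them, AUC standardization, distribution descriptors and
# overlap, relative bias, Pearson correlation.

#' Asymmetric spatial overlap between two masks
#'
#' `100 * |auto intersect manual| / |manual|`: the fraction of the second
#' (manual) mask covered by the first. Deliberately asymmetric — an
#' automatic mask containing the whole manual mask scores 100 regardless of
#' its own size.
#'
#' @param auto first [voxel_mask()].
#' @param manual second [voxel_mask()], the denominator; must be non-empty.
#' @return Overlap percentage.
#' @export
spatial_overlap <- function(auto, manual) {
  stopifnot(inherits(auto, "voxel_mask"), inherits(manual, "voxel_mask"))
  .same_grid(dim(auto$voxels), auto$affine,
             dim(manual$voxels), manual$affine, "masks")
  n_manual <- sum(manual$voxels)
  if (n_manual == 0L) stop("spatial_overlap: manual mask is empty")
  100 * sum(auto$voxels & manual$voxels) / n_manual
}

#' Mean pairwise overlap of a set of masks
#'
#' [spatial_overlap()] over all ordered pairs (i != j), averaged.
#'
#' @param masks list of >= 2 non-empty [voxel_mask()]s on one grid.
#' @return Mean overlap percentage.
#' @export
pairwise_overlap_summary <- function(masks) {
  if (length(masks) < 2L) stop("pairwise_overlap_summary: need >= 2 masks")
  for (m in masks) if (!sum(m$voxels)) stop("pairwise_overlap_summary: empty mask")
  vals <- c()
  for (i in seq_along(masks)) for (j in seq_along(masks)) if (i != j)
    vals <- c(vals, spatial_overlap(masks[[i]], masks[[j]]))
  mean(vals)
}

#' Long-format rater table
#'
#' @param study study identifiers.
#' @param operator operator identifiers.
#' @param value numeric measurements.
#' @return A `data.frame` of class `rater_table`.
#' @export
rater_table <- function(study, operator, value) {
  d <- data.frame(study = as.factor(study), operator = as.factor(operator),
                  value = as.numeric(value))
  if (anyDuplicated(d[c("study", "operator")]))
    stop("rater_table: duplicated (study, operator) rows")
  if (nlevels(d$study) < 2L || nlevels(d$operator) < 2L)
    stop("rater_table: need >= 2 studies and >= 2 operators")
  n_cells <- nlevels(d$study) * nlevels(d$operator)
  if (nrow(d) < n_cells)
    attr(d, "balanced") <- FALSE
  else attr(d, "balanced") <- TRUE
  class(d) <- c("rater_table", "data.frame")
  d
}

#' Variance components and ICCs of a crossed study x operator design
#'
#' REML fit of the random-effects model
#' `value ~ 1 + (1 | operator) + (1 | study)`; the ICC of a component is
#' its variance share of the total `sigma2_study + sigma2_operator +
#' sigma2_residual`, so both ICCs lie in `[0, 1]` (negative components are
#' clipped at zero by REML itself).
#'
#' @param table a [rater_table()].
#' @return List of class `variance_components` with `sigma2_study`,
#'   `sigma2_operator`, `sigma2_residual`, `icc_study`, `icc_operator`.
#' @export
icc_components <- function(table) {
  stopifnot(inherits(table, "rater_table"))
  if (!isTRUE(attr(table, "balanced")))
    message("icc_components: unbalanced study x operator design")
  # boundary fits (a variance component estimated at exactly 0) are
  # expected for degenerate designs; lme4's convergence chatter about them
  # is suppressed, estimation errors are not
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ 1 + (1 | operator) + (1 | study),
                 data = table, REML = TRUE))),
    error = function(e) stop("icc_components: singular or unfittable design: ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_v <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 0L) 0 else max(v, 0)
  }
  s2_study <- get_v("study")
  s2_op <- get_v("operator")
  s2_res <- get_v("Residual")
  tot <- s2_study + s2_op + s2_res
  structure(list(sigma2_study = s2_study, sigma2_operator = s2_op,
                 sigma2_residual = s2_res,
                 icc_study = if (tot > 0) s2_study / tot else NA_real_,
                 icc_operator = if (tot > 0) s2_op / tot else NA_real_),
            class = "variance_components")
}

#' Standardize AUCs by the per-study union-region mean activity
#'
#' Divides each (study, operator) AUC by that study's mean radioactivity
#' within the union of all operators' reference regions, removing
#' between-study variance due to scanner, dose and body mass.
#'
#' @param aucs a [rater_table()] of AUC values.
#' @param union_mean_activity named numeric vector, one positive value per
#'   study level.
#' @return A [rater_table()] of standardized values.
#' @export
standardize_auc <- function(aucs, union_mean_activity) {
  stopifnot(inherits(aucs, "rater_table"))
  lev <- levels(aucs$study)
  if (!all(lev %in% names(union_mean_activity)))
    stop("standardize_auc: missing union mean for study ",
         paste(setdiff(lev, names(union_mean_activity)), collapse = ", "))
  div <- union_mean_activity[as.character(aucs$study)]
  if (any(div <= 0)) stop("standardize_auc: union mean activity must be > 0")
  rater_table(aucs$study, aucs$operator, aucs$value / div)
}

#' Descriptors of a radioactivity (SUV) distribution
#'
#' Mean, sample SD, KDE mode (same KDE settings as the tail-exclusion
#' step), adjusted Fisher-Pearson skewness, and FWHM bounds of the KDE.
#'
#' @param values numeric sample, `n >= 100`.
#' @return List of class `distribution_summary` with `mean`, `sd`, `mode`,
#'   `skewness`, `fwhm_bounds`.
#' @export
distribution_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 100L)
    stop("distribution_summary: need >= 100 samples (got ", n, ")")
  s <- sd(values)
  if (s < .Machine$double.eps^0.5) {
    return(structure(list(mean = mean(values), sd = 0, mode = values[1L],
                          skewness = NA_real_,
                          fwhm_bounds = c(values[1L], values[1L])),
                     class = "distribution_summary"))
  }
  dens <- .pq_density(values)
  i_mode <- which.max(dens$y)
  half <- dens$y[i_mode] / 2
  lo <- .halfmax_bound(dens$x, dens$y, i_mode, half, "lower")
  hi <- .halfmax_bound(dens$x, dens$y, i_mode, half, "upper")
  m3 <- mean((values - mean(values))^3)
  g1 <- m3 / (mean((values - mean(values))^2))^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)  # adjusted Fisher-Pearson
  structure(list(mean = mean(values), sd = s, mode = dens$x[i_mode],
                 skewness = skew,
                 fwhm_bounds = c(lo %||% min(values), hi %||% max(values))),
            class = "distribution_summary")
}

#' Overlap of two sample distributions
#'
#' `100 * int min(p, q)` where `p`, `q` are kernel density estimates of the
#' two samples evaluated on one common grid and renormalized to unit mass
#' on it. Symmetric up to KDE grid tolerance.
#'
#' @param p_samples,q_samples numeric samples, each `n >= 100`.
#' @return Overlap percentage in `[0, 100]`.
#' @export
distribution_overlap <- function(p_samples, q_samples) {
  p_samples <- p_samples[is.finite(p_samples)]
  q_samples <- q_samples[is.finite(q_samples)]
  if (length(p_samples) < 100L || length(q_samples) < 100L)
    stop("distribution_overlap: each sample needs n >= 100")
  lo <- min(p_samples, q_samples); hi <- max(p_samples, q_samples)
  dp <- stats::density(p_samples, bw = "nrd0", n = 512, from = lo, to = hi)
  dq <- stats::density(q_samples, bw = "nrd0", n = 512, from = lo, to = hi)
  dx <- diff(dp$x[1:2])
  p <- dp$y / sum(dp$y * dx)
  q <- dq$y / sum(dq$y * dx)
  100 * sum(pmin(p, q)) * dx
}

#' Relative bias of automatic versus manual-mean values
#'
#' `100 * (auto - manual_mean) / manual_mean`, elementwise; works on
#' scalars, regional vectors, and voxel maps. Zero denominators yield NaN
#' with a warning naming the count.
#'
#' @param auto numeric vector/array of automatic estimates.
#' @param manual_mean numeric vector/array (same shape) of manual-mean
#'   estimates.
#' @return Percent bias, same shape as the inputs.
#' @export
relative_bias <- function(auto, manual_mean) {
  if (!all(dim(auto) %||% length(auto) == dim(manual_mean) %||% length(manual_mean)))
    stop("relative_bias: shape mismatch")
  zero <- is.finite(manual_mean) & manual_mean == 0
  if (any(zero))
    warning(sprintf("relative_bias: %d zero denominator(s) set to NaN", sum(zero)))
  out <- 100 * (auto - manual_mean) / manual_mean
  out[zero] <- NaN
  out
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, length >= 3, each with nonzero variance.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson_r: need equal-length vectors with n >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("pearson_r: zero variance input")
  stats::cor(x, y, method = "pearson")
}
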