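# Kinetic models. All models share one numerical backbone: input curves
# are linearly interpolated onto a uniform fine grid (default step 0.25 s
# expressed in minutes) anchored at (0, 0), and convolution with an
# exponential kernel uses the exact piecewise-linear solution evaluated by
# a linear recurrence (stats::filter, C speed). Nonlinear and basis-
# function fits evaluate the model as frame-interval averages — the same
# integration the scanner applies to the data — so a noiseless forward
# simulation is recovered to optimizer precision. The graphical models
# operate on the frame-midpoint samples, as the plots are defined.

.pq_fine_dt <- 0.25 / 60  # minutes

#' Arterial plasma input curve
#'
#' Metabolite-corrected plasma activity on a dense (possibly irregular)
#' time grid starting at zero.
#'
#' @param t minutes, starting at 0, strictly increasing.
#' @param cp activity, kBq/ml; nonnegative with `cp[1] == 0`.
#' @return Object of class `plasma_input`.
#' @export
plasma_input <- function(t, cp) {
  if (length(t) != length(cp) || length(t) < 2L)
    stop("plasma_input: t and cp must have equal length >= 2")
  if (abs(t[1L]) > 1e-9) stop("plasma_input: t must start at 0")
  if (any(diff(t) <= 0)) stop("plasma_input: t must be strictly increasing")
  if (any(cp < 0)) stop("plasma_input: cp must be nonnegative")
  if (cp[1L] != 0) stop("plasma_input: cp(0) must be 0")
  structure(list(t = as.numeric(t), cp = as.numeric(cp)),
            class = "plasma_input")
}

# Uniform fine grid covering [0, t_end].
.fine_grid <- function(t_end, dt = .pq_fine_dt) seq(0, t_end, by = dt)

# Interpolate a sampled curve onto the fine grid; (0, 0) is prepended when
# the first sample is after time zero (tracer absent before injection),
# and the last value is held constant beyond the final sample.
.interp_fine <- function(t, v, tf) {
  if (t[1L] > 1e-9) { t <- c(0, t); v <- c(0, v) }
  approx(t, v, xout = tf, rule = 2)$y
}

# Exact convolution of a piecewise-linear curve c (on uniform grid, step
# dt) with exp(-theta * t): y_i = y_{i-1} e^{-theta dt} + segment integral.
.exp_conv <- function(cfine, dt, theta) {
  n <- length(cfine)
  if (theta < 1e-12) {
    return(.cumtrapz(seq(0, by = dt, length.out = n), cfine))
  }
  E <- exp(-theta * dt)
  I0 <- (1 - E) / theta
  I1 <- (1 - E * (1 + theta * dt)) / theta^2
  ci <- cfine[-1L]; cim1 <- cfine[-n]
  b <- ci * I0 + (cim1 - ci) * I1 / dt
  c(0, as.numeric(stats::filter(b, E, method = "recursive")))
}

# Sample a fine-grid curve at arbitrary times.
.sample_at <- function(tf, yf, t_out) approx(tf, yf, xout = t_out, rule = 2)$y

# Average a fine-grid curve over frame intervals [start, end] (minutes).
.frame_average <- function(tf, yf, start_min, end_min) {
  .make_frame_averager(tf, start_min, end_min)(yf)
}

# Precompiled frame averager for a fixed uniform grid and frame layout:
# all interpolation indices and endpoint weights are computed once, so the
# per-call cost inside fit loops is one cumsum plus vector arithmetic.
.make_frame_averager <- function(tf, start_min, end_min) {
  n <- length(tf)
  dt <- tf[2L] - tf[1L]
  clamp <- function(x) pmin(pmax(x, tf[1L]), tf[n])
  s <- clamp(start_min); e <- clamp(end_min)
  i_s <- pmin(findInterval(s, tf), n - 1L)
  i_e <- pmin(findInterval(e, tf), n - 1L)
  ds <- s - tf[i_s]; de <- e - tf[i_e]
  dur <- end_min - start_min
  function(yf) {
    seg <- (yf[-1L] + yf[-n]) * (dt / 2)
    Fcum <- c(0, cumsum(seg))
    # partial trapezoid from the grid point below to the interval endpoint
    slope_s <- (yf[i_s + 1L] - yf[i_s]) / dt
    slope_e <- (yf[i_e + 1L] - yf[i_e]) / dt
    Fa <- Fcum[i_s] + ds * (yf[i_s] + (yf[i_s] + slope_s * ds)) / 2
    Fb <- Fcum[i_e] + de * (yf[i_e] + (yf[i_e] + slope_e * de)) / 2
    (Fb - Fa) / dur
  }
}

#' Kinetic fit result container
#'
#' @param model model name.
#' @param params named numeric parameter estimates.
#' @param se named standard errors (NA where undefined).
#' @param fitted fitted [tac()] at the data frames.
#' @param rss residual sum of squares.
#' @param n_points number of fitted points.
#' @param t_star_used t* actually used, minutes (NA for non-graphical models).
#' @return Object of class `kinetic_fit`.
#' @export
kinetic_fit <- function(model, params, se = NULL, fitted = NULL, rss = NA_real_,
                        n_points = NA_integer_, t_star_used = NA_real_) {
  if (!is.null(fitted)) stopifnot(inherits(fitted, "tac"))
  if (is.finite(rss) && rss < 0) stop("kinetic_fit: rss must be >= 0")
  if (all(c("BP_ND", "DVR") %in% names(params)))
    stopifnot(abs(params[["BP_ND"]] - (params[["DVR"]] - 1)) < 1e-12)
  structure(list(model = model, params = params, se = se, fitted = fitted,
                 rss = rss, n_points = n_points, t_star_used = t_star_used),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s (n=%s, rss=%.4g)\n", x$model, x$n_points, x$rss))
  print(round(unlist(x$params), 5))
  invisible(x)
}

.check_same_frames <- function(ct, cr) {
  stopifnot(inherits(ct, "tac"), inherits(cr, "tac"))
  if (length(ct) != length(cr) || max(abs(ct$t_mid - cr$t_mid)) > 1e-9)
    stop("target and reference TACs must share the same frame grid")
  if (ct$unit != cr$unit)
    stop("target and reference TACs must share the same unit")
  invisible(TRUE)
}

# Gauss-ish standard errors from a finite-difference Jacobian at the optimum.
.nls_se <- function(fn_vec, par, w, rss, n) {
  p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  J <- matrix(0, n, p)
  f0 <- fn_vec(par)
  for (j in seq_len(p)) {
    h <- max(1e-6, abs(par[j]) * 1e-6)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn_vec(pj) - f0) / h
  }
  JtWJ <- crossprod(J * sqrt(w))
  cov <- tryCatch(solve(JtWJ) * rss / (n - p), error = function(e) NULL)
  if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
}

#' Fit the simplified reference tissue model (SRTM)
#'
#' Weighted nonlinear least squares of the three-parameter SRTM
#' `C_T = R1 C_R + (k2 - R1 k2a) C_R (x) exp(-k2a t)`, `k2a = k2/(1+BP_ND)`,
#' solved by variable projection: for fixed `k2a` the model is linear in
#' `(R1, phi)`, so the profiled residual is minimized over a 1-D `k2a`
#' bracket located on a log-spaced grid and refined with Brent search.
#' This handles the flat ridge at `BP_ND ~ 0` (where `k2` is weakly
#' identified) exactly rather than by multistart luck.
#'
#' @param ct target [tac()].
#' @param cr reference [tac()] on the identical frame grid and unit.
#' @param weights per-frame weights (see [weights_from_frames()]) or `NULL`
#'   for uniform.
#' @param k2a_range search range for `k2a` (1/min).
#' @return A [kinetic_fit()] with `R1`, `k2`, `k2a`, `BP_ND`, `DVR`.
#' @export
srtm_fit <- function(ct, cr, weights = NULL, k2a_range = c(0.006, 0.6)) {
  .check_same_frames(ct, cr)
  if (length(ct) < 6L) stop("srtm_fit: need at least 6 frames")
  w <- if (is.null(weights)) rep(1, length(ct)) else weights
  t_mid <- ct$t_mid
  s_min <- t_mid - ct$frame_dur / 2
  e_min <- t_mid + ct$frame_dur / 2
  tf <- .fine_grid(e_min[length(e_min)])
  crf <- .interp_fine(cr$t_mid, cr$value, tf)
  favg <- .make_frame_averager(tf, s_min, e_min)
  # the measured reference values are already frame averages of C_R, so
  # they serve as the R1 basis exactly; only the convolution term needs
  # the interpolated fine-grid curve
  cr_fa <- cr$value
  sw <- sqrt(w)
  yv <- ct$value * sw
  lin_fit <- function(theta) {
    B <- favg(.exp_conv(crf, .pq_fine_dt, theta))
    X <- cbind(cr_fa, B) * sw
    cf <- tryCatch(qr.solve(X, yv), error = function(e) NULL)
    if (is.null(cf)) return(list(coef = c(NA, NA), rss = Inf, B = B))
    list(coef = cf, rss = sum((yv - X %*% cf)^2), B = B)
  }
  grid <- exp(seq(log(k2a_range[1L]), log(k2a_range[2L]), length.out = 64L))
  rss_g <- vapply(grid, function(th) lin_fit(th)$rss, 0)
  if (!any(is.finite(rss_g)))
    stop("srtm_fit: singular linear subproblem at every k2a; check the TACs")
  k <- which.min(rss_g)
  br <- c(grid[max(k - 1L, 1L)], grid[min(k + 1L, length(grid))])
  op <- optimize(function(th) lin_fit(th)$rss, interval = br, tol = 1e-12)
  theta <- op$minimum
  bf <- lin_fit(theta)
  R1 <- bf$coef[1L]; phi <- bf$coef[2L]
  k2 <- phi + R1 * theta
  bp <- k2 / theta - 1
  if (!is.finite(bp) || R1 <= 0 || k2 <= 0 || bp <= -0.9 || bp > 30)
    stop(sprintf(
      "srtm_fit: estimates outside physiological bounds (R1=%.3g, k2=%.3g, BP_ND=%.3g)",
      R1, k2, bp))
  fitted_vals <- R1 * cr_fa + phi * bf$B
  model <- function(q) {
    k2a <- q[2L] / (1 + q[3L])
    favg(q[1L] * crf + (q[2L] - q[1L] * k2a) * .exp_conv(crf, .pq_fine_dt, k2a))
  }
  se <- .nls_se(model, c(R1, k2, bp), w, bf$rss, length(ct))
  kinetic_fit("srtm",
              params = list(R1 = R1, k2 = k2, k2a = theta,
                            BP_ND = bp, DVR = bp + 1),
              se = list(R1 = se[1L], k2 = se[2L], BP_ND = se[3L]),
              fitted = tac(t_mid, fitted_vals, ct$unit, ct$frame_dur),
              rss = bf$rss, n_points = length(ct))
}

# Shared OLS for the graphical models; returns slope/intercept + oracle-
# checkable internals.
.graphical_ols <- function(x, y, keep) {
  n <- sum(keep)
  if (n < 3L) stop("graphical fit: need >= 3 frames with t_mid >= t_star")
  xs <- x[keep]; ys <- y[keep]
  sl <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  ic <- mean(ys) - sl * mean(xs)
  res <- ys - sl * xs - ic
  s2 <- sum(res^2) / max(n - 2, 1)
  se_sl <- sqrt(s2 / sum((xs - mean(xs))^2))
  list(slope = sl, intercept = ic, rss = sum(res^2), n = n, se_slope = se_sl,
       x = xs, y = ys)
}

#' Logan graphical analysis with reference-tissue input
#'
#' Ordinary least squares on the Logan coordinates
#' `y(T) = int_0^T C_T / C_T(T)` versus
#' `x(T) = [int_0^T C_R + C_R(T)/k2'] / C_T(T)` for frames with
#' `t_mid >= t_star`; the slope is the distribution volume ratio (DVR) and
#' `BP_ND = DVR - 1`. When `k2prime` is `NULL` the `C_R(T)/k2'` term is
#' omitted (documented simplification; adequate once the reference curve
#' term is small relative to its integral).
#'
#' @param ct target [tac()].
#' @param cr reference [tac()] on the same frame grid.
#' @param t_star start of the linear segment, minutes.
#' @param k2prime reference-tissue clearance rate `k2'` (1/min) or `NULL`.
#' @return A [kinetic_fit()] with `DVR`, `BP_ND`, `intercept`.
#' @export
logan_ref <- function(ct, cr, t_star, k2prime = NULL) {
  .check_same_frames(ct, cr)
  t_mid <- ct$t_mid
  int_ct <- .cumtrapz(c(0, t_mid), c(0, ct$value))[-1L]
  int_cr <- .cumtrapz(c(0, t_mid), c(0, cr$value))[-1L]
  num <- if (is.null(k2prime)) int_cr else int_cr + cr$value / k2prime
  x <- num / ct$value
  y <- int_ct / ct$value
  o <- .graphical_ols(x, y, t_mid >= t_star - 1e-9)
  kinetic_fit("logan_ref",
              params = list(DVR = o$slope, BP_ND = o$slope - 1,
                            intercept = o$intercept),
              se = list(DVR = o$se_slope, BP_ND = o$se_slope),
              rss = o$rss, n_points = o$n, t_star_used = t_star)
}

#' Logan graphical analysis with plasma input
#'
#' Slope of `int_0^T C_T / C_T(T)` versus `int_0^T C_p / C_T(T)` over the
#' late linear segment; the slope is the total distribution volume `V_T`.
#'
#' @param ct target [tac()].
#' @param plasma a [plasma_input()].
#' @param t_star start of the linear segment, minutes.
#' @return A [kinetic_fit()] with `V_T`, `intercept`.
#' @export
logan_plasma <- function(ct, plasma, t_star) {
  stopifnot(inherits(ct, "tac"), inherits(plasma, "plasma_input"))
  t_mid <- ct$t_mid
  if (max(t_mid) > plasma$t[length(plasma$t)] + 1e-9)
    stop(sprintf("plasma curve ends at %g min but frames extend to %g min",
                 plasma$t[length(plasma$t)], max(t_mid)))
  int_cp_grid <- .cumtrapz(plasma$t, plasma$cp)
  int_cp <- approx(plasma$t, int_cp_grid, xout = t_mid, rule = 2)$y
  int_ct <- .cumtrapz(c(0, t_mid), c(0, ct$value))[-1L]
  x <- int_cp / ct$value
  y <- int_ct / ct$value
  o <- .graphical_ols(x, y, t_mid >= t_star - 1e-9)
  kinetic_fit("logan_plasma",
              params = list(V_T = o$slope, intercept = o$intercept),
              se = list(V_T = o$se_slope),
              rss = o$rss, n_points = o$n, t_star_used = t_star)
}

#' Patlak graphical analysis with plasma input
#'
#' Slope of `C_T(T)/C_p(T)` versus `int_0^T C_p / C_p(T)` over the late
#' segment; for an (effectively) irreversibly trapped tracer the slope is
#' the net uptake rate `K_i = K1 k3 / (k2 + k3)` and the intercept the
#' effective distribution volume.
#'
#' @param ct target [tac()].
#' @param plasma a [plasma_input()].
#' @param t_star start of the linear segment, minutes.
#' @return A [kinetic_fit()] with `K_i`, `intercept`.
#' @export
patlak_plasma <- function(ct, plasma, t_star) {
  stopifnot(inherits(ct, "tac"), inherits(plasma, "plasma_input"))
  t_mid <- ct$t_mid
  if (max(t_mid) > plasma$t[length(plasma$t)] + 1e-9)
    stop(sprintf("plasma curve ends at %g min but frames extend to %g min",
                 plasma$t[length(plasma$t)], max(t_mid)))
  int_cp_grid <- .cumtrapz(plasma$t, plasma$cp)
  int_cp <- approx(plasma$t, int_cp_grid, xout = t_mid, rule = 2)$y
  cp_at <- approx(plasma$t, plasma$cp, xout = t_mid, rule = 2)$y
  x <- int_cp / cp_at
  y <- ct$value / cp_at
  o <- .graphical_ols(x, y, t_mid >= t_star - 1e-9)
  kinetic_fit("patlak_plasma",
              params = list(K_i = o$slope, intercept = o$intercept),
              se = list(K_i = o$se_slope),
              rss = o$rss, n_points = o$n, t_star_used = t_star)
}

#' Patlak graphical analysis with reference-tissue input
#'
#' As [patlak_plasma()] with the reference TAC in place of plasma; the
#' slope is a reference-normalized uptake rate in 1/min.
#'
#' @param ct target [tac()].
#' @param cr reference [tac()] on the same frame grid.
#' @param t_star start of the linear segment, minutes.
#' @return A [kinetic_fit()] with `K_i`, `intercept`.
#' @export
patlak_ref <- function(ct, cr, t_star) {
  .check_same_frames(ct, cr)
  t_mid <- ct$t_mid
  int_cr <- .cumtrapz(c(0, t_mid), c(0, cr$value))[-1L]
  x <- int_cr / cr$value
  y <- ct$value / cr$value
  o <- .graphical_ols(x, y, t_mid >= t_star - 1e-9)
  kinetic_fit("patlak_ref",
              params = list(K_i = o$slope, intercept = o$intercept),
              se = list(K_i = o$se_slope),
              rss = o$rss, n_points = o$n, t_star_used = t_star)
}

#' SUV ratio over a time window
#'
#' Ratio of target to reference area under the curve over `window`
#' (trapezoidal, endpoint-interpolated).
#'
#' @param ct target [tac()].
#' @param cr reference [tac()] in the same unit.
#' @param window `c(t0, t1)` minutes.
#' @return A [kinetic_fit()] with `SUVR`.
#' @export
suvr <- function(ct, cr, window) {
  stopifnot(inherits(ct, "tac"), inherits(cr, "tac"))
  if (ct$unit != cr$unit) stop("suvr: TAC units differ")
  denom <- tac_auc(cr, window)
  if (abs(denom) < .Machine$double.eps)
    stop("suvr: reference AUC over the window is zero")
  kinetic_fit("suvr", params = list(SUVR = tac_auc(ct, window) / denom),
              n_points = length(ct))
}

#' Fractional uptake ratio (FUR) for late-scan frames
#'
#' `FUR(T) = C_T(T) / int_0^T C_p(t) dt` per late frame, plus their mean;
#' approximates the Patlak `K_i` for irreversible tracers at late times.
#'
#' @param ct_late [tac()] of late frames.
#' @param plasma a [plasma_input()] covering `[0, T]` for every frame
#'   midpoint `T`.
#' @return A [kinetic_fit()] with `FUR` (mean) and `FUR_per_frame`.
#' @export
fur <- function(ct_late, plasma) {
  stopifnot(inherits(ct_late, "tac"), inherits(plasma, "plasma_input"))
  Tm <- ct_late$t_mid
  if (max(Tm) > plasma$t[length(plasma$t)] + 1e-9)
    stop(sprintf("fur: plasma curve ends at %g min but frames extend to %g min",
                 plasma$t[length(plasma$t)], max(Tm)))
  int_cp_grid <- .cumtrapz(plasma$t, plasma$cp)
  int_cp <- approx(plasma$t, int_cp_grid, xout = Tm)$y
  if (any(int_cp <= 0)) stop("fur: integrated plasma is nonpositive at a frame")
  per_frame <- ct_late$value / int_cp
  kinetic_fit("fur", params = list(FUR = mean(per_frame),
                                   FUR_per_frame = per_frame),
              n_points = length(ct_late))
}

# 2TCM impulse response: sum of two exponentials (analytic eigenvalues).
.tcm2_impulse <- function(K1, k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-12) {  # degenerate equal roots; nudge apart
    a1 <- a1 * (1 - 1e-9); a2 <- a2 * (1 + 1e-9)
  }
  phi1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  phi2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  list(a = c(a1, a2), phi = c(phi1, phi2))
}

.tcm2_model <- function(par, favg, cpf, dt, vB, bloodf) {
  ir <- .tcm2_impulse(par[1L], par[2L], par[3L], par[4L])
  m <- ir$phi[1L] * .exp_conv(cpf, dt, ir$a[1L]) +
       ir$phi[2L] * .exp_conv(cpf, dt, ir$a[2L])
  if (vB > 0) m <- (1 - vB) * m + vB * bloodf
  favg(m)
}

#' Fit the two-tissue compartment model to a regional TAC
#'
#' Nonlinear least squares over `(K1, k2, k3, k4[, V_B])` using the
#' analytic biexponential solution convolved with the plasma input, with a
#' seeded multistart. Voxelwise use is rejected by contract: the model is
#' for regional data.
#'
#' @param ct regional target [tac()].
#' @param plasma a [plasma_input()] with at least one sample per minute over
#'   the early scan.
#' @param vB_mode `"zero"` (default), `"fixed"` (use `vB_value`), or
#'   `"fit"` (requires `blood`).
#' @param vB_value fixed fractional blood volume when `vB_mode = "fixed"`.
#' @param blood whole-blood [tac()] (or `NULL`); required when V_B enters
#'   the model.
#' @param n_starts number of multistart draws (>= 10).
#' @param seed integer seed for the multistart jitter.
#' @return A [kinetic_fit()] with `K1, k2, k3, k4, V_B, V_T` (V_T reported
#'   when `k4 > 0`) and an `irreversible` flag when k4 hits its zero bound.
#' @export
tcm2_fit <- function(ct, plasma, vB_mode = c("zero", "fixed", "fit"),
                     vB_value = 0.05, blood = NULL, n_starts = 10L, seed = 1L) {
  vB_mode <- match.arg(vB_mode)
  stopifnot(inherits(ct, "tac"), inherits(plasma, "plasma_input"))
  early <- plasma$t[plasma$t <= 5]
  if (length(early) > 1L && max(diff(early)) > 1.000001)
    warning("tcm2_fit: plasma sampling sparser than 1/min over the early scan")
  t_mid <- ct$t_mid
  s_min <- t_mid - ct$frame_dur / 2
  e_min <- t_mid + ct$frame_dur / 2
  # 0.5 s convolution step: the induced parameter error (~0.01% on the
  # default schedule) is far below fit tolerances at half the cost
  dt2 <- 0.5 / 60
  tf <- .fine_grid(max(e_min), dt2)
  cpf <- .interp_fine(plasma$t, plasma$cp, tf)
  bloodf <- if (!is.null(blood)) .interp_fine(blood$t_mid, blood$value, tf)
            else cpf
  fit_vB <- vB_mode == "fit"
  if (fit_vB && is.null(blood))
    stop("tcm2_fit: vB_mode='fit' requires a whole-blood curve")
  vB_fixed <- switch(vB_mode, zero = 0, fixed = vB_value, fit = NA_real_)
  favg <- .make_frame_averager(tf, s_min, e_min)
  obj <- function(p) {
    vB <- if (fit_vB) p[5L] else vB_fixed
    m <- .tcm2_model(p[1:4], favg, cpf, dt2, vB, bloodf)
    sum((ct$value - m)^2)
  }
  lower <- c(1e-6, 1e-6, 0, 0)
  upper <- c(3, 3, 2, 1)
  if (fit_vB) { lower <- c(lower, 0); upper <- c(upper, 0.2) }
  starts <- .with_seed(seed, {
    lapply(seq_len(max(n_starts, 10L)), function(i) {
      s <- c(runif(1, 0.02, 0.6), runif(1, 0.02, 0.6),
             runif(1, 0.001, 0.3), runif(1, 0.001, 0.2))
      if (fit_vB) s <- c(s, runif(1, 0, 0.1))
      s
    })
  })
  starts[[1L]] <- if (fit_vB) c(0.1, 0.1, 0.05, 0.02, 0.05) else c(0.1, 0.1, 0.05, 0.02)
  # two stages: a cheap exploration pass from every start, then one tight
  # polish (rel.tol 1e-15) from the best basin
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, obj, lower = lower, upper = upper,
             control = list(eval.max = 120, iter.max = 60, rel.tol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    stop("tcm2_fit: optimization failed from every start")
  best <- nlminb(best$par, obj, lower = lower, upper = upper,
                 control = list(eval.max = 1500, iter.max = 800,
                                rel.tol = 1e-15, x.tol = 1e-12))
  best$value <- best$objective
  p <- best$par
  vB <- if (fit_vB) p[5L] else vB_fixed
  irreversible <- p[4L] < 1e-6
  V_T <- if (!irreversible) (p[1L] / p[2L]) * (1 + p[3L] / p[4L]) else NA_real_
  fitted_vals <- .tcm2_model(p[1:4], favg, cpf, dt2, vB, bloodf)
  se <- .nls_se(function(q) {
    vBq <- if (fit_vB) q[5L] else vB_fixed
    .tcm2_model(q[1:4], favg, cpf, dt2, vBq, bloodf)
  }, p, rep(1, length(ct)), best$value, length(ct))
  params <- list(K1 = p[1L], k2 = p[2L], k3 = p[3L], k4 = p[4L],
                 V_B = vB, V_T = V_T, irreversible = irreversible)
  senames <- c("K1", "k2", "k3", "k4", if (fit_vB) "V_B")
  kinetic_fit("tcm2", params = params,
              se = stats::setNames(as.list(se), senames),
              fitted = tac(t_mid, fitted_vals, ct$unit, ct$frame_dur),
              rss = best$value, n_points = length(ct))
}

# Run expr with a local RNG state seeded at `seed`, restoring the caller's.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
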