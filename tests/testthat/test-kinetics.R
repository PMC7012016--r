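# Frozen forward-model oracles: target TACs are generated by the synthdata
# module from known parameters; fits must recover them. Graphical slopes
# are additionally checked against an independent lm() regression on
# transformed coordinates computed in-test.

test_that("plasma_input enforces its invariants", {
  expect_error(plasma_input(c(1, 2), c(0, 1)), "start at 0")
  expect_error(plasma_input(c(0, 1), c(1, 2)), "cp\\(0\\)")
  expect_error(plasma_input(c(0, 1), c(0, -1)), "nonnegative")
  expect_error(plasma_input(c(0, 1, 1), c(0, 1, 1)), "increasing")
})

test_that("srtm_fit: identity tissue gives R1 = 1, BP_ND = 0", {
  cr <- fx_ref_tac()
  f <- srtm_fit(cr, cr)
  expect_lt(abs(f$params$R1 - 1), 1e-4)
  expect_lt(abs(f$params$BP_ND), 1e-6)
})

test_that("srtm_fit recovers forward-simulated parameters within 0.5%", {
  f <- srtm_fit(fx_srtm_tac(), fx_ref_tac())
  for (p in names(fx_srtm_truth))
    expect_lt(abs(f$params[[p]] - fx_srtm_truth[[p]]) / fx_srtm_truth[[p]],
              0.005, label = sprintf("%s rel err", p))
  expect_equal(f$params$BP_ND, f$params$DVR - 1, tolerance = 1e-12)
  expect_lt(f$rss, 1e-6)
})

test_that("srtm_fit under 5% noise: Monte-Carlo mean BP_ND within 3%", {
  cr <- fx_ref_tac()
  ct0 <- fx_srtm_tac()
  set.seed(77)
  bps <- replicate(20, {
    noisy <- tac(ct0$t_mid, ct0$value * (1 + rnorm(length(ct0), 0, 0.05)),
                 ct0$unit, ct0$frame_dur)
    srtm_fit(noisy, cr)$params$BP_ND
  })
  expect_lt(abs(mean(bps) - 1.5) / 1.5, 0.03)
})

test_that("srtm_fit validates inputs", {
  cr <- fx_ref_tac()
  short <- tac(1:5, rep(1, 5), "kBq/ml", rep(1, 5))
  expect_error(srtm_fit(short, short), "6 frames")
  other_grid <- tac(cr$t_mid + 0.1, cr$value, cr$unit, cr$frame_dur)
  expect_error(srtm_fit(other_grid, cr), "frame grid")
})

test_that("logan_ref: identity, forward-model recovery, regression oracle", {
  cr <- fx_ref_tac()
  ct <- fx_srtm_tac()
  f0 <- logan_ref(cr, cr, t_star = 30)
  expect_lt(abs(f0$params$DVR - 1), 1e-8)
  f <- logan_ref(ct, cr, t_star = 30, k2prime = 0.15)
  expect_lt(abs(f$params$BP_ND - 1.5) / 1.5, 0.02)
  expect_equal(f$params$BP_ND, f$params$DVR - 1, tolerance = 1e-12)

  # independent oracle: lm() on transformed coordinates built in-test
  tm <- ct$t_mid
  ict <- cumsum(c(tm[1] * ct$value[1] / 2,
                  diff(tm) * (head(ct$value, -1) + tail(ct$value, -1)) / 2))
  icr <- cumsum(c(tm[1] * cr$value[1] / 2,
                  diff(tm) * (head(cr$value, -1) + tail(cr$value, -1)) / 2))
  keep <- tm >= 30
  x <- ((icr + cr$value / 0.15) / ct$value)[keep]
  y <- (ict / ct$value)[keep]
  expect_lt(abs(f$params$DVR - unname(coef(lm(y ~ x))[2])), 1e-10)

  expect_error(logan_ref(ct, cr, t_star = 88), ">= 3 frames")
})

test_that("logan slope is invariant under common scaling of both TACs", {
  cr <- fx_ref_tac(); ct <- fx_srtm_tac()
  f1 <- logan_ref(ct, cr, 30)
  ct2 <- tac(ct$t_mid, 7 * ct$value, ct$unit, ct$frame_dur)
  cr2 <- tac(cr$t_mid, 7 * cr$value, cr$unit, cr$frame_dur)
  f2 <- logan_ref(ct2, cr2, 30)
  expect_equal(f1$params$DVR, f2$params$DVR, tolerance = 1e-12)
})

test_that("logan_plasma recovers V_T = K1/k2 for 1TCM tissue within 2%", {
  pl <- fx_plasma(); sched <- fx_sched()
  f1 <- logan_plasma(fx_ref_tac(), pl, 30)          # K1/k2 = 1
  expect_lt(abs(f1$params$V_T - 1), 0.02)
  ct3 <- forward_1tcm(pl, 0.3, 0.1, sched)          # K1/k2 = 3
  f3 <- logan_plasma(ct3, pl, 30)
  expect_lt(abs(f3$params$V_T - 3) / 3, 0.02)
  # joint scaling of cp and ct leaves V_T unchanged
  pl5 <- plasma_input(pl$t, 5 * pl$cp)
  ct5 <- tac(ct3$t_mid, 5 * ct3$value, ct3$unit, ct3$frame_dur)
  expect_equal(logan_plasma(ct5, pl5, 30)$params$V_T, f3$params$V_T,
               tolerance = 1e-12)
})

test_that("patlak_plasma: K_i = K1 k3/(k2+k3) in the irreversible limit", {
  pl <- fx_plasma(); sched <- fx_sched()
  ct <- forward_2tcm(pl, 0.1, 0.15, 0.05, 0, sched)
  f <- patlak_plasma(ct, pl, 30)
  expect_lt(abs(f$params$K_i - 0.025) / 0.025, 0.02)

  # regression oracle on in-test transformed coordinates
  tm <- ct$t_mid
  icp_g <- cumsum(c(0, diff(pl$t) * (head(pl$cp, -1) + tail(pl$cp, -1)) / 2))
  icp <- approx(pl$t, icp_g, tm)$y
  cp_at <- approx(pl$t, pl$cp, tm)$y
  keep <- tm >= 30
  x <- (icp / cp_at)[keep]; y <- (ct$value / cp_at)[keep]
  expect_lt(abs(f$params$K_i - unname(coef(lm(y ~ x))[2])), 1e-10)

  # no trapping -> K_i ~ 0
  ct0 <- forward_2tcm(pl, 0.1, 0.15, 0, 0, sched)
  expect_lt(abs(patlak_plasma(ct0, pl, 30)$params$K_i), 1e-3)

  # joint scaling invariance
  pl2 <- plasma_input(pl$t, 2 * pl$cp)
  ct2 <- tac(ct$t_mid, 2 * ct$value, ct$unit, ct$frame_dur)
  expect_equal(patlak_plasma(ct2, pl2, 30)$params$K_i, f$params$K_i,
               tolerance = 1e-12)
})

test_that("patlak_ref behaves as the reference-input variant", {
  cr <- fx_ref_tac()
  f <- patlak_ref(cr, cr, 30)
  expect_lt(abs(f$params$K_i), 1e-10)
  expect_lt(abs(f$params$intercept - 1), 1e-10)
  # irreversible target over reversible reference: positive slope that
  # matches an in-test regression oracle
  ct <- forward_2tcm(fx_plasma(), 0.1, 0.15, 0.05, 0, fx_sched())
  f2 <- patlak_ref(ct, cr, 40)
  expect_gt(f2$params$K_i, 0)
  tm <- ct$t_mid
  icr <- cumsum(c(tm[1] * cr$value[1] / 2,
                  diff(tm) * (head(cr$value, -1) + tail(cr$value, -1)) / 2))
  keep <- tm >= 40
  x <- (icr / cr$value)[keep]; y <- (ct$value / cr$value)[keep]
  expect_lt(abs(f2$params$K_i - unname(coef(lm(y ~ x))[2])), 1e-10)
  expect_error(patlak_ref(ct, cr, 89), ">= 3 frames")
})

test_that("suvr is an AUC ratio with the PiB 60-90 min default window", {
  cr <- fx_ref_tac()
  expect_equal(suvr(cr, cr, c(60, 90))$params$SUVR, 1)
  ct2 <- tac(cr$t_mid, 2 * cr$value, cr$unit, cr$frame_dur)
  expect_equal(suvr(ct2, cr, c(60, 90))$params$SUVR, 2, tolerance = 1e-12)
  zero <- tac(cr$t_mid, rep(0, length(cr)), cr$unit, cr$frame_dur)
  expect_error(suvr(cr, zero, c(60, 90)), "zero")
  expect_equal(default_tracer_config("pib")$model_params$suvr_window, c(60, 90))
})

test_that("fur: closed form for constant curves, halves when cp doubles", {
  # constant tissue c, plasma p from (effectively) time zero
  p <- 3; cc <- 6
  pl <- plasma_input(c(0, 1e-12, 30, 60, 90), c(0, p, p, p, p))
  late <- tac(c(60, 75, 90), rep(cc, 3), "kBq/ml", rep(15, 3))
  f <- fur(late, pl)
  expect_equal(f$params$FUR_per_frame, cc / (p * c(60, 75, 90)),
               tolerance = 1e-10)
  pl2 <- plasma_input(pl$t, 2 * pl$cp)
  expect_equal(fur(late, pl2)$params$FUR, f$params$FUR / 2, tolerance = 1e-12)
  # plasma not covering the frames -> error
  short <- plasma_input(c(0, 1e-12, 30), c(0, p, p))
  expect_error(fur(late, short), "ends at")
})

test_that("fur approaches Patlak K_i for an irreversible tracer", {
  pl <- fx_plasma()
  long_sched <- frame_schedule(seq(0, 330, by = 30) * 60,
                               seq(30, 360, by = 30) * 60)
  pl_long <- plasma_curve(input_model_params(), seq(0, 360, by = 0.05))
  ct <- forward_2tcm(pl_long, 0.1, 0.15, 0.05, 0, long_sched)
  late <- tac(tail(ct$t_mid, 3), tail(ct$value, 3), ct$unit,
              tail(ct$frame_dur, 3))
  f <- fur(late, pl_long)
  expect_lt(abs(f$params$FUR - 0.025) / 0.025, 0.10)
})

test_that("tcm2_fit recovers 2TCM parameters and V_T", {
  pl <- fx_plasma()
  ct <- forward_2tcm(pl, 0.1, 0.12, 0.07, 0.04, fx_sched())
  f <- tcm2_fit(ct, pl, seed = 7)
  truth <- c(K1 = 0.1, k2 = 0.12, k3 = 0.07, k4 = 0.04)
  for (p in names(truth))
    expect_lt(abs(f$params[[p]] - truth[[p]]) / truth[[p]], 0.02,
              label = sprintf("%s rel err", p))
  v_t_true <- (0.1 / 0.12) * (1 + 0.07 / 0.04)
  expect_lt(abs(f$params$V_T - v_t_true) / v_t_true, 0.01)
})

test_that("tcm2_fit nested 1TCM limit and input validation", {
  pl <- fx_plasma()
  ct <- forward_1tcm(pl, 0.1, 0.1, fx_sched())
  f <- tcm2_fit(ct, pl, seed = 3)
  expect_lt(f$params$k3, 1e-3)
  expect_lt(abs(f$params$K1 - 0.1) / 0.1, 0.01)
  expect_error(plasma_input(c(0, 1, 2), c(0, -0.5, 1)), "nonnegative")
})

test_that("unit rescaling leaves model estimates invariant (SUV property)", {
  d <- subject_dose(420, 70)
  cr <- fx_ref_tac(); ct <- fx_srtm_tac()
  f_kbq <- suvr(ct, cr, c(60, 90))$params$SUVR
  f_suv <- suvr(to_suv(ct, d), to_suv(cr, d), c(60, 90))$params$SUVR
  expect_equal(f_kbq, f_suv, tolerance = 1e-12)
  l1 <- logan_ref(ct, cr, 30)$params$DVR
  l2 <- logan_ref(to_suv(ct, d), to_suv(cr, d), 30)$params$DVR
  expect_equal(l1, l2, tolerance = 1e-10)
})
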