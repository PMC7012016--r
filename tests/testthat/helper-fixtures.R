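# Shared fixtures, memoized so expensive objects are built once per run.
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_sched <- function() memo("sched", default_schedule())

fx_plasma <- function() memo("plasma", {
  plasma_curve(input_model_params(), seq(0, 97, by = 0.25 / 60))
})

# Reference-region TAC: 1TCM with K1 = 0.1, k2 = 0.1 (V_T = 1)
fx_ref_tac <- function() memo("ref_tac",
  forward_1tcm(fx_plasma(), 0.1, 0.1, fx_sched()))

# Carfentanil-like SRTM target, R1 = 1.2, k2 = 0.15 /min, BP_ND = 1.5
fx_srtm_tac <- function() memo("srtm_tac",
  forward_srtm(fx_ref_tac(), 1.2, 0.15, 1.5, fx_sched()))

fx_srtm_truth <- list(R1 = 1.2, k2 = 0.15, BP_ND = 1.5)

# Default phantom with 5% noise, seed 42
fx_phantom <- function() memo("phantom", {
  build_phantom(
    phantom_spec(noise = list(type = "gaussian", scale = 0.05), seed = 42),
    region_kinetics(8L, "1tcm", list(K1 = 0.1, k2 = 0.1)),
    list(region_kinetics(17L, "srtm", list(R1 = 1.2, k2 = 0.15, BP_ND = 1.5)),
         region_kinetics(18L, "srtm", list(R1 = 1.0, k2 = 0.12, BP_ND = 0.5))))
})

# Noiseless twin of the default phantom
fx_phantom0 <- function() memo("phantom0", {
  build_phantom(
    phantom_spec(noise = list(type = "none")),
    region_kinetics(8L, "1tcm", list(K1 = 0.1, k2 = 0.1)),
    list(region_kinetics(17L, "srtm", list(R1 = 1.2, k2 = 0.15, BP_ND = 1.5))))
})

# Small identity-affine grid helpers for mask construction
grid_affine <- function(vox = 1) diag(c(vox, vox, vox, 1))

cube_mask <- function(dim3, from, to, affine = grid_affine()) {
  m <- array(FALSE, dim3)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  voxel_mask(m, affine)
}

# Uniform-duration schedule: n frames of len_s seconds
simple_sched <- function(n, len_s = 60) {
  frame_schedule(seq(0, by = len_s, length.out = n),
                 seq(len_s, by = len_s, length.out = n))
}

constant_tac <- function(value, n = 11, len_s = 60) {
  s <- simple_sched(n, len_s)
  tac(frame_midtimes(s), rep(value, n), "kBq/ml", frame_durations(s))
}
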