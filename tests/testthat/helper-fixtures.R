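# Shared fixtures: the default input, schedule, and representative kinetics.

fx_sched <- schedule_60min_mouse()
fx_input <- feng_input()

# tumor-like kinetics (high k3/k4) and a matched one-tissue reference
fx_tumor <- tissue_kinetics(K1 = 0.25, k2 = 0.45, k3 = 0.15, k4 = 0.04)
fx_ref <- tissue_kinetics(K1 = 0.10, k2 = 0.18)

# draw physiologically plausible random parameter sets that equilibrate
# within a 60-min scan
draw_kinetics <- function(n, seed, vB_max = 0) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tissue_kinetics(K1 = runif(1, 0.1, 0.6),
                      k2 = runif(1, 0.15, 0.6),
                      k3 = runif(1, 0.02, 0.30),
                      k4 = runif(1, 0.04, 0.15),
                      vB = if (vB_max > 0) runif(1, 0, vB_max) else 0)
    })
  })
}

# numerical ODE oracle for the two-tissue model (independent of the
# analytic convolution path)
ode_2tcm <- function(kin, input, grid) {
  rhs <- function(t, y, p) {
    Cp <- eval_input(input, t)
    list(c(p$K1 * Cp - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  sol <- deSolve::ode(y = c(Ct = 0, Cm = 0), times = grid, func = rhs,
                      parms = kin, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  list(Ct = sol[, "Ct"], Cm = sol[, "Cm"],
       total = kin$vB * eval_input(input, grid) +
         (1 - kin$vB) * (sol[, "Ct"] + sol[, "Cm"]))
}

# a small phantom spec that keeps voxel-level tests fast; vB_tumor /
# vB_muscle let tests isolate kinetics from blood-volume contamination
small_phantom_spec <- function(dim = 24L, vB_tumor = 0.05, vB_muscle = 0.02) {
  s <- dim / 64
  phantom_spec(
    dim_xyz = rep(dim, 3L), voxel_size_mm = 0.8 / s,
    regions = list(
      tumor = list(shape = "sphere", center = round(c(18, 32, 32) * s),
                   radius = max(2, round(6 * s)),
                   kinetics = tissue_kinetics(0.25, 0.45, 0.15, 0.04,
                                              vB = vB_tumor)),
      muscle = list(shape = "sphere", center = round(c(18, 12, 32) * s),
                    radius = max(2, round(4 * s)),
                    kinetics = tissue_kinetics(0.10, 0.18, vB = vB_muscle)),
      lv_blood = list(shape = "sphere", center = round(c(32, 32, 14) * s),
                      radius = max(2, round(3 * s)),
                      kinetics = tissue_kinetics(0, 1), blood = TRUE)
    ))
}
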