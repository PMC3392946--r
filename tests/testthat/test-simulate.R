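p <- fs_params()

test_that("stimulus protocols evaluate piecewise as specified", {
  step <- build_protocol("step", amplitude = 100, duration = 1000,
                         pre_ms = 200, post_ms = 100)
  expect_equal(stim_current(step, 100), 0)
  expect_equal(stim_current(step, 700), 100)    # 500 ms into the step
  expect_equal(stim_current(step, 1250), 0)
  expect_equal(step$duration, 1300)
  ramp <- build_protocol("ramp", duration = 1000, ramp_rate = 200)
  expect_equal(stim_current(ramp, 0), 0)
  expect_equal(stim_current(ramp, 500), 100)
  expect_equal(stim_current(ramp, 1000), 200)   # rate x duration
  zero <- build_protocol("step", amplitude = 0, duration = 500)
  expect_true(all(stim_current(zero, seq(0, 500, 10)) == 0))
  expect_error(build_protocol("step", duration = -1), "duration")
  expect_error(fs_stimulus(data.frame(duration = 0, mode = "hold",
                                      start = 0)), "durations")
})

test_that("RK4 integrates the pure-capacitor model exactly", {
  p0 <- fs_params(g_Na = 0, g_Kv1 = 0, g_Kv3 = 0, g_SK = 0, g_Ca = 0,
                  g_leak = 0)
  b <- buffer_scheme("none")
  st <- initial_state(p0, b, V = -70)
  traj <- fs_integrate(st, p0, b, build_protocol("step", 30, 100))
  # dV/dt = 1 mV/ms for 100 ms (linear ODE: RK4 is exact up to roundoff)
  expect_equal(unname(final_state(traj)[["V"]]), -70 + 100,
               tolerance = 1e-10)
})

test_that("integration is deterministic and the time grid is regular", {
  b <- buffer_scheme("pv", 200)
  st <- initial_state(p, b)
  stim <- build_protocol("step", 100, 200)
  t1 <- fs_integrate(st, p, b, stim)
  t2 <- fs_integrate(st, p, b, stim)
  expect_identical(t1$state, t2$state)          # bitwise reproducible
  expect_identical(t1$currents, t2$currents)
  expect_true(all(diff(t1$time) > 0))
  expect_equal(length(t1$time), floor(200 / (0.01 * 5)) + 1)
})

test_that("halving the step leaves spike times essentially unchanged", {
  b <- buffer_scheme("pv", 1000)
  st <- cached("eqPV1000", equilibrate(p, b))
  stim <- build_protocol("step", 100, 1000)
  s1 <- detect_spikes(fs_integrate(st, p, b, stim, dt = 0.01))$times
  s2 <- detect_spikes(fs_integrate(st, p, b, stim, dt = 0.005,
                                   record_stride = 10L))$times
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 0.1)
})

test_that("RK4 trajectories match a high-accuracy adaptive reference", {
  skip_if_not_installed("deSolve")
  b <- buffer_scheme("pv", 1000)
  st <- cached("eqPV1000", equilibrate(p, b))
  stim <- build_protocol("step", 100, 200)
  traj <- fs_integrate(st, p, b, stim, record_stride = 20L)  # 0.2 ms grid
  f <- function(t, y, parms) {
    names(y) <- state_names(b)
    list(unname(fs_rhs(y, p, b, I_app = 100)))
  }
  ref <- deSolve::lsoda(unname(st), traj$time, f, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(ref[, 2] - traj$state[, "V"])), 0.5)
})

test_that("burn-in settles to a quiescent state near -70 mV", {
  b <- buffer_scheme("pv", 1000)
  st <- cached("eqPV1000", equilibrate(p, b))
  expect_lt(attr(st, "residual"), 1e-4)
  # resting potential near -70 mV (leak plus standing SK current)
  expect_gt(st[["V"]], -72)
  expect_lt(st[["V"]], -68)
  expect_gte(st[["Ca"]], p$Ca_rest * 0.999)
  expect_lt(st[["Ca"]], p$Ca_rest * 1.1)
  # cross-check against the Newton equilibrium at 0 pA
  eq <- find_equilibrium(p, b, 0)
  expect_equal(unname(st[["V"]]), unname(eq$state[["V"]]), tolerance = 1e-3)
})

test_that("holding currents below and above threshold behave as expected", {
  b <- buffer_scheme("pv", 1000)
  st20 <- equilibrate(p, b, hold_current = 20, duration = 2000)
  expect_lt(attr(st20, "residual"), 1e-3)       # subthreshold steady state
  expect_warning(
    st100 <- equilibrate(p, b, hold_current = 100, duration = 2000),
    "spontaneous")                              # sustained spiking at 100 pA
})

test_that("trajectory round-trips to CSV with metadata", {
  b <- buffer_scheme("fast", 50)
  st <- initial_state(p, b)
  traj <- fs_integrate(st, p, b, build_protocol("step", 100, 50))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  first <- readLines(path, n = 1)
  expect_match(first, "^# fsneuron trajectory")
  df <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(df), length(traj$time))
  expect_true(all(c("time_ms", "V_mV", "Ca_uM", "I_SK", "Iapp_pA") %in%
                    names(df)))
  expect_equal(df$V_mV, unname(traj$state[, "V"]), tolerance = 1e-6)
})
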