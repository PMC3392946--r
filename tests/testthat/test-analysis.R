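test_that("spike detection finds upward threshold crossings", {
  # triangular wave crossing 0 mV upward five times
  t <- seq(0, 100, by = 0.1)
  V <- 30 * (2 * abs(((t / 20) + 0.75) %% 1 - 0.5) - 0.5)  # period 20 ms
  traj <- synthetic_traj(t, V)
  sp <- detect_spikes(traj)
  expect_equal(length(sp$times), 5)
  # crossings are interpolated between samples: one per 20-ms period
  expect_equal(sp$times, c(20, 40, 60, 80, 100), tolerance = 0.1)
  # constant subthreshold trace has no spikes
  expect_equal(length(detect_spikes(synthetic_traj(t, rep(-70, length(t))))$times), 0)
})

test_that("refractory guard suppresses double counts relative to accepted spikes", {
  t <- seq(0, 10, by = 0.01)
  V <- rep(-70, length(t))
  V[round(t, 2) %in% c(1, 1.3, 1.6, 5)] <- 10  # near-coincident crossings
  traj <- synthetic_traj(t, V)
  sp <- detect_spikes(traj, refractory = 1)
  expect_equal(length(sp$times), 2)   # 1.0 (1.3, 1.6 guarded) and 5.0
})

test_that("mean frequency implements spikes-per-window and ISI variants", {
  spikes <- seq(10, 990, length.out = 31)      # 31 spikes in 1 s
  expect_equal(mean_frequency(spikes, c(0, 1000)), 31)
  expect_equal(mean_frequency(numeric(0), c(0, 1000)), 0)
  expect_equal(mean_frequency(spikes, c(0, 500)), 2 * sum(spikes < 500))
  expect_equal(mean_frequency(spikes, c(0, 1000), method = "isi"),
               30 / (spikes[31] - spikes[1]) * 1000)
  expect_error(mean_frequency(spikes, c(500, 500)), "window")
})

test_that("envelope extraction recovers exact extrema of a sawtooth", {
  t <- seq(0, 100, by = 0.05)
  period <- 10
  phase <- (t %% period) / period
  V <- ifelse(phase < 0.02, 20, -60)           # narrow spikes every 10 ms
  Ca <- 1 - 0.9 * phase                        # sawtooth: max 1 after spike
  ISK <- 10 + 5 * phase
  traj <- synthetic_traj(t, V, Ca = Ca, ISK = ISK)
  sp <- detect_spikes(traj)
  env <- extract_envelopes(traj, sp)
  expect_equal(nrow(env), length(sp$times) - 1)
  expect_true(all(abs(env$ca_min - 0.1) < 0.01))
  expect_true(all(env$ca_min < env$ca_max))
  expect_true(all(abs(env$ca_max - 1) < 0.05))
  expect_true(all(env$isk_max <= 15 + 1e-9))
  expect_error(extract_envelopes(synthetic_traj(t, rep(-70, length(t)))),
               "2 spikes")
})

test_that("plateau window starts where the lower envelope settles", {
  env <- data.frame(t_start = seq(0, 190, by = 10),
                    t_end = seq(10, 200, by = 10),
                    ca_min = c(seq(0.1, 0.3, length.out = 10), rep(0.3, 10)))
  w <- plateau_window(env, rel_tol = 0.01)
  expect_equal(attr(w, "interval_index"), 10)  # constant from the 10th on
  expect_equal(w[2], 200)
  # never-settling envelope falls back to the preset with a warning
  env$ca_min <- seq(1, 20, length.out = 20)
  expect_warning(w2 <- plateau_window(env, rel_tol = 0.001,
                                      preset = c(4000, 5000)), "plateau")
  expect_equal(as.numeric(w2), c(4000, 5000))
  expect_equal(plateau_preset(build_protocol("step", 100, 5000,
                                             pre_ms = 500)),
               c(4500, 5500))
})

test_that("frequency-concentration sweeps are deterministic", {
  p <- fs_params()
  tab <- frequency_vs_concentration(
    p, "fast", c(100, 100), protocol = build_protocol("step", 100, 500),
    burn_in_ms = 500)
  expect_equal(tab$frequency_Hz[1], tab$frequency_Hz[2])
  expect_equal(tab$scheme, c("fast", "fast"))
  expect_error(frequency_vs_concentration(p, "fast", c(-5)), ">= 0")
})
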