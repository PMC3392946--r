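p <- fs_params()

test_that("currents vanish at their reversal potentials", {
  b <- buffer_scheme("none")
  st <- initial_state(p, b, V = -68)
  I <- ionic_currents(st, p)
  expect_equal(unname(I[["I_leak"]]), 0)
  st <- initial_state(p, b, V = -90)
  I <- ionic_currents(st, p)
  expect_equal(unname(I[["I_SK"]]), 0)
  expect_equal(unname(I[["I_Kv1"]]), 0)
  expect_equal(unname(I[["I_Kv3"]]), 0)
})

test_that("currents match their defining formulas at hand-picked states", {
  st <- c(V = -70, h = 0.5, n1 = 0.3, n3 = 0.4, k = 1, Ca = 0.07)
  I <- ionic_currents(st, p)
  g <- steady_state_gates(-70, p)
  expect_equal(unname(I[["I_SK"]]), 2 * 1 * (-70 + 90))   # 40 pA at k = 1
  expect_equal(unname(I[["I_Kv1"]]), 2 * 0.3^4 * 20)
  expect_equal(unname(I[["I_Kv3"]]), 300 * 0.4^2 * 20)
  expect_equal(unname(I[["I_Na"]]), 700 * g$m_inf^3 * 0.5 * (-70 - 74))
  expect_equal(unname(I[["I_Ca"]]), 30 * g$a_inf^2 * (-70 - 80))
  expect_equal(unname(I[["I_leak"]]), 2.5 * (-70 + 68))
  # squared SK convention doubles down on the open fraction
  p2 <- fs_params(sk_exponent = 2)
  expect_equal(unname(ionic_currents(st, p2)[["I_SK"]]),
               unname(ionic_currents(st, p)[["I_SK"]]))  # k = 1: identical
  st["k"] <- 0.5
  expect_equal(unname(ionic_currents(st, p2)[["I_SK"]]),
               0.5 * unname(ionic_currents(st, p)[["I_SK"]]))
})

test_that("each current changes sign only at its reversal potential", {
  V <- seq(-120, 70, by = 0.5)
  b <- buffer_scheme("none")
  for (v in V) {
    st <- initial_state(p, b, V = v)
    st[c("h", "n1", "n3", "k")] <- 0.5
    I <- ionic_currents(st, p)
    expect_equal(sign(I[["I_Na"]]), sign(v - 74))
    expect_equal(sign(I[["I_SK"]]), sign(v + 90))
    expect_equal(sign(I[["I_Kv3"]]), sign(v + 90))
    expect_equal(sign(I[["I_Ca"]]), sign(v - 80))
    expect_equal(sign(I[["I_leak"]]), sign(v + 68))
  }
})

test_that("pure-capacitor configuration gives dV/dt = I/C", {
  p0 <- fs_params(g_Na = 0, g_Kv1 = 0, g_Kv3 = 0, g_SK = 0, g_Ca = 0,
                  g_leak = 0)
  b <- buffer_scheme("none")
  st <- initial_state(p0, b, V = -70)
  d <- fs_rhs(st, p0, b, I_app = 30)
  expect_equal(unname(d[["V"]]), 1)   # 30 pA / 30 pF = 1 mV/ms
})

test_that("compiled and reference vector fields agree", {
  set.seed(7)
  for (kind in c("none", "pv", "fast")) {
    b <- buffer_scheme(kind, 500)
    for (i in 1:10) {
      st <- initial_state(p, b, V = stats::runif(1, -90, 30))
      st[c("h", "n1", "n3", "k")] <- stats::runif(4)
      st["Ca"] <- 10^stats::runif(1, -1.2, 0.8)
      I <- stats::runif(1, -50, 150)
      d_r <- fs_rhs(st, p, b, I_app = I)
      d_c <- fsneuron:::.cpp_rhs(unname(st), I, fsneuron:::.pack_params(p),
                                 fsneuron:::.pack_rates(p$rates),
                                 fsneuron:::.scheme_code[[b$kind]],
                                 fsneuron:::.pack_scheme(b))
      expect_equal(unname(d_r), d_c, tolerance = 1e-12)
    }
  }
})

test_that("the vector field vanishes at a solved equilibrium", {
  b <- buffer_scheme("pv", 1000)
  eq <- find_equilibrium(p, b, I_app = 20)
  d <- fs_rhs(eq$state, p, b, I_app = 20)
  expect_true(all(abs(d) < 1e-8))
})

test_that("gating variables stay within [0,1] along a spiking trajectory", {
  traj <- cached("bounds_run", {
    b <- buffer_scheme("pv", 1000)
    st <- equilibrate(p, b, duration = 1000)
    fs_integrate(st, p, b, build_protocol("step", 100, 1000))
  })
  for (x in c("h", "n1", "n3", "k")) {
    expect_true(all(traj$state[, x] >= -1e-6))
    expect_true(all(traj$state[, x] <= 1 + 1e-6))
  }
  expect_true(all(traj$state[, "Ca"] > 0))
})

test_that("without SK conductance, excitability decouples from the buffer", {
  p0 <- fs_params(g_SK = 0)
  stim <- build_protocol("step", 100, 1000)
  spikes <- lapply(c(0, 1000), function(bt) {
    b <- if (bt == 0) buffer_scheme("none") else buffer_scheme("pv", bt)
    st <- equilibrate(p0, b, duration = 1000)
    detect_spikes(fs_integrate(st, p0, b, stim))$times
  })
  expect_equal(length(spikes[[1]]), length(spikes[[2]]))
  expect_true(all(abs(spikes[[1]] - spikes[[2]]) < 0.01))
})

test_that("state validation rejects corrupted states", {
  b <- buffer_scheme("pv", 100)
  st <- initial_state(p, b)
  bad <- st; bad["h"] <- 1.5
  expect_error(fsneuron:::check_state(bad, b), "gating")
  bad <- st; bad["Ca"] <- -1
  expect_error(fsneuron:::check_state(bad, b), "Ca")
  bad <- st; bad["PVCa"] <- 200
  expect_error(fsneuron:::check_state(bad, b), "B_T")
})
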