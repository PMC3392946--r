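p <- fs_params()

test_that("calcium balance reproduces hand-computed unit conversions", {
  pv0 <- buffer_scheme("none")
  st <- c(V = -70, h = 0.9, n1 = 0, n3 = 0, k = 0.1, Ca = 0.07)
  # -1 pA inward with no clearance: pure influx term
  p0 <- fs_params(gamma = 0)
  d <- calcium_derivatives(st, I_Ca = -1, p0, pv0)
  expect_equal(unname(d[["Ca"]]), 8.637e-3, tolerance = 1e-4)
  # pure clearance: gamma (Ca - Ca_rest) with Ca 0.1 uM above rest
  st["Ca"] <- 0.17
  d <- calcium_derivatives(st, I_Ca = 0, p, pv0)
  expect_equal(unname(d[["Ca"]]), -0.1, tolerance = 1e-12)
})

test_that("equilibrium occupancy is a fixed point of the binding ODEs", {
  pv <- buffer_scheme("pv", 1000)
  occ <- equilibrium_occupancy(p$Ca_rest, p$Mg_i, pv)
  st <- c(V = -70, h = 0.9, n1 = 0, n3 = 0, k = 0.1, Ca = p$Ca_rest,
          PVCa = occ$bound_ca_uM, PVMg = occ$bound_mg_uM)
  d <- calcium_derivatives(st, I_Ca = 0, p, pv)
  expect_true(all(abs(d) < 1e-9))
  expect_equal(occ$free + occ$bound_ca + occ$bound_mg, 1)
})

test_that("closed-form occupancy matches an ODE-relaxation oracle", {
  skip_if_not_installed("deSolve")
  pv <- buffer_scheme("pv", 1000)
  relax <- function(Ca, Mg) {
    # integrate the binding ODEs at clamped Ca, Mg to steady state
    f <- function(t, y, parms) {
      free <- pv$B_T - y[1] - y[2]
      list(c(pv$k_on_ca * Ca * free - pv$k_off_ca * y[1],
             pv$k_on_mg * Mg * free - pv$k_off_mg * y[2]))
    }
    out <- deSolve::lsoda(c(0, 0), c(0, 5e5), f, NULL,
                          rtol = 1e-12, atol = 1e-12)
    utils::tail(out, 1)[, 2:3] / pv$B_T
  }
  set.seed(42)
  for (i in 1:20) {
    Ca <- 10^stats::runif(1, -2, 1)     # 0.01 to 10 uM
    Mg <- stats::runif(1, 0, 1000)
    occ <- equilibrium_occupancy(Ca, Mg, pv)
    ora <- relax(Ca, Mg)
    expect_equal(occ$bound_ca, unname(ora[1]), tolerance = 1e-6)
    expect_equal(occ$bound_mg, unname(ora[2]), tolerance = 1e-6)
  }
})

test_that("single-site occupancy saturates as expected", {
  fast <- buffer_scheme("fast", 100)
  expect_equal(equilibrium_occupancy(0.01, 0, fast)$bound_ca, 0.5)
  slow <- buffer_scheme("slow", 100)
  expect_lt(abs(equilibrium_occupancy(1e4, 0, slow)$bound_ca - 1), 1e-3)
  expect_error(equilibrium_occupancy(0, 0, fast), "Ca")
})

test_that("buffering capacity follows the differential binding ratio", {
  none <- buffer_scheme("none")
  expect_equal(buffering_capacity(0.1, none), 0)
  fast <- buffer_scheme("fast", 1000)
  expect_equal(buffering_capacity(0.01, fast), 1000 * 0.01 / 0.02^2)
  expect_equal(buffering_capacity(0.01, fast), 25000)
  Ca <- seq(0.01, 10, length.out = 200)
  expect_true(all(diff(buffering_capacity(Ca, fast)) < 0))
  expect_true(all(buffering_capacity(Ca, buffer_scheme("slow", 50)) >= 0))
})

test_that("buffer mass is conserved along a simulated trajectory", {
  traj <- cached("short_pv", {
    b <- buffer_scheme("pv", 1000)
    st <- equilibrate(p, b, duration = 500)
    fs_integrate(st, p, b, build_protocol("step", 100, 500))
  })
  bound <- traj$state[, "PVCa"] + traj$state[, "PVMg"]
  expect_true(all(bound >= 0))
  expect_true(all(bound <= 1000 * (1 + 1e-6)))
  # with single-site schemes BCa stays within [0, B_T] as well
  b2 <- buffer_scheme("fast", 200)
  st2 <- equilibrate(p, b2, duration = 500)
  tr2 <- fs_integrate(st2, p, b2, build_protocol("step", 100, 500))
  expect_true(all(tr2$state[, "BCa"] >= 0 &
                    tr2$state[, "BCa"] <= 200 * (1 + 1e-6)))
})

test_that("a zero-concentration buffer reduces exactly to the unbuffered shell", {
  stim <- build_protocol("step", 100, 300)
  st_none <- initial_state(p, buffer_scheme("none"))
  tr_none <- fs_integrate(st_none, p, buffer_scheme("none"), stim)
  b0 <- buffer_scheme("pv", 0)
  st_b0 <- initial_state(p, b0)
  tr_b0 <- fs_integrate(st_b0, p, b0, stim)
  expect_equal(tr_b0$state[, "V"], tr_none$state[, "V"], tolerance = 1e-12)
  expect_equal(tr_b0$state[, "Ca"], tr_none$state[, "Ca"], tolerance = 1e-12)
})

test_that("magnesium is a fixed parameter, not a state variable", {
  for (kind in c("pv", "slow", "fast", "none"))
    expect_false("Mg" %in% state_names(buffer_scheme(kind, 10)))
})
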