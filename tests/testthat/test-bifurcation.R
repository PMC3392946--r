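p <- fs_params()
pv <- buffer_scheme("pv", 1000)

test_that("Newton solver and numeric Jacobian work on analytic systems", {
  # 2-D system with known root and Jacobian
  f <- function(y) c(y[1]^2 + y[2] - 3, y[1] - y[2])
  sol <- fsneuron:::newton_solve(f, c(2, 0))
  expect_true(sol$ok)
  expect_equal(sol$y, c((sqrt(13) - 1) / 2, (sqrt(13) - 1) / 2),
               tolerance = 1e-8)
  J <- fsneuron:::numeric_jacobian(f, c(1, 2))
  expect_equal(J, rbind(c(2, 1), c(1, -1)), tolerance = 1e-5)
})

test_that("with no voltage-gated conductances the branch is the leak line", {
  p0 <- fs_params(g_Na = 0, g_Kv1 = 0, g_Kv3 = 0, g_SK = 0, g_Ca = 0)
  b <- buffer_scheme("none")
  for (I in c(0, 40, 120)) {
    eq <- find_equilibrium(p0, b, I)
    expect_equal(unname(eq$state[["V"]]), -68 + I / 2.5, tolerance = 1e-6)
    expect_true(eq$stable)
  }
})

test_that("equilibria at reference currents have the expected stability", {
  eq0 <- find_equilibrium(p, pv, 0)
  expect_true(eq0$stable)
  expect_gt(eq0$state[["V"]], -72)
  expect_lt(eq0$state[["V"]], -68)
  expect_lt(eq0$residual, 1e-8)
  expect_equal(length(eq0$eigenvalues), length(state_names(pv)))
  eq20 <- find_equilibrium(p, pv, 20, guess = eq0$state)
  expect_true(eq20$stable)
  # above the Hopf point the focus is unstable (repetitive firing regime)
  g <- eq20$state
  for (I in seq(22, 100, by = 2)) {
    e <- find_equilibrium(p, pv, I, guess = g)
    g <- e$state
    if (I == 100) expect_false(e$stable)
  }
})

test_that("stability flips exactly once along the branch up to 120 pA", {
  br <- cached("branch", equilibrium_branch(p, pv, c(0, 120), step = 2))
  flips <- sum(diff(br$stable[!is.na(br$stable)]) != 0)
  expect_equal(flips, 1)
  # branch is single-valued: multi-start equilibria agree with the branch
  for (I in c(10, 30, 60)) {
    row <- which(br$I_app == I)
    for (V0 in c(-75, -60, -45)) {
      e <- tryCatch(
        find_equilibrium(p, pv, I, guess = initial_state(p, pv, V = V0)),
        error = function(err) NULL)
      if (!is.null(e))
        expect_equal(unname(e$state[["V"]]), br$V[row], tolerance = 1e-4)
    }
  }
})

test_that("the stability change is a Hopf bifurcation with a complex pair", {
  hb <- cached("hopf", find_hopf(p, pv, c(0, 120), tol = 0.1))
  eq <- attr(hb, "equilibrium")
  crit <- eq$eigenvalues[which.max(Re(eq$eigenvalues))]
  expect_gt(abs(Im(crit)), 1e-3)
  # bisection honours its bracket and tolerance
  br <- cached("branch", equilibrium_branch(p, pv, c(0, 120), step = 2))
  last_stable <- max(br$I_app[which(br$stable)])
  expect_gt(as.numeric(hb), last_stable - 2.1)
  expect_lt(as.numeric(hb), last_stable + 2.1)
})

test_that("oscillation classification separates quiescence from spiking", {
  st_quiet <- initial_state(p, pv, V = -67)
  expect_false(fsneuron:::classify_oscillating(p, pv, 10, st_quiet,
                                               settle_ms = 1500, dt = 0.01,
                                               criterion = "persistent"))
  st <- cached("eq_short", equilibrate(p, pv, duration = 1000))
  expect_true(fsneuron:::classify_oscillating(p, pv, 100, st,
                                              settle_ms = 1500, dt = 0.01,
                                              criterion = "persistent"))
  # at 100 pA firing is also regular
  expect_true(fsneuron:::classify_oscillating(p, pv, 100, st,
                                              settle_ms = 1500, dt = 0.01,
                                              criterion = "regular"))
})
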