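# Shared fixtures: a per-file cache so expensive simulations are run once
# per test file, plus constructors for small synthetic trajectories.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# full pipeline for a 100-pA step at a given buffer condition
step_run <- function(bt, kind = "pv", duration = 5000, params = fs_params()) {
  key <- sprintf("step_%s_%s_%s_%s", kind, bt, duration,
                 fsneuron:::params_hash(params))
  cached(key, {
    scheme <- if (bt == 0) buffer_scheme("none")
              else buffer_scheme(kind, B_T = bt)
    st <- equilibrate(params, scheme)
    fs_integrate(st, params, scheme,
                 build_protocol("step", 100, duration))
  })
}

# hand-built trajectory for analysis unit tests (no integration involved)
synthetic_traj <- function(time, V, Ca = NULL, ISK = NULL,
                           scheme = buffer_scheme("none")) {
  n <- length(time)
  if (is.null(Ca)) Ca <- rep(0.1, n)
  if (is.null(ISK)) ISK <- rep(0, n)
  state <- cbind(V = V, h = 0.5, n1 = 0.1, n3 = 0.1, k = 0.2, Ca = Ca)
  currents <- cbind(I_Na = rep(0, n), I_Kv1 = 0, I_Kv3 = 0, I_SK = ISK,
                    I_Ca = 0, I_leak = 0)
  structure(list(time = time, state = state, currents = currents,
                 iapp = rep(0, n), dt = diff(time[1:2]), record_stride = 1L,
                 params = fs_params(), scheme = scheme,
                 stimulus = NULL),
            class = "fs_trajectory")
}
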