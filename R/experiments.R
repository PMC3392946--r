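# Configuration handling and figure-style experiment recipes.

.param_keys <- c("C_m", "g_Na", "g_Kv1", "g_Kv3", "g_SK", "g_Ca", "g_leak",
                 "V_Na", "V_K", "V_Ca", "V_leak", "K_SK", "k_on_sk",
                 "k_off_sk", "gamma", "d", "A", "Ca_rest", "Mg_i", "F",
                 "literal_tau_k", "sk_exponent")
.scheme_keys <- c("scheme", "B_T", "k_on_ca", "k_off_ca", "k_on_mg",
                  "k_off_mg", "k_on", "K_D")
.experiment_keys <- c("name", "concentrations", "protocol", "amplitude",
                      "duration", "pre_ms", "post_ms", "ramp_rate", "dt",
                      "burn_in_ms", "outdir")

#' Validate and resolve a configuration
#'
#' Parses a YAML or JSON configuration (text, file path, or an already-parsed
#' list) into model parameters, a buffer scheme and experiment settings.
#' Unknown keys are rejected with the list of valid keys; keys that are
#' omitted take the model defaults. `K_SK`, if given, rescales `k_off_sk` to
#' `K_SK * k_on_sk` (the half-activation is the ratio of the two rates).
#'
#' @param config a file path, a YAML/JSON string, or a named list.
#' @return List with `params` ([fs_params()]), `scheme` ([buffer_scheme()])
#'   and `experiment` (list of the remaining experiment settings), plus the
#'   resolved flat configuration as `resolved`.
#' @examples
#' cfg <- validate_config("scheme: pv\nB_T: 1000")
#' cfg$scheme$K_D_mg  # 31.25 uM, derived from the rate pair
#' @export
validate_config <- function(config = list()) {
  raw <- if (is.character(config) && length(config) == 1L) {
    if (file.exists(config)) yaml::read_yaml(config)
    else yaml::yaml.load(config)
  } else config
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must parse to a named list")
  valid <- c(.param_keys, .scheme_keys, .experiment_keys)
  unknown <- setdiff(names(raw), valid)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(valid, collapse = ", "))

  pk <- intersect(names(raw), setdiff(.param_keys, "K_SK"))
  pargs <- raw[pk]
  if (!is.null(raw$K_SK)) {
    kon <- raw$k_on_sk %||% 0.4
    pargs$k_on_sk <- kon
    pargs$k_off_sk <- raw$K_SK * kon
  }
  params <- do.call(fs_params, pargs)

  sk <- intersect(names(raw), setdiff(.scheme_keys, "scheme"))
  sargs <- raw[sk]
  sargs$kind <- raw$scheme %||% "pv"
  scheme <- do.call(buffer_scheme, sargs)

  experiment <- raw[intersect(names(raw), .experiment_keys)]
  list(params = params, scheme = scheme, experiment = experiment,
       resolved = c(list(scheme = scheme$kind, B_T = scheme$B_T),
                    params[setdiff(.param_keys, c("literal_tau_k"))],
                    list(literal_tau_k = params$literal_tau_k)))
}

write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a registered figure-style experiment
#'
#' Regenerates the quantitative content of the model's standard analyses
#' from one call. Registered recipes:
#' \describe{
#'   \item{`bifurcation`}{equilibrium branch over 0--120 pA with PV 1000 uM,
#'     Hopf point and oscillation onset (class-2 structure).}
#'   \item{`step_ramp`}{burn-in, 1-s 100-pA step and 1-s 200-pA/s ramp with
#'     PV 1000 uM; trajectories and mean step frequency.}
#'   \item{`summation`}{5-s 100-pA step for PV/slow/fast at low and high
#'     concentrations; calcium envelopes, occupancy and plateau windows.}
#'   \item{`frequency_sweep`}{firing frequency vs. buffer concentration
#'     (0--1500 uM) for all three schemes.}
#'   \item{`sk_amplitude`}{interspike Ca2+ and I_SK statistics at the
#'     steady-state plateau (4th--5th s) for low/high concentrations.}
#'   \item{`custom`}{a frequency sweep with user-supplied scheme and
#'     concentration list.}
#' }
#' Every run writes trajectory/summary files into `outdir` and returns a
#' manifest; all quantities are deterministic.
#'
#' @param name recipe name (see above).
#' @param outdir output directory (created if needed).
#' @param config optional configuration (see [validate_config()]) carrying
#'   parameter overrides, scheme and concentration list.
#' @param dt integration step (ms).
#' @return List of class `fs_experiment`: `name`, `files` (written paths),
#'   `summary` (the key quantities, also written as JSON).
#' @export
run_experiment <- function(name = c("bifurcation", "step_ramp", "summation",
                                    "frequency_sweep", "sk_amplitude",
                                    "custom"),
                           outdir = tempfile("fsneuron_"), config = list(),
                           dt = 0.01) {
  name <- match.arg(name)
  cfg <- validate_config(config)
  params <- cfg$params
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add_file <- function(p) files[[length(files) + 1L]] <<- p
  summary <- list(recipe = name, resolved_config = cfg$resolved)

  lowhigh <- c(50, 1000)   # reference low/high buffer concentrations
  grid <- cfg$experiment$concentrations %||% c(0, 50, 250, 500, 1000, 1500)
  if (name == "custom" && length(grid) == 0)
    stop("custom recipe requires a non-empty concentration list")

  if (name == "bifurcation") {
    scheme <- cfg$scheme
    rep <- bifurcation_report(params, scheme, dt = dt)
    bpath <- file.path(outdir, "equilibrium_branch.csv")
    write.csv(as.data.frame(rep$branch), bpath, row.names = FALSE)
    add_file(bpath)
    summary$i_hb_pa <- rep$I_HB
    summary$i_snlc_pa <- rep$I_osc_onset
    summary$bistability_bracket_pa <- unname(rep$bistability_bracket)
  } else if (name == "step_ramp") {
    scheme <- cfg$scheme
    st <- equilibrate(params, scheme, dt = dt)
    for (proto in c("step", "ramp")) {
      stim <- build_protocol(proto, amplitude = 100, duration = 1000,
                             ramp_rate = 200)
      traj <- fs_integrate(st, params, scheme, stim, dt = dt)
      tpath <- file.path(outdir, paste0("trajectory_", proto, ".csv"))
      write_trajectory_csv(traj, tpath)
      add_file(tpath)
      sp <- detect_spikes(traj)
      f <- mean_frequency(sp, c(0, stim$duration))
      if (proto == "step") summary$mean_frequency_hz <- f
      else summary$ramp_spike_count <- length(sp$times)
    }
  } else if (name == "summation") {
    stim <- build_protocol("step", 100, 5000)
    rows <- list()
    for (kind in c("pv", "slow", "fast")) for (bt in lowhigh) {
      scheme <- buffer_scheme(kind, B_T = bt)
      st <- equilibrate(params, scheme, dt = dt)
      traj <- fs_integrate(st, params, scheme, stim, dt = dt)
      env <- extract_envelopes(traj)
      epath <- file.path(outdir, sprintf("envelope_%s_%g.csv", kind, bt))
      write.csv(as.data.frame(env), epath, row.names = FALSE)
      add_file(epath)
      pw <- plateau_window(env, preset = plateau_preset(stim))
      rows[[length(rows) + 1L]] <-
        data.frame(scheme = kind, B_T = bt, plateau_start_ms = pw[1],
                   occupancy_final = env$occupancy[nrow(env)])
    }
    tab <- do.call(rbind, rows)
    tpath <- file.path(outdir, "plateau_summary.csv")
    write.csv(tab, tpath, row.names = FALSE)
    add_file(tpath)
    summary$plateau <- tab
  } else if (name %in% c("frequency_sweep", "custom")) {
    kinds <- if (name == "custom") cfg$scheme$kind else c("pv", "slow", "fast")
    stim <- build_protocol("step", 100, 5000)
    tab <- do.call(rbind, lapply(kinds, function(kind)
      frequency_vs_concentration(params, kind, grid, protocol = stim,
                                 dt = dt)))
    tpath <- file.path(outdir, "frequency_vs_concentration.csv")
    write.csv(tab, tpath, row.names = FALSE)
    add_file(tpath)
    summary$frequency_table <- tab
    summary$frequency_hz_at_0 <- tab$frequency_Hz[tab$B_T == 0][1]
    if (any(tab$B_T == 1500))
      summary$frequency_hz_at_1500 <- tab$frequency_Hz[tab$B_T == 1500][1]
  } else if (name == "sk_amplitude") {
    stim <- build_protocol("step", 100, 5000)
    win <- plateau_preset(stim)
    rows <- list()
    for (kind in c("pv", "slow", "fast")) for (bt in lowhigh) {
      scheme <- buffer_scheme(kind, B_T = bt)
      st <- equilibrate(params, scheme, dt = dt)
      traj <- fs_integrate(st, params, scheme, stim, dt = dt)
      s <- interspike_stats(traj, win)
      rows[[length(rows) + 1L]] <-
        data.frame(scheme = kind, B_T = bt, ca_isi_min_um = s$ca_min_mean,
                   ca_isi_max_um = s$ca_max_mean,
                   isk_min_pa = s$isk_min_mean, isk_max_pa = s$isk_max_mean,
                   isk_median_pa = s$isk_median,
                   occupancy = s$occupancy_mean)
    }
    tab <- do.call(rbind, rows)
    tpath <- file.path(outdir, "interspike_stats.csv")
    write.csv(tab, tpath, row.names = FALSE)
    add_file(tpath)
    summary$interspike <- tab
    pv <- tab[tab$scheme == "pv", ]
    summary$ca_isi_min_um_pv50 <- pv$ca_isi_min_um[pv$B_T == 50]
    summary$ca_isi_min_um_pv1000 <- pv$ca_isi_min_um[pv$B_T == 1000]
    summary$isk_median_pa_pv50 <- pv$isk_median_pa[pv$B_T == 50]
    summary$isk_max_pa_pv1000 <- pv$isk_max_pa[pv$B_T == 1000]
  }

  spath <- file.path(outdir, "summary.json")
  write_summary_json(summary, spath)
  add_file(spath)
  structure(list(name = name, outdir = outdir, files = unlist(files),
                 summary = summary),
            class = "fs_experiment")
}

#' @export
print.fs_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s' -> %s\n", x$name, x$outdir))
  for (f in x$files) cat("  ", f, "\n", sep = "")
  invisible(x)
}
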