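#' Experiment presets and file-writing entry points
#'
#' Named configurations covering the standard in-silico experiments:
#' single-cell sensitivity scans, wild-type crypts under the imposed-gradient
#' models (both Wnt extents and both contact-inhibition thresholds), the
#' internal division-based model (both reservoir sizes, three noise levels),
#' and the APC double-mutant washout ensembles. The `simulate_*` functions
#' are thin wrappers that run an experiment and write plain-text outputs
#' (CSV/JSON) plus the fully resolved configuration for provenance; they are
#' also the back end of the command-line script shipped in
#' `inst/cli/cryptdyn.R`.
#'
#' @name cli_config
NULL

.flatten_config <- function(cfg) {
  flat <- list()
  add <- function(prefix, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) add(paste0(prefix, nm, "."), v)
      else if (is.numeric(v) || is.character(v) || is.logical(v))
        flat[[paste0(prefix, nm)]] <<- v
    }
  }
  add("", unclass(cfg))
  flat
}

#' List or build an experiment preset
#'
#' @param name preset name; with no argument, returns the available names.
#'   Crypt presets follow the pattern
#'   `fig3_<me1|me2>_w<40|100>_ci<60|90>` (imposed gradient),
#'   `fig4_mi_r<10|20>_s<0|10|20>` (internal model), and
#'   `fig5_washout_<me1|mi>_<low|high>_ci<60|90>`; `fig2a_scan` and
#'   `fig2b_scan` are the single-cell sensitivity analyses.
#' @param t_max override of the simulated duration (h).
#' @param seed RNG seed stored in the configuration.
#' @return For scan presets, a list with `type = "scan"` and grids; for crypt
#'   presets, a list with `type = "crypt"` (or `"washout"`) and an
#'   [engine_config()].
#' @export
experiment_preset <- function(name = NULL, t_max = NULL, seed = 1) {
  me_grid <- expand.grid(model = c("me1", "me2"), w = c(40, 100),
                         ci = c(60, 90), stringsAsFactors = FALSE)
  mi_grid <- expand.grid(r = c(10, 20), s = c(0, 10, 20),
                         stringsAsFactors = FALSE)
  wo_grid <- expand.grid(model = c("me1", "mi"), wnt = c("low", "high"),
                         ci = c(60, 90), stringsAsFactors = FALSE)
  all <- c("fig2a_scan", "fig2b_scan",
           sprintf("fig3_%s_w%d_ci%d", me_grid$model, me_grid$w, me_grid$ci),
           sprintf("fig4_mi_r%d_s%d", mi_grid$r, mi_grid$s),
           sprintf("fig5_washout_%s_%s_ci%d", wo_grid$model, wo_grid$wnt,
                   wo_grid$ci))
  if (is.null(name)) return(all)
  name <- match.arg(name, all)
  if (name == "fig2a_scan")
    return(list(type = "scan", scan = "pH_KH",
                axis1 = seq(0, 60000, length.out = 13),
                axis2 = c(5, 10, 20, 40, 80), W = 1))
  if (name == "fig2b_scan")
    return(list(type = "scan", scan = "W_pH",
                axis1 = seq(0.05, 1, length.out = 12),
                axis2 = seq(0, 60000, length.out = 13)))
  if (grepl("^fig3_", name)) {
    p <- regmatches(name, regexec("fig3_(me[12])_w(\\d+)_ci(\\d+)", name))[[1]]
    cfg <- engine_config(
      wnt = wnt_config(toupper(p[2]), theta_W = as.numeric(p[3]) / 100),
      theta_CI = as.numeric(p[4]) / 100,
      t_max = if (is.null(t_max)) 200 else t_max, seed = seed)
    return(list(type = "crypt", config = cfg, name = name))
  }
  if (grepl("^fig4_", name)) {
    p <- regmatches(name, regexec("fig4_mi_r(\\d+)_s(\\d+)", name))[[1]]
    cfg <- engine_config(
      wnt = wnt_config("MI", rho = as.numeric(p[2]) / 100,
                       sigma = as.numeric(p[3]) / 100),
      theta_CI = 0.6,
      t_max = if (is.null(t_max)) 200 else t_max, seed = seed)
    return(list(type = "crypt", config = cfg, name = name))
  }
  p <- regmatches(name, regexec("fig5_washout_(me1|mi)_(low|high)_ci(\\d+)",
                                name))[[1]]
  wnt <- if (p[2] == "me1") {
    wnt_config("ME1", theta_W = if (p[3] == "low") 0.4 else 1.0)
  } else {
    wnt_config("MI", rho = if (p[3] == "low") 0.1 else 0.2, sigma = 0)
  }
  cfg <- engine_config(wnt = wnt, theta_CI = as.numeric(p[4]) / 100,
                       t_max = if (is.null(t_max)) 1000 else t_max,
                       seed = seed)
  list(type = "washout", config = cfg, name = name)
}

#' Run a single-cell sensitivity scan and write its outputs
#'
#' @param preset `"fig2a_scan"` or `"fig2b_scan"`, or a list with `scan`,
#'   `axis1`, `axis2` (and `W` for the `"pH_KH"` layout).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the scan matrix.
#' @export
simulate_cell <- function(preset = "fig2b_scan", out_dir = "cell_scan") {
  if (is.character(preset)) preset <- experiment_preset(preset)
  if (!identical(preset$type, "scan") && is.null(preset$scan))
    stop("not a scan preset")
  m <- sensitivity_scan(preset$axis1, preset$axis2, scan = preset$scan,
                        W = if (is.null(preset$W)) 1 else preset$W)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scan_csv(m, file.path(out_dir, "durations.csv"))
  write_config(list(scan = preset$scan,
                    axis1 = paste(preset$axis1, collapse = " "),
                    axis2 = paste(preset$axis2, collapse = " "),
                    version = as.character(utils::packageVersion("cryptdyn"))),
               file.path(out_dir, "config.txt"))
  invisible(m)
}

#' Run a crypt simulation and write trajectory, profiles and event log
#'
#' @param config an [engine_config()] or the name of a crypt preset.
#' @param out_dir output directory.
#' @param burn_in burn-in excluded from the profiles (h).
#' @param n_bins height bins for the profiles.
#' @return Invisibly, the `crypt_sim` object.
#' @export
simulate_crypt <- function(config, out_dir = "crypt_run", burn_in = 10,
                           n_bins = 20) {
  if (is.character(config)) config <- experiment_preset(config)$config
  stopifnot(inherits(config, "engine_config"))
  sim <- run_simulation(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$snapshots, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  H <- config$domain$height; W_c <- config$domain$width
  utils::write.csv(mitotic_index_profile(sim$snapshots, H, n_bins, burn_in),
                   file.path(out_dir, "mitotic_index.csv"), row.names = FALSE)
  utils::write.csv(velocity_profile(sim$snapshots, H, W_c, n_bins, burn_in),
                   file.path(out_dir, "velocity.csv"), row.names = FALSE)
  utils::write.csv(wnt_profile(sim$snapshots, H, n_bins, burn_in),
                   file.path(out_dir, "wnt.csv"), row.names = FALSE)
  cfgflat <- .flatten_config(config)
  cfgflat$version <- as.character(utils::packageVersion("cryptdyn"))
  write_config(cfgflat, file.path(out_dir, "config.txt"))
  invisible(sim)
}

#' Run a washout ensemble and write outcome tables
#'
#' @param config an [engine_config()] or the name of a washout preset;
#'   `config$t_max` is the per-run timeout.
#' @param n ensemble size (the reference experiments use 150; small `n`
#'   yields a wide, unreliable confidence interval and triggers a warning).
#' @param base_seed base seed; run `i` derives its own stream from it.
#' @param out_dir output directory.
#' @return Invisibly, the [washout_probability()] result.
#' @export
washout_experiment <- function(config, n = 150, base_seed = 1,
                               out_dir = "washout") {
  if (is.character(config)) config <- experiment_preset(config)$config
  stopifnot(inherits(config, "engine_config"))
  if (n < 10) warning("n < 10: the binomial confidence interval is unreliable")
  runs <- run_washout_ensemble(config, n, base_seed)
  wr <- washout_probability(runs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(runs, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(wr), file.path(out_dir, "washout.json"),
                       auto_unbox = TRUE, digits = NA)
  cfgflat <- .flatten_config(config)
  cfgflat$n <- n; cfgflat$base_seed <- base_seed
  cfgflat$version <- as.character(utils::packageVersion("cryptdyn"))
  write_config(cfgflat, file.path(out_dir, "config.txt"))
  invisible(wr)
}

#' Recompute profiles from a written trajectory
#'
#' @param traj_csv path to a `trajectory.csv` written by [simulate_crypt()].
#' @param H,W_c crypt dimensions used for the run.
#' @param out_dir output directory for the recomputed profiles.
#' @inheritParams simulate_crypt
#' @return Invisibly, a list of the three profiles.
#' @export
analyze_trajectory <- function(traj_csv, H = 20, W_c = 16,
                               out_dir = dirname(traj_csv), burn_in = 10,
                               n_bins = 20) {
  traj <- utils::read.csv(traj_csv)
  out <- list(mitotic = mitotic_index_profile(traj, H, n_bins, burn_in),
              velocity = velocity_profile(traj, H, W_c, n_bins, burn_in),
              wnt = wnt_profile(traj, H, n_bins, burn_in))
  utils::write.csv(out$mitotic, file.path(out_dir, "mitotic_index.csv"),
                   row.names = FALSE)
  utils::write.csv(out$velocity, file.path(out_dir, "velocity.csv"),
                   row.names = FALSE)
  utils::write.csv(out$wnt, file.path(out_dir, "wnt.csv"), row.names = FALSE)
  invisible(out)
}
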