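#' Multiscale crypt engine
#'
#' Orchestrates the coupled loop: spring mechanics on the periodic band,
#' Voronoi volumes, Wnt assignment (imposed gradient or internal
#' division-based), volume-dependent Hippo activation, per-cell signalling and
#' cell-cycle ODE advance, divisions, and sloughing of cells leaving the
#' crypt top. Runs are deterministic given the seed.
#'
#' @name crypt_engine
NULL

#' Engine configuration
#'
#' @param domain a [crypt_domain()].
#' @param mech a [mech_params()].
#' @param wnt a [wnt_config()].
#' @param sig a [signalling_params()].
#' @param cyc a [cycle_params()].
#' @param theta_CI contact-inhibition volume threshold as a fraction of the
#'   equilibrium volume (0.6 or 0.9 in the standard settings).
#' @param V_eq equilibrium cell volume (area); default is the hexagonal
#'   packing area `sqrt(3)/2` at unit spacing.
#' @param t_max simulated time (h).
#' @param snapshot_dt interval between recorded snapshots (h).
#' @param seed RNG seed for the run.
#' @param ode_substeps RK4 substeps of the stiff per-cell signalling advance
#'   per mechanics step.
#' @param cyc_substeps RK4 substeps of the (non-stiff) cycle advance.
#' @param tau_V time constant (h) of the low-pass filter applied to the
#'   Voronoi volume before the contact-inhibition check: the Hippo module
#'   responds to sustained compression, not to the instantaneous
#'   tessellation (which jumps at every division). Daughters inherit the
#'   mother's filtered volume.
#' @param geom_every steps between tessellation rebuilds (newly divided cells
#'   join the tessellation at the next rebuild; removals remap the edge
#'   list).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(domain = crypt_domain(), mech = mech_params(),
                          wnt = wnt_config("ME1", theta_W = 1),
                          sig = signalling_params(), cyc = cycle_params(),
                          theta_CI = 0.9, V_eq = sqrt(3) / 2,
                          t_max = 200, snapshot_dt = 1, seed = 1,
                          ode_substeps = 8, cyc_substeps = 2,
                          geom_every = 5, tau_V = 2) {
  stopifnot(inherits(domain, "crypt_domain"), inherits(mech, "mech_params"),
            inherits(wnt, "wnt_config"), inherits(sig, "signalling_params"),
            inherits(cyc, "cycle_params"),
            theta_CI > 0, theta_CI <= 1, V_eq > 0, t_max >= 0,
            snapshot_dt > 0, ode_substeps >= 1, cyc_substeps >= 1,
            geom_every >= 1, tau_V > 0)
  structure(list(domain = domain, mech = mech, wnt = wnt, sig = sig,
                 cyc = cyc, theta_CI = theta_CI, V_eq = V_eq, t_max = t_max,
                 snapshot_dt = snapshot_dt, seed = seed,
                 ode_substeps = ode_substeps, cyc_substeps = cyc_substeps,
                 geom_every = geom_every, tau_V = tau_V),
            class = "engine_config")
}

#' Effective volume-dependent Hippo sequestration rate
#'
#' Step activation: zero at or above the contact-inhibition threshold
#' `theta_CI * V_eq`, the full rate `pH` below it. Mutants are never contact
#' inhibited; cells whose Voronoi polygon was clipped at the crypt base are
#' excluded (their truncated area is an artefact, not a crowding signal).
#'
#' @param V Voronoi volume(s).
#' @param V_eq equilibrium volume.
#' @param theta_CI threshold fraction.
#' @param pH maximal sequestration rate.
#' @param mutant logical, recycled.
#' @param clipped logical, recycled.
#' @return Vector of effective rates `p_H_hat` in `[0, pH]`.
#' @export
effective_hippo_rate <- function(V, V_eq, theta_CI, pH, mutant = FALSE,
                                 clipped = FALSE) {
  stopifnot(all(V > 0 | is.na(V)), V_eq > 0, theta_CI > 0, pH >= 0)
  out <- ifelse(!is.na(V) & V < theta_CI * V_eq, pH, 0)
  out[rep_len(mutant, length(out))] <- 0
  out[rep_len(clipped, length(out))] <- 0
  out
}

# ---- crypt state ------------------------------------------------------------

# state fields are parallel arrays over active cells (rows 1..n)
.new_state <- function(t, pos, sig, cyc, phase, phase_age, W, wnt_k, mutant,
                       lineage, id, birth, sister, sis_until, next_id,
                       V_ema = NULL, g1_mut = NA_real_) {
  if (is.null(V_ema)) V_ema <- rep(sqrt(3) / 2, nrow(pos))
  structure(list(t = t, n = nrow(pos), pos = pos, sig = sig, cyc = cyc,
                 phase = phase, phase_age = phase_age, W = W, wnt_k = wnt_k,
                 mutant = mutant, lineage = lineage, id = id, birth = birth,
                 sister = sister, sis_until = sis_until, next_id = next_id,
                 V_ema = V_ema, g1_mut = g1_mut),
            class = "crypt_state")
}

.ss_cache <- new.env(parent = emptyenv())

# steady-state signalling over a fixed W grid (cached per parameter set),
# linearly interpolated per cell
.init_signalling <- function(W, sparams) {
  grid <- seq(0, 1, by = 0.04)
  key <- paste(signif(unlist(sparams), 12), collapse = ",")
  ss <- .ss_cache[[key]]
  if (is.null(ss)) {
    ss <- vapply(grid, function(w)
      unclass(steady_state_signalling(sparams, w, 0, rhs_tol = 1e-6))[.sig_ode],
      numeric(length(.sig_ode)))
    .ss_cache[[key]] <- ss
  }
  out <- matrix(0, length(W), length(.sig_ode),
                dimnames = list(NULL, .sig_ode))
  for (q in seq_along(.sig_ode))
    out[, q] <- stats::approx(grid, ss[q, ], xout = W, rule = 2)$y
  out
}

# initial cycle states: cells are seeded at random points of the cycle so the
# population starts desynchronised; non-G1 cells carry a fired switch state
.init_cycle <- function(n, cparams) {
  ic <- cycle_initial_conditions()
  probs <- c(20, cparams$dur_S, cparams$dur_G2, cparams$dur_M)
  phase <- sample.int(4, n, replace = TRUE, prob = probs / sum(probs))
  durs <- c(20, cparams$dur_S, cparams$dur_G2, cparams$dur_M)
  phase_age <- stats::runif(n) * durs[phase]
  cyc <- matrix(rep(ic, each = n), n, 5, dimnames = list(NULL, .cyc_vars))
  fired <- phase > 1
  cyc[fired, "E2F1"] <- 1.05
  cyc[fired, "CycDa"] <- 0.3
  list(cyc = cyc, phase = phase, phase_age = phase_age)
}

#' Initialise a wild-type crypt
#'
#' Cells on a jittered hexagonal lattice filling the domain; signalling at
#' the per-cell Wnt steady state (Hippo off); cycle states seeded at random
#' phases to desynchronise the initial population. Uses the current RNG
#' stream.
#'
#' @param cfg an [engine_config()].
#' @return A `crypt_state`.
#' @export
init_crypt <- function(cfg) {
  stopifnot(inherits(cfg, "engine_config"))
  dom <- cfg$domain
  pos <- hex_lattice(dom)
  pos <- pos + matrix(stats::runif(length(pos), -0.02, 0.02), ncol = 2)
  pos[, 1] <- pos[, 1] %% dom$width
  pos[, 2] <- pmax(pos[, 2], 0.05)
  n <- nrow(pos)
  h <- pmin(pos[, 2] / dom$height, 1)
  W <- if (cfg$wnt$mode == "MI") {
    w <- rep(cfg$wnt$W_max, n)
    apply_reservoir(w, pos[, 2], dom$height, cfg$wnt)
  } else {
    external_wnt(h, cfg$wnt)
  }
  sig <- .init_signalling(W, cfg$sig)
  ci <- .init_cycle(n, cfg$cyc)
  .new_state(t = 0, pos = pos, sig = sig, cyc = ci$cyc, phase = ci$phase,
             phase_age = ci$phase_age, W = W, wnt_k = integer(n),
             mutant = logical(n), lineage = seq_len(n), id = seq_len(n),
             birth = rep(0, n), sister = rep(NA_integer_, n),
             sis_until = rep(-Inf, n), next_id = n + 1L,
             V_ema = rep(cfg$V_eq, n))
}

#' Turn one wild-type cell into an APC double mutant
#'
#' Disables the destruction complex in the cell's signalling (its marking
#' flux is zero at any Wnt level), removes Hippo responsiveness (the cell is
#' never contact inhibited), and fixes its cycle at the maximal-proliferation
#' setting: G1 equal to the wild-type G1 at `W = 1` with Hippo off.
#'
#' @param state a `crypt_state`.
#' @param id cell id to mutate.
#' @param cfg an [engine_config()] (used to derive the mutant G1 duration).
#' @return The modified state.
#' @export
apply_mutation <- function(state, id, cfg) {
  stopifnot(inherits(state, "crypt_state"))
  row <- match(id, state$id)
  if (is.na(row)) stop("no cell with id ", id)
  if (state$mutant[row]) stop("cell ", id, " is already mutant")
  state$mutant[row] <- TRUE
  if (is.na(state$g1_mut))
    state$g1_mut <- .g1_duration(1, 0, cfg$cyc, cfg$sig)
  state
}

#' Remove cells sloughed over the crypt top
#'
#' Cells with centre height above `H` are removed from the simulation.
#'
#' @param state a `crypt_state`.
#' @param domain a [crypt_domain()].
#' @return List with `state` (cells removed) and `removed` (data.frame of t,
#'   id, lineage, mutant of removed cells).
#' @export
remove_sloughed <- function(state, domain) {
  stopifnot(inherits(state, "crypt_state"))
  out <- state$pos[, 2] > domain$height
  removed <- data.frame(t = rep(state$t, sum(out)), id = state$id[out],
                        lineage = state$lineage[out],
                        mutant = state$mutant[out])
  if (any(out)) state <- .subset_state(state, !out)
  list(state = state, removed = removed)
}

.subset_state <- function(state, keep) {
  state$pos <- state$pos[keep, , drop = FALSE]
  state$sig <- state$sig[keep, , drop = FALSE]
  state$cyc <- state$cyc[keep, , drop = FALSE]
  for (f in c("phase", "phase_age", "W", "wnt_k", "mutant", "lineage", "id",
              "birth", "sister", "sis_until", "V_ema"))
    state[[f]] <- state[[f]][keep]
  state$n <- nrow(state$pos)
  state
}

#' Divide one cell
#'
#' The mother record continues as the first daughter; the second daughter is
#' placed 0.1 cell diameters away in a uniformly random direction. Both
#' daughters inherit the mother's signalling state and lineage, reset their
#' cycle variables to the post-mitotic initial conditions, and receive Wnt
#' according to the active Wnt model (imposed models: read at own birth
#' position; internal model: conserved split). Uses the current RNG stream.
#'
#' @param state a `crypt_state`.
#' @param id id of the mother (must have completed M phase in engine use;
#'   not enforced here so the operation can be tested in isolation).
#' @param cfg an [engine_config()].
#' @return The modified state (one extra cell).
#' @export
divide_cell <- function(state, id, cfg) {
  row <- match(id, state$id)
  if (is.na(row)) stop("no cell with id ", id)
  .do_divisions(state, row, cfg)
}

# rows: integer vector of mother rows; processes in row order
.do_divisions <- function(state, rows, cfg) {
  dom <- cfg$domain
  for (row in rows) {
    ang <- stats::runif(1, 0, 2 * pi)
    newpos <- state$pos[row, ] + 0.1 * c(cos(ang), sin(ang))
    newpos[1] <- newpos[1] %% dom$width
    newpos[2] <- max(newpos[2], 0)
    id1 <- state$id[row]
    id2 <- state$next_id
    state$next_id <- state$next_id + 1L
    # Wnt assignment
    if (cfg$wnt$mode == "MI") {
      w <- divide_wnt(state$W[row], cfg$wnt$sigma)
      W1 <- w[1]; W2 <- w[2]
      k2 <- state$wnt_k[row] + 1L
      state$wnt_k[row] <- k2
    } else {
      h1 <- min(state$pos[row, 2] / dom$height, 1)
      h2 <- min(newpos[2] / dom$height, 1)
      W1 <- external_wnt(h1, cfg$wnt)
      W2 <- external_wnt(h2, cfg$wnt)
      k2 <- 0L
    }
    ic <- cycle_initial_conditions()
    state$W[row] <- W1
    state$cyc[row, ] <- ic
    state$phase[row] <- 1L
    state$phase_age[row] <- 0
    state$birth[row] <- state$t
    state$sister[row] <- id2
    state$sis_until[row] <- state$t + cfg$mech$maturation
    # append daughter 2
    state$pos <- rbind(state$pos, newpos)
    state$sig <- rbind(state$sig, state$sig[row, ])
    state$cyc <- rbind(state$cyc, ic)
    state$phase <- c(state$phase, 1L)
    state$phase_age <- c(state$phase_age, 0)
    state$W <- c(state$W, W2)
    state$wnt_k <- c(state$wnt_k, k2)
    state$mutant <- c(state$mutant, state$mutant[row])
    state$V_ema <- c(state$V_ema, state$V_ema[row])
    state$lineage <- c(state$lineage, state$lineage[row])
    state$id <- c(state$id, id2)
    state$birth <- c(state$birth, state$t)
    state$sister <- c(state$sister, id1)
    state$sis_until <- c(state$sis_until, state$t + cfg$mech$maturation)
  }
  state$n <- nrow(state$pos)
  state
}

# ---- main loop --------------------------------------------------------------

#' Run a crypt simulation
#'
#' Executes the multiscale loop from `t = state$t` (or a fresh crypt) until
#' `cfg$t_max`, recording snapshots every `cfg$snapshot_dt` hours and an
#' event log of divisions, removals and phase exits. Deterministic given
#' `cfg$seed` (the seed is set here unless `state` is supplied, in which case
#' the caller owns the RNG stream).
#'
#' @param cfg an [engine_config()].
#' @param state optional `crypt_state` to continue from.
#' @param stop_rule optional function of the state returning `TRUE` to end
#'   the run early (checked once per simulated hour).
#' @return An object of class `crypt_sim`: list with `snapshots` (long-format
#'   data.frame), `events`, `final` (the final `crypt_state`), `config`, and
#'   `stopped_early`.
#' @export
run_simulation <- function(cfg, state = NULL, stop_rule = NULL) {
  stopifnot(inherits(cfg, "engine_config"))
  if (is.null(state)) {
    set.seed(cfg$seed)
    state <- init_crypt(cfg)
  }
  dom <- cfg$domain
  mech <- cfg$mech
  dt <- mech$dt
  spv <- .sp_vec(cfg$sig)
  cpv <- .cp_vec(cfg$cyc)
  # loop-hoisted constants
  wnt_mode <- cfg$wnt$mode
  W_max <- cfg$wnt$W_max; theta_W <- cfg$wnt$theta_W; rho <- cfg$wnt$rho
  H <- dom$height; W_c <- dom$width
  CI_vol <- cfg$theta_CI * cfg$V_eq; pH_max <- cfg$sig$pH
  e2f1_thr <- cfg$cyc$e2f1_threshold
  dur_S <- cfg$cyc$dur_S; dur_G2 <- cfg$cyc$dur_G2; dur_M <- cfg$cyc$dur_M
  n_sub_s <- cfg$ode_substeps; n_sub_c <- cfg$cyc_substeps
  ema_gain <- dt / cfg$tau_V
  n_steps <- max(0L, round((cfg$t_max - state$t) / dt))
  snaps <- list()
  ev_t <- numeric(0); ev_type <- character(0); ev_id <- integer(0)
  ev_lin <- integer(0)
  next_snap <- state$t
  edges <- NULL
  geom_age <- Inf
  areas <- rep(cfg$V_eq, state$n)
  clipped <- rep(FALSE, state$n)
  check_t <- state$t
  stopped <- FALSE
  mut_g1 <- state$g1_mut

  take_snapshot <- function(state, areas, clipped) {
    data.frame(t = state$t, id = state$id, lineage = state$lineage,
               mutant = state$mutant, x = state$pos[, 1], y = state$pos[, 2],
               volume = areas, W = state$W,
               phase = .phases[state$phase], E2F1 = state$cyc[, "E2F1"],
               clipped = clipped)
  }

  for (step in seq_len(n_steps + 1L)) {
    # rebuild tessellation when stale or after topology changes
    if (geom_age >= cfg$geom_every) {
      geom <- cpp_crypt_geometry(state$pos[, 1], state$pos[, 2], W_c,
                                 dom$ytop, mech$cutoff)
      geom_age <- 0
      edges <- geom$edges
      areas <- geom$areas
      clipped <- geom$clipped
    }
    if (state$t >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- take_snapshot(state, areas, clipped)
      next_snap <- next_snap + cfg$snapshot_dt
    }
    if (!is.null(stop_rule) && state$t >= check_t - 1e-9) {
      if (isTRUE(stop_rule(state))) { stopped <- TRUE; break }
      check_t <- check_t + 1
    }
    if (step > n_steps) break
    geom_age <- geom_age + 1

    # --- mechanics -----------------------------------------------------------
    rest <- rep(mech$rest_length, nrow(edges))
    young <- which(state$sis_until > state$t & !is.na(state$sister))
    if (length(young)) {
      # sister-sister springs ramp from newborn_rest to the mature length
      idx <- match(state$sister[young], state$id)
      ok <- !is.na(idx)
      if (any(ok)) {
        a <- young[ok]; b <- idx[ok]
        code <- pmin(a, b) * (state$n + 1) + pmax(a, b)
        ecode <- edges[, 1] * (state$n + 1) + edges[, 2]
        hit <- match(code, ecode)
        frac <- 1 - (state$sis_until[a] - state$t) / mech$maturation
        rl <- mech$newborn_rest +
          (mech$rest_length - mech$newborn_rest) * pmin(pmax(frac, 0), 1)
        rest[hit[!is.na(hit)]] <- rl[!is.na(hit)]
      }
    }
    F <- cpp_spring_forces(state$pos, edges, rest, mech$mu, W_c)
    dr <- F / mech$eta * dt
    if (max(abs(dr)) > 1)
      stop("mechanical instability at t = ", round(state$t, 3))
    state$pos <- state$pos + dr
    state$pos[, 1] <- state$pos[, 1] %% W_c
    state$pos[, 2] <- pmax(state$pos[, 2], 0)

    # --- Wnt field (reservoir refresh after mechanics) -----------------------
    if (wnt_mode == "ME2") {
      h <- pmin(state$pos[, 2] / H, 1)
      state$W <- W_max * pmax(0, 1 - h / theta_W)
    } else if (wnt_mode == "MI") {
      inres <- state$pos[, 2] <= rho * H
      state$W[inres] <- W_max
      state$wnt_k[inres] <- 0L
    }

    # --- Hippo activation and ODE advance ------------------------------------
    ok_a <- !is.na(areas)
    state$V_ema[ok_a] <- state$V_ema[ok_a] +
      ema_gain * (areas[ok_a] - state$V_ema[ok_a])
    pHhat <- ifelse(state$V_ema < CI_vol & !state$mutant & !clipped,
                    pH_max, 0)
    adv <- cpp_advance_cells(state$sig, state$cyc, state$W, pHhat,
                             state$mutant, spv, cpv, dt, n_sub_s, n_sub_c)
    state$sig <- adv$sig
    state$cyc <- adv$cyc
    state$t <- state$t + dt
    state$phase_age <- state$phase_age + dt

    # --- phase transitions ---------------------------------------------------
    wt_exit <- state$phase == 1L & !state$mutant & state$cyc[, "E2F1"] > e2f1_thr
    if (any(state$mutant)) {
      if (is.na(mut_g1)) {
        mut_g1 <- .g1_duration(1, 0, cfg$cyc, cfg$sig)
        state$g1_mut <- mut_g1
      }
      mu_exit <- state$phase == 1L & state$mutant & state$phase_age >= mut_g1
    } else mu_exit <- FALSE
    g1_exit <- wt_exit | mu_exit
    if (any(g1_exit)) {
      state$phase[g1_exit] <- 2L
      state$phase_age[g1_exit] <- 0
    }
    s_done <- state$phase == 2L & state$phase_age >= dur_S
    state$phase[s_done] <- 3L; state$phase_age[s_done] <- 0
    g2_done <- state$phase == 3L & state$phase_age >= dur_G2
    state$phase[g2_done] <- 4L; state$phase_age[g2_done] <- 0
    m_done <- which(state$phase == 4L & state$phase_age >= dur_M)

    # --- divisions -----------------------------------------------------------
    if (length(m_done)) {
      mothers <- state$id[m_done]
      lin <- state$lineage[m_done]
      state <- .do_divisions(state, m_done, cfg)
      ev_t <- c(ev_t, rep(state$t, length(mothers)))
      ev_type <- c(ev_type, rep("division", length(mothers)))
      ev_id <- c(ev_id, mothers)
      ev_lin <- c(ev_lin, lin)
      areas <- c(areas, areas[m_done])
      clipped <- c(clipped, clipped[m_done])
    }

    # --- sloughing -----------------------------------------------------------
    out <- state$pos[, 2] > dom$height
    if (any(out)) {
      ev_t <- c(ev_t, rep(state$t, sum(out)))
      ev_type <- c(ev_type, rep("removal", sum(out)))
      ev_id <- c(ev_id, state$id[out])
      ev_lin <- c(ev_lin, state$lineage[out])
      keep_map <- cumsum(!out)
      keep_map[out] <- NA_integer_
      e_keep <- !is.na(keep_map[edges[, 1]]) & !is.na(keep_map[edges[, 2]])
      edges <- cbind(keep_map[edges[e_keep, 1]], keep_map[edges[e_keep, 2]])
      state <- .subset_state(state, !out)
      areas <- areas[!out]
      clipped <- clipped[!out]
    }
    if (state$n < 4) stop("crypt collapsed (fewer than 4 cells)")
  }

  structure(list(
    snapshots = do.call(rbind, snaps),
    events = data.frame(t = ev_t, event = ev_type, id = ev_id,
                        lineage = ev_lin),
    final = state, config = cfg, stopped_early = stopped),
    class = "crypt_sim")
}

#' @export
print.crypt_sim <- function(x, ...) {
  cat("crypt simulation: t =", round(x$final$t, 2), "h,", x$final$n, "cells,",
      length(unique(x$snapshots$t)), "snapshots,",
      sum(x$events$event == "division"), "divisions\n")
  invisible(x)
}

#' Washout ensemble for an APC double mutant
#'
#' Repeats the mutant experiment `n` times: relax a wild-type crypt, mutate
#' one cell in the bottom 5% of the crypt, and run until the mutant lineage
#' is eliminated (`WASHOUT`), has taken over the whole crypt (`TAKEOVER`,
#' monoclonal conversion), or `t_max` is reached (`TIMEOUT`). Each run uses
#' an independent seed derived from `base_seed`.
#'
#' @param cfg an [engine_config()]; `cfg$t_max` is the per-run timeout.
#' @param n number of runs.
#' @param base_seed base RNG seed.
#' @param relax wild-type relaxation time before the mutation (h).
#' @return data.frame with columns `run`, `seed`, `outcome`, `t_end`.
#' @export
run_washout_ensemble <- function(cfg, n, base_seed = 1, relax = 20) {
  stopifnot(n >= 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- (base_seed * 1000L + i * 7L) %% 2147483647L
    set.seed(seed_i)
    relax_cfg <- cfg
    relax_cfg$t_max <- relax
    sim <- run_simulation(relax_cfg, state = init_crypt(cfg))
    st <- sim$final
    low <- which(st$pos[, 2] <= 0.05 * cfg$domain$height & !st$mutant)
    if (!length(low)) low <- which.min(st$pos[, 2])
    pick <- low[sample.int(length(low), 1)]
    st <- apply_mutation(st, st$id[pick], cfg)
    run_cfg <- cfg
    run_cfg$t_max <- relax + cfg$t_max
    sim2 <- run_simulation(run_cfg, state = st, stop_rule = function(s)
      !any(s$mutant) || all(s$mutant))
    outcome <- if (!any(sim2$final$mutant)) "WASHOUT"
               else if (all(sim2$final$mutant)) "TAKEOVER"
               else "TIMEOUT"
    out[[i]] <- data.frame(run = i, seed = seed_i, outcome = outcome,
                           t_end = sim2$final$t - relax)
  }
  do.call(rbind, out)
}
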