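#' Restriction-point cell-cycle module
#'
#' G1 progression is governed by a five-variable ODE model of the mammalian
#' G1/S transition (pRb, E2F1, inactive and active cyclin D/cdk4-6, and
#' phosphorylated pRb). The mitogenic input of the module is proportional to
#' the transcriptional beta-catenin level `CT` of the signalling network
#' (gain `mu_ct`), so Wnt shortens G1 while Hippo-mediated sequestration of
#' beta-catenin lengthens it and can arrest the cell. The G1 to S transition
#' fires when E2F1 first exceeds 1; S, G2 and M have fixed durations.
#'
#' @name cell_cycle
NULL

.cyc_vars <- c("pRb", "E2F1", "CycDi", "CycDa", "pRbP")
.phases <- c("G1", "S", "G2", "M")

#' Cell-cycle parameters
#'
#' Rate constants of the G1/S restriction-point switch (dimensionless
#' concentrations, hours), fixed S/G2/M durations, the arrest-declaration
#' horizon and the coupling gain from transcriptional beta-catenin to the
#' mitogenic input.
#'
#' @param ... named overrides.
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(...) {
  p <- list(
    # G1/S switch constants
    k1 = 1, k2 = 1.6, k3 = 0.05, k16 = 0.4, k34 = 0.04, k43 = 0.01,
    k61 = 0.3, k23 = 0.3, kp = 0.05, a = 0.04,
    J11 = 0.5, J12 = 5, J13 = 0.002, J61 = 5, J62 = 8, J63 = 2,
    Km1 = 0.5, Km2 = 4, Km4 = 0.3,
    phi_pRb = 0.005, phi_E2F1 = 0.1, phi_CycDi = 0.023,
    phi_CycDa = 0.03, phi_pRbP = 0.06,
    # coupling and phase structure
    tau = 10,         # time-scale of the switch dynamics (multiplies the RHS)
    mu_ct = 0.104,    # mitogenic gain per nM of transcriptional beta-catenin
    e2f1_threshold = 1,
    dur_S = 5, dur_G2 = 4, dur_M = 1,  # fixed phase durations (h)
    T_max = 100                         # arrest-declaration horizon (h)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cycle parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (p$dur_S <= 0 || p$dur_G2 <= 0 || p$dur_M <= 0) stop("phase durations must be > 0")
  if (p$T_max <= p$dur_S + p$dur_G2 + p$dur_M) stop("T_max must exceed a typical cycle length")
  structure(p, class = "cycle_params")
}

#' Post-mitotic initial conditions of the cycle variables
#'
#' The documented reset state applied to both daughters at division: the
#' quiescent branch of the switch with a small seed of active cyclin D/cdk
#' (the active-complex equation has an invariant zero manifold, so a strictly
#' positive seed is required for the switch to be reachable).
#'
#' @return Named numeric vector over the five cycle variables.
#' @export
cycle_initial_conditions <- function() {
  c(pRb = 1.5, E2F1 = 0.1, CycDi = 0.1, CycDa = 0.02, pRbP = 0.1)
}

#' Construct a cell-cycle state
#'
#' @param vars named numeric vector of the five continuous variables.
#' @param phase one of `"G1"`, `"S"`, `"G2"`, `"M"`.
#' @param phase_age time spent in the current phase (h).
#' @return An object of class `cycle_state`.
#' @export
cycle_state <- function(vars = cycle_initial_conditions(), phase = "G1",
                        phase_age = 0) {
  stopifnot(all(.cyc_vars %in% names(vars)), phase %in% .phases, phase_age >= 0)
  if (vars[["E2F1"]] < 0) stop("E2F1 must be >= 0")
  structure(list(vars = vars[.cyc_vars], phase = phase, phase_age = phase_age),
            class = "cycle_state")
}

# internal: rhs of the 5 cycle ODEs given mitogenic input m = mu_ct * CT
.cyc_rhs <- function(v, m, p) {
  R <- v[["pRb"]]; E <- v[["E2F1"]]; Di <- v[["CycDi"]]
  Da <- v[["CycDa"]]; Rp <- v[["pRbP"]]
  act <- Da / (p$Km4 + Da)
  p$tau * c(pRb = p$k1 * (E / (p$Km1 + E)) * (p$J11 / (p$J11 + R)) * (p$J61 / (p$J61 + Rp)) -
        p$k16 * R * Da + p$k61 * Rp - p$phi_pRb * R,
    E2F1 = p$kp + p$k2 * ((p$a^2 + E^2) / (p$Km2^2 + E^2)) *
        (p$J12 / (p$J12 + R)) * (p$J62 / (p$J62 + Rp)) - p$phi_E2F1 * E,
    CycDi = p$k3 * m + p$k23 * E * (p$J13 / (p$J13 + R)) * (p$J63 / (p$J63 + Rp)) +
        p$k43 * Da - p$k34 * Di * act - p$phi_CycDi * Di,
    CycDa = p$k34 * Di * act - (p$k43 + p$phi_CycDa) * Da,
    pRbP = p$k16 * R * Da - p$k61 * Rp - p$phi_pRbP * Rp)
}

#' Time derivatives of the cell-cycle variables
#'
#' @param state a [cycle_state()].
#' @param CT transcriptional beta-catenin level (nM), the coupling input.
#' @param params a [cycle_params()] object.
#' @return Named numeric vector of five derivatives (1/h).
#' @export
cycle_rhs <- function(state, CT, params) {
  stopifnot(inherits(state, "cycle_state"), inherits(params, "cycle_params"))
  if (!is.numeric(CT) || length(CT) != 1 || !is.finite(CT) || CT < 0)
    stop("CT must be a single non-negative number")
  d <- .cyc_rhs(state$vars, params$mu_ct * CT, params)
  if (any(!is.finite(d))) stop("non-finite cycle derivative")
  d
}

#' Has the G1 exit threshold been reached?
#'
#' `TRUE` iff E2F1 strictly exceeds the threshold (default 1). Only valid in
#' G1.
#'
#' @param state a [cycle_state()] in phase G1.
#' @param params a [cycle_params()] object.
#' @return Logical scalar.
#' @export
g1_exit_reached <- function(state, params = cycle_params()) {
  stopifnot(inherits(state, "cycle_state"))
  if (state$phase != "G1") stop("g1_exit_reached() is only defined in G1")
  state$vars[["E2F1"]] > params$e2f1_threshold
}

# internal: coupled 9+5 ODE integration from post-mitotic cycle ICs with the
# signalling network started at its fixed point for (W, pH_hat). Returns the
# G1 duration (first crossing of the E2F1 threshold) or NA if arrested.
.g1_duration <- function(W, pH_hat, cparams, sparams, s0 = NULL) {
  ss <- if (is.null(s0)) steady_state_signalling(sparams, W, pH_hat, rhs_tol = 1e-6)
        else s0
  y0 <- c(unclass(ss)[.sig_ode], cycle_initial_conditions())
  T_tot <- unclass(ss)[["T"]] + unclass(ss)[["CT"]]
  f <- function(t, y, parms) {
    y[y < 0] <- 0
    s9 <- y[seq_along(.sig_ode)]; names(s9) <- .sig_ode
    v <- y[length(.sig_ode) + seq_along(.cyc_vars)]; names(v) <- .cyc_vars
    list(c(.sig_rhs9(s9, sparams, W, pH_hat, T_tot = T_tot),
           .cyc_rhs(v, cparams$mu_ct * s9[["CT"]], cparams)))
  }
  root <- function(t, y, parms) y[length(.sig_ode) + 2] - cparams$e2f1_threshold
  sol <- deSolve::lsodar(y = y0, times = c(0, cparams$T_max), func = f,
                         parms = NULL, rootfunc = root,
                         rtol = 1e-8, atol = 1e-10)
  troot <- attr(sol, "troot")
  if (is.null(troot) || length(troot) == 0) NA_real_ else troot[1]
}

#' Cell-cycle duration under fixed Wnt and Hippo inputs
#'
#' Integrates the coupled signalling + cycle system from the post-mitotic
#' reset, with the signalling network initialised at its fixed point for the
#' given `(W, pH_hat)`, and returns the division-to-division time: the G1
#' duration (time for E2F1 to exceed 1) plus the fixed S, G2 and M durations.
#' Returns `NA` (arrest) if E2F1 never crosses the threshold within `T_max`.
#'
#' @param W Wnt level in `[0, 1]`.
#' @param pH_hat Hippo sequestration rate (nM/h), `>= 0`.
#' @param cparams a [cycle_params()] object.
#' @param sparams a [signalling_params()] object.
#' @return Duration in hours, or `NA_real_` when arrested.
#' @export
cycle_duration <- function(W, pH_hat = 0, cparams = cycle_params(),
                           sparams = signalling_params()) {
  stopifnot(W >= 0, W <= 1, pH_hat >= 0)
  g1 <- .g1_duration(W, pH_hat, cparams, sparams)
  if (is.na(g1)) return(NA_real_)
  g1 + cparams$dur_S + cparams$dur_G2 + cparams$dur_M
}

#' Single-cell sensitivity scan
#'
#' Evaluates [cycle_duration()] over a 2-D parameter grid. Two scan layouts
#' are supported: `"pH_KH"` (sequestration rate against its dissociation
#' constant, at fixed Wnt) and `"W_pH"` (Wnt level against sequestration rate,
#' at the default `KH`). Arrested entries are `NA`.
#'
#' @param axis1,axis2 numeric grids. For `"pH_KH"`: axis1 = pH values, axis2 =
#'   KH values. For `"W_pH"`: axis1 = W values, axis2 = pH values.
#' @param scan layout, `"pH_KH"` or `"W_pH"`.
#' @param W Wnt level used by the `"pH_KH"` layout.
#' @param cparams,sparams model parameters.
#' @return Matrix of durations (rows = axis1, cols = axis2) with the grids as
#'   dimnames; arrested cells are `NA`.
#' @export
sensitivity_scan <- function(axis1, axis2, scan = c("pH_KH", "W_pH"), W = 1,
                             cparams = cycle_params(),
                             sparams = signalling_params()) {
  scan <- match.arg(scan)
  stopifnot(length(axis1) >= 1, length(axis2) >= 1,
            all(is.finite(axis1)), all(is.finite(axis2)))
  m <- matrix(NA_real_, length(axis1), length(axis2),
              dimnames = list(format(axis1, trim = TRUE),
                              format(axis2, trim = TRUE)))
  for (i in seq_along(axis1)) for (j in seq_along(axis2)) {
    m[i, j] <- if (scan == "pH_KH") {
      sp <- sparams; sp$KH <- axis2[j]
      cycle_duration(W, axis1[i], cparams, sp)
    } else {
      cycle_duration(axis1[i], axis2[j], cparams, sparams)
    }
  }
  attr(m, "scan") <- scan
  m
}

#' Write a scan matrix as CSV
#'
#' Axis values become row/column headers; arrested entries are written as
#' empty cells.
#'
#' @param m matrix from [sensitivity_scan()].
#' @param path output file.
#' @export
write_scan_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, na = "", row.names = TRUE)
  invisible(path)
}
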