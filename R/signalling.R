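#' Wnt/beta-catenin signalling network with Hippo-mediated sequestration
#'
#' The subcellular module tracks ten molecular species (all in nM):
#' free Axin (`X`), the active destruction complex (`D`), free adhesive
#' molecules (`A`), free transcription molecules (`T`), and five pools of
#' beta-catenin -- junction-bound (`CA`), cytoplasmic (`CC`), transcriptional/
#' nuclear (`CT`), marked for degradation (`CU`) and sequestered in the
#' YAP-P/beta-catenin complex (`CH`) -- plus a Wnt target protein (`Y`).
#' Transcription molecules are conserved (`T + CT` is constant), so nine ODEs
#' are integrated and `T` is recovered algebraically.
#'
#' Kinetics are mass-action except for two saturable fluxes:
#' \itemize{
#'   \item destruction-complex marking of cytoplasmic beta-catenin,
#'     `pU * D * CC / (KC + CC)`, feeding the degradation-marked pool;
#'   \item Hippo-mediated sequestration, `pH_hat * CC / (KH + CC)`, moving
#'     cytoplasmic beta-catenin into the YAP-P complex `CH`, which decays at
#'     first order (`dH * CH`). `pH_hat` is the *maximal sequestration flux*
#'     (nM/h); the abundance of phosphorylated YAP is absorbed into it, and
#'     `KH` acts as the half-saturation (dissociation) constant.
#' }
#' Wnt raises the three tilde-rates controlling Axin and destruction-complex
#' turnover (`dX`, `dDX`, `dD`) by linear interpolation between their Wnt-off
#' and Wnt-on values; high Wnt destabilises the destruction complex, letting
#' cytoplasmic beta-catenin accumulate and load the transcriptional pool `CT`
#' that drives the cell cycle.
#'
#' @name signalling
NULL

.sig_species <- c("X", "D", "A", "T", "CA", "CC", "CT", "CU", "CH", "Y")
# integrated subset (T eliminated by conservation)
.sig_ode <- c("X", "D", "A", "CA", "CC", "CT", "CU", "CH", "Y")

#' Signalling rate constants
#'
#' Returns the default rate constants of the Wnt/Hippo network. All rates are
#' per hour, concentrations in nM. The Wnt-responsive rates carry `_off`/`_on`
#' suffixes and are interpolated by [wnt_modulated_rates()].
#'
#' @param ... named overrides of individual rates.
#' @return An object of class `signalling_params` (named list).
#' @examples
#' p <- signalling_params()
#' p$KH
#' @export
signalling_params <- function(...) {
  p <- list(
    # Axin / destruction complex
    sX = 25,        # Axin synthesis (nM/h)
    dX_off = 0.5,   # Axin degradation, Wnt off (1/h)
    dX_on = 50,     # Axin degradation, Wnt on (1/h)
    pXD = 100,      # destruction-complex assembly (1/h)
    dDX_off = 5,    # complex disassembly releasing Axin, Wnt off (1/h)
    dDX_on = 50,
    dD_off = 5,     # complex degradation, Wnt off (1/h)
    dD_on = 50,
    # beta-catenin
    sC = 35000,     # synthesis into cytoplasm (nM/h)
    dC = 100,       # basal cytoplasmic decay (1/h)
    pU = 50000,     # marking by destruction complex (1/h per nM of D)
    KC = 100,       # half-saturation of marking (nM)
    dU = 50,        # degradation of marked beta-catenin (1/h)
    # adhesive junctions
    sA = 10,        # synthesis of adhesive molecules (nM/h)
    dA = 0.1,       # decay of free adhesive molecules (1/h)
    pA = 0.1,       # junction binding (1/(nM h))
    dCA = 10,       # junction unbinding (1/h)
    # transcriptional complex (conserved partner pool)
    T_tot = 50,     # total transcription molecules (nM)
    pT = 2,         # nuclear complex formation (1/(nM h))
    dCT = 2000,     # nuclear complex dissociation (1/h)
    # Wnt target protein
    sY = 100,       # maximal target synthesis (nM/h)
    KY = 10,        # half-saturation in CT (nM)
    dY = 1,         # target decay (1/h)
    # Hippo sequestration
    pH = 26000,     # maximal YAP-P/beta-catenin sequestration flux (nM/h)
    KH = 20,        # sequestration half-saturation / dissociation constant (nM)
    dH = 350        # decay of the YAP-P/beta-catenin complex (1/h)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown signalling parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))))
  if (any(unlist(p[setdiff(names(p), "pH")]) <= 0)) stop("all rates must be > 0")
  if (p$pH < 0) stop("pH must be >= 0")
  structure(p, class = "signalling_params")
}

#' Named signalling parameter presets
#'
#' `"wnt_on"` and `"wnt_off"` pin the Wnt-responsive rates at their extreme
#' values (useful for boundary checks); `"default_hippo"` is the default set
#' with the calibrated Hippo constants (`pH` = 26000, `KH` = 20 nM).
#'
#' @param name one of `"wnt_on"`, `"wnt_off"`, `"default_hippo"`.
#' @return A `signalling_params` object.
#' @export
signalling_preset <- function(name = c("default_hippo", "wnt_on", "wnt_off")) {
  name <- match.arg(name)
  p <- signalling_params()
  if (name == "wnt_on") {
    p$dX_off <- p$dX_on; p$dDX_off <- p$dDX_on; p$dD_off <- p$dD_on
  } else if (name == "wnt_off") {
    p$dX_on <- p$dX_off; p$dDX_on <- p$dDX_off; p$dD_on <- p$dD_off
  }
  p
}

#' Wnt modulation of the destruction-complex rates
#'
#' Linearly interpolates the three Wnt-responsive rates between their Wnt-off
#' (`W = 0`) and Wnt-on (`W = 1`) values.
#'
#' @param params a [signalling_params()] object.
#' @param W Wnt level in `[0, 1]`.
#' @return Named vector `c(dX, dDX, dD)` of effective rates (1/h).
#' @export
wnt_modulated_rates <- function(params, W) {
  stopifnot(inherits(params, "signalling_params"))
  if (!is.numeric(W) || length(W) != 1 || !is.finite(W) || W < 0 || W > 1)
    stop("W must be a single value in [0, 1]")
  c(dX  = params$dX_off  + W * (params$dX_on  - params$dX_off),
    dDX = params$dDX_off + W * (params$dDX_on - params$dDX_off),
    dD  = params$dD_off  + W * (params$dD_on  - params$dD_off))
}

#' Construct a signalling state
#'
#' @param X,D,A,CA,CC,CT,CU,CH,Y species concentrations (nM); `T` is derived
#'   from the conserved total `T_tot - CT` when integrating, but can be given
#'   explicitly here for a full 10-species state.
#' @param T_free free transcription molecules; defaults to `50 - CT`.
#' @return Named numeric vector of length 10 with class `signalling_state`.
#' @export
signalling_state <- function(X = 0.5, D = 5, A = 100, CA = 25, CC = 25,
                             CT = 1, CU = 20, CH = 0, Y = 10,
                             T_free = NULL) {
  if (is.null(T_free)) T_free <- 50 - CT
  s <- c(X = X, D = D, A = A, T = T_free, CA = CA, CC = CC, CT = CT,
         CU = CU, CH = CH, Y = Y)
  if (any(!is.finite(s)) || any(s < 0)) stop("signalling state must be finite and non-negative")
  structure(s, class = "signalling_state")
}

# internal: rhs of the 9 integrated species; s9 named vector over .sig_ode,
# T reconstructed from T_tot. Mutant cells have the marking flux disabled.
.sig_rhs9 <- function(s9, params, W, pH_hat, T_tot = params$T_tot,
                      mutant = FALSE) {
  r <- wnt_modulated_rates(params, W)
  X <- s9[["X"]]; D <- s9[["D"]]; A <- s9[["A"]]
  CA <- s9[["CA"]]; CC <- s9[["CC"]]; CT <- s9[["CT"]]
  CU <- s9[["CU"]]; CH <- s9[["CH"]]; Y <- s9[["Y"]]
  Tf <- max(T_tot - CT, 0)
  p <- params
  J_mark <- if (mutant) 0 else p$pU * D * CC / (p$KC + CC)
  J_hippo <- pH_hat * CC / (p$KH + CC)
  J_adh  <- p$pA * A * CC - p$dCA * CA
  J_tcf  <- p$pT * Tf * CC - p$dCT * CT
  c(X  = p$sX - r[["dX"]] * X - p$pXD * X + r[["dDX"]] * D,
    D  = p$pXD * X - (r[["dDX"]] + r[["dD"]]) * D,
    A  = p$sA - p$dA * A - J_adh,
    CA = J_adh,
    CC = p$sC - p$dC * CC - J_mark - J_adh - J_tcf - J_hippo,
    CT = J_tcf,
    CU = J_mark - p$dU * CU,
    CH = J_hippo - p$dH * CH,
    Y  = p$sY * CT / (p$KY + CT) - p$dY * Y)
}

#' Time derivatives of the signalling network
#'
#' Evaluates the right-hand side of the ten-species system at one state. The
#' Hippo term removes cytoplasmic beta-catenin and adds it to the YAP-P
#' complex at the identical instantaneous rate; with `pH_hat = 0` the system
#' reduces to the Wnt-only baseline (the complex only decays).
#'
#' @param state a [signalling_state()] (or named 10-vector).
#' @param params a [signalling_params()] object.
#' @param W Wnt level in `[0, 1]`.
#' @param pH_hat effective volume-dependent sequestration rate, in
#'   `[0, params$pH]` (nM/h).
#' @return Named numeric vector of 10 derivatives (nM/h); `T` mirrors `-CT`.
#' @export
signalling_rhs <- function(state, params, W, pH_hat = 0) {
  stopifnot(inherits(params, "signalling_params"))
  s <- unclass(state)
  if (is.null(names(s)) || !all(.sig_species %in% names(s)))
    stop("state must carry the 10 species names")
  if (any(s < 0)) stop("negative concentrations are not allowed")
  if (!is.finite(pH_hat) || pH_hat < 0 || pH_hat > params$pH)
    stop("pH_hat must lie in [0, pH]")
  T_tot <- s[["T"]] + s[["CT"]]
  d9 <- .sig_rhs9(s[.sig_ode], params, W, pH_hat, T_tot = T_tot)
  if (any(!is.finite(d9))) stop("non-finite derivative: integration failure")
  out <- c(d9, T = -d9[["CT"]])[.sig_species]
  out
}

#' Integrate the signalling network
#'
#' Adaptive Runge-Kutta (4,5) integration (`deSolve::ode`, method `"ode45"`)
#' of the nine-ODE system; free transcription molecules are reconstructed from
#' the conserved total of the initial state.
#'
#' @param s0 initial [signalling_state()].
#' @param params a [signalling_params()] object.
#' @param W Wnt level: a single number or a function of time.
#' @param pH_hat Hippo sequestration rate: a single number or a function of
#'   time.
#' @param t_span numeric of length 2, start and end time (h).
#' @param tol relative tolerance (absolute tolerance is `tol * 1e-3`).
#' @param n_out number of output rows.
#' @return A data.frame with column `t` and the ten species.
#' @export
integrate_signalling <- function(s0, params, W, pH_hat = 0,
                                 t_span = c(0, 100), tol = 1e-6,
                                 n_out = 201) {
  stopifnot(inherits(params, "signalling_params"),
            length(t_span) == 2, all(is.finite(t_span)), tol > 0)
  s <- unclass(s0)
  T_tot <- s[["T"]] + s[["CT"]]
  Wf <- if (is.function(W)) W else function(t) W
  Hf <- if (is.function(pH_hat)) pH_hat else function(t) pH_hat
  if (t_span[2] == t_span[1]) {
    out <- as.data.frame(as.list(c(t = t_span[1], s[.sig_species])))
    return(out)
  }
  times <- seq(t_span[1], t_span[2], length.out = max(2, n_out))
  f <- function(t, y, parms) {
    names(y) <- .sig_ode
    y[y < 0] <- 0
    list(.sig_rhs9(y, params, Wf(t), Hf(t), T_tot = T_tot))
  }
  sol <- deSolve::ode(y = s[.sig_ode], times = times, func = f, parms = NULL,
                      method = "ode45", rtol = tol, atol = tol * 1e-3)
  if (attr(sol, "istate")[1] < 0)
    stop("signalling integration failed near t = ", max(sol[, 1]))
  df <- as.data.frame(sol)
  names(df)[1] <- "t"
  df[df < 0 & !is.na(df)] <- 0
  df$T <- pmax(T_tot - df$CT, 0)
  df[, c("t", .sig_species)]
}

#' Steady state of the signalling network
#'
#' Locates the fixed point at constant Wnt level and Hippo rate by stiff
#' integration until the right-hand side norm falls below `rhs_tol`.
#'
#' @inheritParams integrate_signalling
#' @param rhs_tol convergence threshold on the max-norm of the derivatives
#'   (nM/h).
#' @param t_max maximal integration horizon before giving up (h).
#' @return A [signalling_state()] at the fixed point.
#' @export
steady_state_signalling <- function(params, W, pH_hat = 0, s0 = NULL,
                                    rhs_tol = 1e-8, t_max = 1e5) {
  stopifnot(inherits(params, "signalling_params"))
  if (is.null(s0)) s0 <- signalling_state(T_free = params$T_tot - 1)
  s <- unclass(s0)
  T_tot <- s[["T"]] + s[["CT"]]
  y <- s[.sig_ode]
  f <- function(t, y, parms) {
    names(y) <- .sig_ode
    y[y < 0] <- 0
    list(.sig_rhs9(y, params, W, pH_hat, T_tot = T_tot))
  }
  t_chunk <- 200
  t_done <- 0
  repeat {
    sol <- deSolve::ode(y = y, times = c(0, t_chunk), func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10,
                        maxsteps = 50000)
    y <- pmax(sol[nrow(sol), -1], 0)
    names(y) <- .sig_ode
    t_done <- t_done + t_chunk
    nrm <- max(abs(.sig_rhs9(y, params, W, pH_hat, T_tot = T_tot)))
    if (nrm < rhs_tol) break
    if (t_done >= t_max) stop("steady state not reached within t_max (rhs norm ", signif(nrm, 3), ")")
  }
  do.call(signalling_state, c(as.list(y), list(T_free = max(T_tot - y[["CT"]], 0))))
}

#' Write / read flat key-value parameter files
#'
#' Plain-text serialization (`key: value` per line) for parameter sets and
#' other flat configuration lists.
#'
#' @param x named list of scalars.
#' @param path file path.
#' @return `read_config()` returns a named list.
#' @export
write_config <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    paste0(k, ": ", if (is.character(v)) v else format(v, digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v)) m[3] else v
  })
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}
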