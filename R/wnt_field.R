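#' Wnt field models
#'
#' Three ways of assigning the Wnt level each cell experiences:
#' \describe{
#'   \item{M_E1 (static external)}{an imposed linear gradient read once at
#'     the cell's birth position;}
#'   \item{M_E2 (dynamic external)}{the same gradient re-read continuously at
#'     the cell's current position;}
#'   \item{M_I (internal, division-based)}{Wnt is a conserved cellular
#'     cargo, split between daughters at division in proportions
#'     `0.5 +/- xi` (`xi` zero-mean normal, sd `sigma`, resampled until the
#'     proportion lies in `[0, 1]`), with a basal reservoir (bottom fraction
#'     `rho` of the crypt) where cells are refreshed to the maximal level.}
#' }
#'
#' @name wnt_field
NULL

#' Wnt model configuration
#'
#' @param mode `"ME1"`, `"ME2"` or `"MI"`.
#' @param theta_W extent of the imposed gradient as a fraction of crypt
#'   height (the height at which the external Wnt reaches zero); 0.4 or 1.0
#'   in the standard settings.
#' @param rho reservoir height fraction for the internal model (0.1 or 0.2
#'   in the standard settings).
#' @param sigma standard deviation of the division-split noise (0, 0.1 or
#'   0.2 in the standard settings).
#' @param W_max maximal Wnt level.
#' @return An object of class `wnt_config`.
#' @export
wnt_config <- function(mode = c("ME1", "ME2", "MI"), theta_W = 1,
                       rho = 0.1, sigma = 0, W_max = 1) {
  mode <- match.arg(mode)
  stopifnot(theta_W > 0, theta_W <= 1, rho >= 0, rho < 1, sigma >= 0, W_max > 0)
  structure(list(mode = mode, theta_W = theta_W, rho = rho, sigma = sigma,
                 W_max = W_max), class = "wnt_config")
}

#' Imposed external Wnt gradient
#'
#' Linear decrease from `W_max` at the base to zero at height fraction
#' `theta_W` (and zero above).
#'
#' @param h height fraction(s) in `[0, 1]`.
#' @param cfg a [wnt_config()] with mode `"ME1"` or `"ME2"`.
#' @return Wnt level(s).
#' @export
external_wnt <- function(h, cfg) {
  stopifnot(inherits(cfg, "wnt_config"))
  if (cfg$mode == "MI") stop("external_wnt() requires an external-gradient mode")
  if (any(h < 0 | h > 1)) stop("height fraction must lie in [0, 1]")
  cfg$W_max * pmax(0, 1 - h / cfg$theta_W)
}

#' Wnt level a cell experiences this step
#'
#' `"ME1"`: the value stored at birth. `"ME2"`: the external gradient at the
#' current height. `"MI"`: the cell's internal level.
#'
#' @param W_stored the cell's stored Wnt level (birth value for ME1,
#'   internal cargo for MI).
#' @param h current height fraction in `[0, 1]`.
#' @param cfg a [wnt_config()].
#' @return Wnt level(s) used by the signalling module.
#' @export
cell_wnt <- function(W_stored, h, cfg) {
  stopifnot(inherits(cfg, "wnt_config"))
  switch(cfg$mode,
         ME1 = W_stored,
         ME2 = external_wnt(h, cfg),
         MI = W_stored)
}

#' Split a mother's Wnt between two daughters
#'
#' Daughter 1 receives fraction `f = 0.5 + xi`, daughter 2 the rest, with
#' `xi ~ N(0, sigma^2)` resampled until `f` lies in `[0, 1]` (rejection
#' preserves the zero mean). The split conserves Wnt exactly.
#'
#' @param W_mother mother's Wnt level (`>= 0`).
#' @param sigma split-noise standard deviation (`>= 0`).
#' @return Numeric vector `c(W_d1, W_d2)`.
#' @export
divide_wnt <- function(W_mother, sigma) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  stopifnot(W_mother >= 0)
  f <- 0.5
  if (sigma > 0) {
    repeat {
      f <- 0.5 + stats::rnorm(1, 0, sigma)
      if (f >= 0 && f <= 1) break
    }
  }
  c(f * W_mother, W_mother - f * W_mother)
}

#' Refresh the basal Wnt reservoir
#'
#' Internal-Wnt model only: every cell whose centre height is at most
#' `rho * H` has its Wnt level set to `W_max`; all other cells keep their
#' internal level (no diffusion between cells).
#'
#' @param W internal Wnt levels.
#' @param y cell heights (cell diameters).
#' @param H crypt height.
#' @param cfg a [wnt_config()] with mode `"MI"`.
#' @return Updated Wnt vector.
#' @export
apply_reservoir <- function(W, y, H, cfg) {
  stopifnot(inherits(cfg, "wnt_config"))
  if (cfg$mode != "MI") stop("apply_reservoir() requires the internal Wnt model")
  W[y <= cfg$rho * H] <- cfg$W_max
  W
}
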