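#' Spatial and ensemble statistics
#'
#' Profiles are computed on height bins (fractions of the crypt height `H`),
#' excluding an initial burn-in period from all time averages. Quartiles use
#' linear interpolation (R's default type 7).
#'
#' @name observables
NULL

.bin_heights <- function(y, H, n_bins) {
  h <- pmin(pmax(y / H, 0), 1 - 1e-12)
  pmin(floor(h * n_bins) + 1L, n_bins)
}

.profile_frame <- function(n_bins) {
  data.frame(bin = seq_len(n_bins),
             h_lo = (seq_len(n_bins) - 1) / n_bins,
             h_hi = seq_len(n_bins) / n_bins,
             h_mid = (seq_len(n_bins) - 0.5) / n_bins)
}

#' Mitotic index profile
#'
#' Per height bin, the time-averaged fraction of resident cells in M phase
#' (mean over post-burn-in snapshots of the per-snapshot fraction; snapshots
#' with no resident cells in a bin do not contribute). Bins never populated
#' get `NA`, not 0.
#'
#' @param traj snapshot data.frame from [run_simulation()] (`$snapshots`).
#' @param H crypt height (cell diameters).
#' @param n_bins number of height bins.
#' @param burn_in time excluded from the average (h).
#' @return A `crypt_profile` data.frame with columns `bin`, `h_lo`, `h_hi`,
#'   `h_mid`, `value` (mitotic index), `sd`, `n` (cell-snapshots per bin).
#' @export
mitotic_index_profile <- function(traj, H, n_bins = 20, burn_in = 10) {
  stopifnot(is.data.frame(traj), "phase" %in% names(traj))
  traj <- traj[traj$t >= burn_in, ]
  if (!nrow(traj)) stop("no snapshots after burn-in")
  bin <- .bin_heights(traj$y, H, n_bins)
  isM <- traj$phase == "M"
  fr <- tapply(isM, list(factor(bin, levels = seq_len(n_bins)),
                         factor(traj$t)), mean)
  out <- .profile_frame(n_bins)
  out$value <- apply(fr, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  })
  out$sd <- apply(fr, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  out$n <- as.integer(tabulate(bin, n_bins))
  class(out) <- c("crypt_profile", class(out))
  attr(out, "kind") <- "mitotic_index"
  out
}

# per-cell speeds between consecutive snapshot pairs (central difference),
# with the minimum-image convention in x; returns one row per (cell, time)
.cell_speeds <- function(traj, W_c, burn_in) {
  traj <- traj[order(traj$id, traj$t), ]
  by_id <- split(seq_len(nrow(traj)), traj$id)
  res_y <- res_v <- res_t <- vector("list", length(by_id))
  for (q in seq_along(by_id)) {
    rows <- by_id[[q]]
    if (length(rows) < 3) next
    tt <- traj$t[rows]
    dx <- traj$x[rows[-(1:2)]] - traj$x[rows[seq_len(length(rows) - 2)]]
    dx <- dx - W_c * round(dx / W_c)
    dy <- traj$y[rows[-(1:2)]] - traj$y[rows[seq_len(length(rows) - 2)]]
    dt2 <- tt[-(1:2)] - tt[seq_len(length(rows) - 2)]
    mid <- rows[2:(length(rows) - 1)]
    res_v[[q]] <- sqrt(dx^2 + dy^2) / dt2
    res_y[[q]] <- traj$y[mid]
    res_t[[q]] <- tt[2:(length(rows) - 1)]
  }
  out <- data.frame(t = unlist(res_t), y = unlist(res_y),
                    speed = unlist(res_v))
  out[out$t >= burn_in, ]
}

#' Velocity profile (box-whisker statistics per height bin)
#'
#' Per-cell speeds from central differences of consecutive snapshot
#' positions, binned by height: median, quartiles (linear interpolation) and
#' the most extreme values recorded.
#'
#' @inheritParams mitotic_index_profile
#' @param W_c crypt circumference (for the periodic x-difference).
#' @return A `crypt_profile` data.frame with columns `bin`, `h_lo`, `h_hi`,
#'   `h_mid`, `value` (median speed), `q25`, `q75`, `lo`, `hi`, `n`.
#' @export
velocity_profile <- function(traj, H, W_c, n_bins = 20, burn_in = 10) {
  stopifnot(is.data.frame(traj))
  if (length(unique(traj$t)) < 2) stop("need at least 2 snapshots")
  sp <- .cell_speeds(traj, W_c, burn_in)
  if (!nrow(sp)) stop("no speed samples after burn-in")
  bin <- .bin_heights(sp$y, H, n_bins)
  out <- .profile_frame(n_bins)
  qs <- function(b, p) {
    v <- sp$speed[bin == b]
    if (!length(v)) NA_real_ else unname(stats::quantile(v, p, type = 7))
  }
  out$value <- vapply(seq_len(n_bins), qs, numeric(1), p = 0.5)
  out$q25 <- vapply(seq_len(n_bins), qs, numeric(1), p = 0.25)
  out$q75 <- vapply(seq_len(n_bins), qs, numeric(1), p = 0.75)
  out$lo <- vapply(seq_len(n_bins), function(b) {
    v <- sp$speed[bin == b]; if (!length(v)) NA_real_ else min(v) }, numeric(1))
  out$hi <- vapply(seq_len(n_bins), function(b) {
    v <- sp$speed[bin == b]; if (!length(v)) NA_real_ else max(v) }, numeric(1))
  out$n <- as.integer(tabulate(bin, n_bins))
  class(out) <- c("crypt_profile", class(out))
  attr(out, "kind") <- "velocity"
  out
}

#' Mean crypt cell speed
#'
#' Mean of all per-cell speeds over post-burn-in snapshots (the summary used
#' for condition-to-condition comparisons).
#'
#' @inheritParams velocity_profile
#' @return A single number (cell diameters per hour).
#' @export
mean_crypt_velocity <- function(traj, W_c, burn_in = 10) {
  sp <- .cell_speeds(traj, W_c, burn_in)
  if (!nrow(sp)) stop("no speed samples after burn-in")
  mean(sp$speed)
}

#' Wnt profile (mean and standard deviation per height bin)
#'
#' Pooled over cells and post-burn-in snapshots.
#'
#' @inheritParams mitotic_index_profile
#' @return A `crypt_profile` data.frame with `value` (mean W), `sd`, `n`.
#' @export
wnt_profile <- function(traj, H, n_bins = 20, burn_in = 10) {
  stopifnot(is.data.frame(traj), "W" %in% names(traj))
  traj <- traj[traj$t >= burn_in, ]
  if (!nrow(traj)) stop("no snapshots after burn-in")
  bin <- .bin_heights(traj$y, H, n_bins)
  out <- .profile_frame(n_bins)
  out$value <- vapply(seq_len(n_bins), function(b) {
    v <- traj$W[bin == b]; if (!length(v)) NA_real_ else mean(v) }, numeric(1))
  out$sd <- vapply(seq_len(n_bins), function(b) {
    v <- traj$W[bin == b]; if (length(v) < 2) NA_real_ else stats::sd(v) },
    numeric(1))
  out$n <- as.integer(tabulate(bin, n_bins))
  class(out) <- c("crypt_profile", class(out))
  attr(out, "kind") <- "wnt"
  out
}

#' Washout probability with a normal-approximation confidence interval
#'
#' `p = k / n` over the valid (non-timeout) runs, with the 95% interval
#' `p +/- z * sqrt(p (1 - p) / n)`, `z = 1.959964` (the 97.5 percentile of a
#' standard normal), clipped to `[0, 1]`. Timeouts are excluded from the
#' denominator and reported separately.
#'
#' @param outcomes character vector (or the data.frame from
#'   [run_washout_ensemble()]) of `"WASHOUT"`, `"TAKEOVER"`, `"TIMEOUT"`.
#' @return An object of class `washout_result`: list with `k`, `n`, `p`,
#'   `ci_low`, `ci_high`, `z`, `n_timeout`.
#' @export
washout_probability <- function(outcomes) {
  if (is.data.frame(outcomes)) outcomes <- outcomes$outcome
  outcomes <- as.character(outcomes)
  bad <- setdiff(outcomes, c("WASHOUT", "TAKEOVER", "TIMEOUT"))
  if (length(bad)) stop("unknown outcome(s): ", paste(unique(bad), collapse = ", "))
  n_timeout <- sum(outcomes == "TIMEOUT")
  valid <- outcomes[outcomes != "TIMEOUT"]
  n <- length(valid)
  if (n < 1) stop("no valid (non-timeout) outcomes")
  k <- sum(valid == "WASHOUT")
  p <- k / n
  z <- 1.959964
  half <- z * sqrt(p * (1 - p) / n)
  structure(list(k = k, n = n, p = p,
                 ci_low = max(0, p - half), ci_high = min(1, p + half),
                 z = z, n_timeout = n_timeout),
            class = "washout_result")
}

#' @export
print.washout_result <- function(x, ...) {
  cat(sprintf("washout probability %.3f (%d/%d), 95%% CI [%.3f, %.3f]",
              x$p, x$k, x$n, x$ci_low, x$ci_high))
  if (x$n_timeout) cat(",", x$n_timeout, "timeout(s) excluded")
  cat("\n")
  invisible(x)
}

#' Percent change between two condition summaries
#'
#' `100 (a - b) / a`: positive values are reductions from `a` to `b`.
#'
#' @param a reference value (non-zero).
#' @param b comparison value.
#' @return Percent change.
#' @export
relative_change <- function(a, b) {
  if (any(a == 0)) stop("reference value must be non-zero")
  100 * (a - b) / a
}

#' Locate the dip-then-rise feature of a mitotic-index profile
#'
#' For the internal (division-based) Wnt model the noiseless mitotic profile
#' dips above the reservoir and then rises sharply where the first
#' post-reservoir divisions occur. Scanning upward above the reservoir, this
#' returns the height fraction of the local minimum that immediately precedes
#' the largest upward jump of the profile.
#'
#' @param profile a `crypt_profile` from [mitotic_index_profile()].
#' @param rho reservoir height fraction (search starts above it).
#' @param h_max upper end of the search window (height fraction).
#' @return Height fraction (midpoint of the minimum bin), or `NA` if the
#'   profile has no rise in the window.
#' @export
mitotic_rise_location <- function(profile, rho = 0.1, h_max = 0.8) {
  stopifnot(inherits(profile, "crypt_profile"))
  p <- profile[profile$h_mid > rho & profile$h_mid <= h_max & !is.na(profile$value), ]
  if (nrow(p) < 3) return(NA_real_)
  jumps <- diff(p$value)
  if (max(jumps) <= 0) return(NA_real_)
  j <- which.max(jumps)
  # walk left from the jump to the local minimum
  while (j > 1 && p$value[j - 1] <= p$value[j]) j <- j - 1
  p$h_mid[j]
}
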