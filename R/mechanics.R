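#' Cell-centre mechanics on the unrolled periodic crypt
#'
#' The crypt cylinder is unrolled to a planar band, periodic in `x` with
#' period equal to the crypt circumference. Each cell is a point connected to
#' its Delaunay neighbours by linear springs; motion is overdamped. Cell
#' "volumes" are Voronoi areas of the tessellation, clipped to the band
#' `y` in `[0, H + 0.5]`; mirror images across the base and the clip top
#' bound every Voronoi polygon. Cells whose polygon touches the base plane
#' are flagged (`clipped`) and excluded from volume-based contact
#' inhibition (an area truncated at the crypt wall is not a crowding
#' signal; the top plane merely caps the open orifice).
#'
#' @name mechanics
NULL

#' Crypt domain geometry
#'
#' @param width crypt circumference `W_c` in cell diameters.
#' @param height crypt height `H` in cell diameters.
#' @return An object of class `crypt_domain`.
#' @export
crypt_domain <- function(width = 16, height = 20) {
  stopifnot(width > 0, height > 0)
  structure(list(width = width, height = height, ytop = height + 0.5),
            class = "crypt_domain")
}

#' Mechanical parameters
#'
#' Defaults follow the conventions of cell-centre crypt models: unit drag,
#' time step 1/120 h, mature rest length of one cell diameter, and a newborn
#' sister-sister rest length growing linearly from 0.1 to 1 diameter over the
#' first hour after division. The spring stiffness (60 force units per cell
#' diameter) is calibrated so that homeostatic packing sits between the two
#' standard contact-inhibition thresholds; the time step sits at the
#' overdamped stability bound `dt <= eta / (4 mu)`.
#'
#' @param ... named overrides.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(...) {
  p <- list(mu = 60, eta = 1, dt = 1 / 240, rest_length = 1,
            newborn_rest = 0.1, maturation = 1, cutoff = 1.5)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown mechanical parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (p$mu <= 0 || p$eta <= 0 || p$dt <= 0) stop("mu, eta, dt must be > 0")
  if (p$newborn_rest >= p$rest_length) stop("newborn rest length must be below the mature one")
  if (p$dt > p$eta / (4 * p$mu)) stop("dt exceeds the stability bound eta/(4 mu)")
  structure(p, class = "mech_params")
}

#' Neighbour graph of a cell configuration
#'
#' Delaunay adjacency with periodic wrapping in `x` (ghost replication),
#' pruned of edges longer than `cutoff` (minimum-image metric).
#'
#' @param positions n x 2 matrix of cell centres (x, y), in cell diameters.
#' @param domain a [crypt_domain()].
#' @param cutoff maximal edge length retained (cell diameters).
#' @return Integer matrix (m x 2) of 1-based cell index pairs, `i < j`.
#' @export
neighbour_graph <- function(positions, domain, cutoff = 1.5) {
  stopifnot(inherits(domain, "crypt_domain"), nrow(positions) >= 3)
  g <- cpp_crypt_geometry(positions[, 1], positions[, 2], domain$width,
                          domain$ytop, cutoff)
  g$edges
}

#' Voronoi cell areas on the periodic band
#'
#' Areas of the Voronoi regions (the model's cell "volumes"), clipped to
#' `y` in `[0, H + 0.5]`. The clipped areas partition the band exactly.
#'
#' @inheritParams neighbour_graph
#' @return List with `areas` (numeric) and `clipped` (logical: polygon
#'   touched the base plane; such volumes are excluded from contact
#'   inhibition).
#' @export
cell_volumes <- function(positions, domain) {
  stopifnot(inherits(domain, "crypt_domain"), nrow(positions) >= 3)
  g <- cpp_crypt_geometry(positions[, 1], positions[, 2], domain$width,
                          domain$ytop, cutoff = 1.5)
  list(areas = g$areas, clipped = g$clipped)
}

#' Pairwise spring forces
#'
#' Linear (Hookean) forces along the minimum-image separation of each edge;
#' equal and opposite on the two endpoints.
#'
#' @param positions n x 2 matrix of cell centres.
#' @param edges m x 2 integer matrix of index pairs.
#' @param rest rest length per edge (recycled if scalar).
#' @param mu spring stiffness.
#' @param domain a [crypt_domain()] (for the periodic width).
#' @return n x 2 matrix of forces.
#' @export
spring_forces <- function(positions, edges, rest, mu, domain) {
  stopifnot(inherits(domain, "crypt_domain"))
  if (length(rest) == 1) rest <- rep(rest, nrow(edges))
  stopifnot(length(rest) == nrow(edges), all(rest > 0))
  cpp_spring_forces(positions, edges, rest, mu, domain$width)
}

#' Overdamped position update
#'
#' `dr = (F / eta) dt`; `x` is wrapped into `[0, W_c)` and `y` clamped at the
#' crypt base (`y >= 0`). Signals instability if any displacement exceeds one
#' cell diameter.
#'
#' @param positions n x 2 matrix.
#' @param forces n x 2 matrix.
#' @param eta drag coefficient.
#' @param dt time step (h).
#' @param domain a [crypt_domain()].
#' @return Updated n x 2 matrix.
#' @export
step_positions <- function(positions, forces, eta, dt, domain) {
  stopifnot(inherits(domain, "crypt_domain"), eta > 0, dt > 0)
  dr <- forces / eta * dt
  if (any(sqrt(rowSums(dr^2)) > 1))
    stop("mechanical instability: displacement exceeds one cell diameter in a step")
  p <- positions + dr
  p[, 1] <- p[, 1] %% domain$width
  p[, 2] <- pmax(p[, 2], 0)
  p
}

#' Cell speed from a position history
#'
#' Central-difference displacement over a window of samples, minimum-image in
#' `x`.
#'
#' @param history k x 2 matrix of successive positions of one cell (rows =
#'   samples).
#' @param dt time between samples (h).
#' @param domain a [crypt_domain()].
#' @return Speed (cell diameters per hour) at the central sample(s): a vector
#'   of length `k - 2` (or length 1 forward difference if `k == 2`).
#' @export
cell_velocity <- function(history, dt, domain) {
  stopifnot(inherits(domain, "crypt_domain"))
  k <- nrow(history)
  if (is.null(k) || k < 2) stop("need at least 2 samples")
  W <- domain$width
  mi <- function(d) d - W * round(d / W)
  if (k == 2) {
    dx <- mi(history[2, 1] - history[1, 1]); dy <- history[2, 2] - history[1, 2]
    return(sqrt(dx^2 + dy^2) / dt)
  }
  i <- 2:(k - 1)
  dx <- mi(history[i + 1, 1] - history[i - 1, 1])
  dy <- history[i + 1, 2] - history[i - 1, 2]
  sqrt(dx^2 + dy^2) / (2 * dt)
}

#' Hexagonal seed lattice for the crypt
#'
#' Rows of horizontally offset cells at vertical spacing `sqrt(3)/2`, with a
#' small deterministic jitter to keep the tessellation in general position.
#'
#' @param domain a [crypt_domain()].
#' @param spacing lattice constant (cell diameters).
#' @param y0 height of the first row.
#' @return n x 2 position matrix.
#' @export
hex_lattice <- function(domain, spacing = 1, y0 = 0.25) {
  stopifnot(inherits(domain, "crypt_domain"))
  nx <- max(3, round(domain$width / spacing))
  dy <- spacing * sqrt(3) / 2
  ys <- seq(y0, domain$height - 0.4, by = dy)
  pos <- do.call(rbind, lapply(seq_along(ys), function(j) {
    xs <- (seq_len(nx) - 1 + ifelse(j %% 2 == 0, 0.5, 0)) * (domain$width / nx)
    cbind(xs, ys[j])
  }))
  jit <- 1e-4 * sin(1e3 * seq_len(nrow(pos)) + 0.3)
  pos[, 1] <- (pos[, 1] + jit) %% domain$width
  pos[, 2] <- pos[, 2] + rev(jit)
  dimnames(pos) <- NULL
  pos
}
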