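# Independent oracles used across the suite.

# fixed-step classical RK4 on the 9 integrated signalling species
rk4_signalling <- function(s0, params, W, pH_hat, t_end, dt) {
  y <- unclass(s0)[cryptdyn:::.sig_ode]
  T_tot <- unclass(s0)[["T"]] + unclass(s0)[["CT"]]
  f <- function(y) cryptdyn:::.sig_rhs9(pmax(y, 0), params, W, pH_hat,
                                        T_tot = T_tot)
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  y
}

# total spring energy of a configuration (periodic in x)
spring_energy <- function(pos, edges, rest, mu, W_c) {
  dx <- pos[edges[, 2], 1] - pos[edges[, 1], 1]
  dx <- dx - W_c * round(dx / W_c)
  dy <- pos[edges[, 2], 2] - pos[edges[, 1], 2]
  d <- sqrt(dx^2 + dy^2)
  sum(0.5 * mu * (d - rest)^2)
}

# force on each cell as minus the central finite-difference energy gradient
fd_forces <- function(pos, edges, rest, mu, W_c, h = 1e-6) {
  F <- matrix(0, nrow(pos), 2)
  for (i in seq_len(nrow(pos))) for (q in 1:2) {
    pp <- pos; pp[i, q] <- pp[i, q] + h
    pm <- pos; pm[i, q] <- pm[i, q] - h
    F[i, q] <- -(spring_energy(pp, edges, rest, mu, W_c) -
                 spring_energy(pm, edges, rest, mu, W_c)) / (2 * h)
  }
  F
}

# tiny crypt configuration for fast engine tests
tiny_config <- function(t_max = 5, seed = 7, mode = "ME1", theta_W = 1,
                        theta_CI = 0.9, rho = 0.1, sigma = 0, ...) {
  wnt <- if (mode == "MI") wnt_config("MI", rho = rho, sigma = sigma)
         else wnt_config(mode, theta_W = theta_W)
  engine_config(domain = crypt_domain(8, 10), wnt = wnt,
                theta_CI = theta_CI, t_max = t_max, seed = seed, ...)
}
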