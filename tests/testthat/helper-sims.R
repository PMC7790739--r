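# Shared crypt simulations for the slower scientific tests, built lazily on
# first request and cached for the session. The imposed-gradient comparisons
# run on the full 16 x 20 reference crypt (110 h, one seed) because the
# velocity and profile statistics are height-sensitive; the internal-Wnt and
# division-based Wnt runs also use the full crypt (120 h); only the
# dynamic-gradient ordering check uses a reduced 12 x 16 crypt.

.sim_cache <- new.env(parent = emptyenv())

test_crypt_sim <- function(name) {
  if (!is.null(.sim_cache[[name]])) return(.sim_cache[[name]])
  spec <- switch(name,
    me1_w10_ci06 = list(wnt = wnt_config("ME1", theta_W = 1.0), ci = 0.6,
                        dom = crypt_domain(16, 20), t_max = 110),
    me1_w10_ci09 = list(wnt = wnt_config("ME1", theta_W = 1.0), ci = 0.9,
                        dom = crypt_domain(16, 20), t_max = 110),
    me1_w04_ci06 = list(wnt = wnt_config("ME1", theta_W = 0.4), ci = 0.6,
                        dom = crypt_domain(16, 20), t_max = 110),
    me2_w04_ci06 = list(wnt = wnt_config("ME2", theta_W = 0.4), ci = 0.6,
                        dom = crypt_domain(12, 16), t_max = 70),
    mi_r01_s0    = list(wnt = wnt_config("MI", rho = 0.1, sigma = 0), ci = 0.6,
                        dom = crypt_domain(16, 20), t_max = 120),
    mi_r02_s0    = list(wnt = wnt_config("MI", rho = 0.2, sigma = 0), ci = 0.6,
                        dom = crypt_domain(16, 20), t_max = 120),
    mi_r01_s02   = list(wnt = wnt_config("MI", rho = 0.1, sigma = 0.2), ci = 0.6,
                        dom = crypt_domain(16, 20), t_max = 120),
    stop("unknown test simulation: ", name))
  cfg <- engine_config(domain = spec$dom, wnt = spec$wnt,
                       theta_CI = spec$ci, t_max = spec$t_max, seed = 20)
  .sim_cache[[name]] <- run_simulation(cfg)
  .sim_cache[[name]]
}

test_burn_in <- 30

# mean mitotic index over the near-base bins, excluding the wall-contact bin
# (bin 1), whose Voronoi volumes are clipped at the base plane
base_mitotic <- function(profile) mean(profile$value[2:4], na.rm = TRUE)

# upper third of the bins that remain proliferative in the reference profile
top_niche_bins <- function(prof06) {
  niche <- which(prof06$value > 0.2 * max(prof06$value, na.rm = TRUE))
  niche[niche > max(niche) - ceiling(length(niche) / 3)]
}
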