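test_that("effective Hippo rate follows the step threshold rule", {
  Veq <- sqrt(3) / 2
  expect_equal(effective_hippo_rate(Veq, Veq, 0.9, 26000), 0)
  expect_equal(effective_hippo_rate(0.5 * Veq, Veq, 0.6, 26000), 26000)
  expect_equal(effective_hippo_rate(0.7 * Veq, Veq, 0.6, 26000), 0)
  expect_equal(effective_hippo_rate(0.7 * Veq, Veq, 0.9, 26000), 26000)
  # mutants and boundary-clipped cells are never inhibited
  expect_equal(effective_hippo_rate(0.1, Veq, 0.9, 26000, mutant = TRUE), 0)
  expect_equal(effective_hippo_rate(0.1, Veq, 0.9, 26000, clipped = TRUE), 0)
  # non-increasing in V
  v <- effective_hippo_rate(c(0.3, 0.6, 0.9), Veq, 0.9, 26000)
  expect_true(all(diff(v) <= 0))
})

test_that("mutation disables destruction marking without touching others", {
  set.seed(2)
  cfg <- tiny_config(t_max = 0)
  st <- init_crypt(cfg)
  st2 <- apply_mutation(st, id = 5, cfg)
  expect_true(st2$mutant[5])
  expect_false(any(st2$mutant[-5]))
  expect_identical(st2$sig[-5, ], st$sig[-5, ])   # locality
  expect_error(apply_mutation(st2, 5, cfg), "already mutant")
  # the marking flux is zero for the mutant at any Wnt level
  spv <- cryptdyn:::.sp_vec(cfg$sig)
  cpv <- cryptdyn:::.cp_vec(cfg$cyc)
  adv <- cryptdyn:::cpp_advance_cells(st2$sig, st2$cyc, rep(0, st2$n),
                                      rep(0, st2$n), st2$mutant, spv, cpv,
                                      0.5, 1200, 20)
  # at W = 0 a wild-type cell keeps high destruction and low CC; the mutant
  # accumulates beta-catenin towards sC/dC
  expect_gt(adv$sig[5, "CC"], 5 * median(adv$sig[-5, "CC"]))
})

test_that("division inherits lineage and splits internal Wnt conservatively", {
  set.seed(4)
  cfg <- tiny_config(t_max = 0, mode = "MI", sigma = 0)
  st <- init_crypt(cfg)
  st$W[3] <- 0.8
  n0 <- st$n
  st2 <- divide_cell(st, id = st$id[3], cfg)
  expect_equal(st2$n, n0 + 1)
  expect_equal(st2$W[3], 0.4)
  expect_equal(st2$W[st2$n], 0.4)
  expect_equal(st2$lineage[st2$n], st$lineage[3])
  expect_equal(st2$mutant[st2$n], st$mutant[3])
  # daughters inherit the mother's signalling state
  expect_equal(unname(st2$sig[st2$n, ]), unname(st$sig[3, ]))
  # cycle reset for both
  ic <- cycle_initial_conditions()
  expect_equal(unname(st2$cyc[3, ]), unname(ic))
  expect_equal(st2$phase[c(3, st2$n)], c(1L, 1L))
})

test_that("sloughing removes exactly the cells above the crypt top", {
  set.seed(6)
  cfg <- tiny_config(t_max = 0)
  st <- init_crypt(cfg)
  res0 <- remove_sloughed(st, cfg$domain)
  expect_equal(nrow(res0$removed), 0)
  expect_equal(res0$state$n, st$n)
  st$pos[2, 2] <- cfg$domain$height + 0.1
  res <- remove_sloughed(st, cfg$domain)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$id, st$id[2])
  expect_equal(res$state$n, st$n - 1)
})

test_that("daughters separate to the mature rest length within ~1 h", {
  # isolated two-cell relaxation with the ramping sister spring
  mech <- mech_params()
  dom <- crypt_domain(8, 10)
  pos <- rbind(c(4, 5), c(4.07, 5.07))
  e <- matrix(c(1L, 2L), 1)
  dt <- mech$dt
  for (s in seq_len(round(1.2 / dt))) {
    t <- s * dt
    frac <- min(t / mech$maturation, 1)
    rl <- mech$newborn_rest + (mech$rest_length - mech$newborn_rest) * frac
    F <- spring_forces(pos, e, rl, mech$mu, dom)
    pos <- step_positions(pos, F, mech$eta, dt, dom)
  }
  d <- sqrt(sum((pos[2, ] - pos[1, ])^2))
  expect_equal(d, mech$rest_length, tolerance = 0.05)
})

test_that("identical seeds give bit-identical runs", {
  cfg <- tiny_config(t_max = 4, seed = 123)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$final$pos, s2$final$pos)
  expect_identical(s1$snapshots, s2$snapshots)
  cfg2 <- tiny_config(t_max = 4, seed = 124)
  s3 <- run_simulation(cfg2)
  expect_false(identical(s1$final$pos, s3$final$pos))
})

test_that("cell counts balance divisions and removals", {
  cfg <- tiny_config(t_max = 6, seed = 5)
  sim <- run_simulation(cfg)
  n0 <- length(unique(sim$snapshots$id[sim$snapshots$t == 0]))
  ndiv <- sum(sim$events$event == "division")
  nrem <- sum(sim$events$event == "removal")
  expect_equal(sim$final$n, n0 + ndiv - nrem)
})

test_that("washout ensemble classifies outcomes and bookkeeps counts", {
  cfg <- tiny_config(t_max = 25, seed = 1)
  runs <- run_washout_ensemble(cfg, n = 2, base_seed = 3, relax = 2)
  expect_equal(nrow(runs), 2)
  expect_true(all(runs$outcome %in% c("WASHOUT", "TAKEOVER", "TIMEOUT")))
  expect_true(all(runs$t_end <= 25 + 1e-6))
})
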