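test_that("Wnt-modulated rates interpolate between off and on values", {
  p <- signalling_params()
  r0 <- wnt_modulated_rates(p, 0)
  r1 <- wnt_modulated_rates(p, 1)
  expect_equal(unname(r0), c(p$dX_off, p$dDX_off, p$dD_off))
  expect_equal(unname(r1), c(p$dX_on, p$dDX_on, p$dD_on))
  # midpoint evaluated by hand from the linear relationship
  r5 <- wnt_modulated_rates(p, 0.5)
  expect_equal(unname(r5), c((p$dX_off + p$dX_on) / 2,
                             (p$dDX_off + p$dDX_on) / 2,
                             (p$dD_off + p$dD_on) / 2))
  expect_error(wnt_modulated_rates(p, -0.1), "W must")
  expect_error(wnt_modulated_rates(p, 1.1), "W must")
})

test_that("Hippo binding flux is mass-conserving between CC and CH", {
  p <- signalling_params()
  s <- signalling_state(CC = 80, CH = 12, CT = 4)
  for (ph in c(0, 5000, 26000)) {
    d_on <- signalling_rhs(s, p, W = 0.5, pH_hat = ph)
    d_off <- signalling_rhs(s, p, W = 0.5, pH_hat = 0)
    # the only difference between the two vector fields is the binding flux,
    # removed from CC and added to CH at the identical rate
    expect_equal(d_off[["CC"]] - d_on[["CC"]], d_on[["CH"]] - d_off[["CH"]],
                 tolerance = 1e-12)
    expect_equal(d_on[["CH"]] - d_off[["CH"]], ph * 80 / (p$KH + 80),
                 tolerance = 1e-12)
  }
})

test_that("with Hippo off the complex has no inflow and only decays", {
  p <- signalling_params()
  s <- signalling_state(CC = 200, CH = 30)
  d <- signalling_rhs(s, p, W = 1, pH_hat = 0)
  expect_equal(d[["CH"]], -p$dH * 30)
})

test_that("signalling_rhs rejects invalid input", {
  p <- signalling_params()
  s <- signalling_state()
  s2 <- unclass(s); s2[["CC"]] <- -1
  expect_error(signalling_rhs(s2, p, 0.5), "negative")
  expect_error(signalling_rhs(s, p, 0.5, pH_hat = -1), "pH_hat")
  expect_error(signalling_rhs(s, p, 0.5, pH_hat = p$pH + 1), "pH_hat")
})

test_that("transcription-molecule total is conserved along trajectories", {
  p <- signalling_params()
  s0 <- signalling_state(CT = 5, T_free = 45)
  tr <- integrate_signalling(s0, p, W = 0.8, pH_hat = 0, t_span = c(0, 5))
  expect_true(all(abs(tr$T + tr$CT - 50) < 1e-9))
  expect_true(all(as.matrix(tr[, -1]) >= 0))
})

test_that("zero-length integration returns the initial state", {
  p <- signalling_params()
  s0 <- signalling_state(CC = 77)
  tr <- integrate_signalling(s0, p, W = 0.3, t_span = c(2, 2))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$CC, 77)
})

test_that("adaptive integration matches a fixed-step RK4 oracle over 10 h", {
  p <- signalling_params()
  s0 <- signalling_state(CC = 50, CT = 2, CH = 0)
  tr <- integrate_signalling(s0, p, W = 0.7, pH_hat = 5000,
                             t_span = c(0, 10), tol = 1e-8)
  oracle <- rk4_signalling(s0, p, W = 0.7, pH_hat = 5000, t_end = 10,
                           dt = 2.5e-4)
  end <- unlist(tr[nrow(tr), cryptdyn:::.sig_ode])
  expect_lt(max(abs(end - oracle)), 1e-5)
})

test_that("halving the tolerance changes the terminal state only slightly", {
  p <- signalling_params()
  s0 <- signalling_state(CC = 50)
  t1 <- integrate_signalling(s0, p, 0.6, 0, c(0, 20), tol = 1e-6)
  t2 <- integrate_signalling(s0, p, 0.6, 0, c(0, 20), tol = 5e-7)
  expect_lt(abs(t1$CT[nrow(t1)] - t2$CT[nrow(t2)]), 10 * 1e-6)
})

test_that("steady state satisfies the rhs-norm contract", {
  p <- signalling_params()
  ss <- steady_state_signalling(p, W = 1, pH_hat = 0)
  d <- signalling_rhs(ss, p, W = 1, pH_hat = 0)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("steady-state CT is monotone in Hippo rate and Wnt level", {
  p <- signalling_params()
  ct_ph <- vapply(c(0, 5000, 15000, 26000), function(ph)
    steady_state_signalling(p, 1, ph, rhs_tol = 1e-6)[["CT"]], numeric(1))
  expect_true(all(diff(ct_ph) <= 1e-8))
  ct_w <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w)
    steady_state_signalling(p, w, 0, rhs_tol = 1e-6)[["CT"]], numeric(1))
  expect_true(all(diff(ct_w) >= -1e-8))
})

test_that("parameter presets pin the Wnt-responsive rates", {
  on <- signalling_preset("wnt_on")
  off <- signalling_preset("wnt_off")
  expect_equal(wnt_modulated_rates(on, 0), wnt_modulated_rates(on, 1))
  expect_equal(wnt_modulated_rates(off, 0), wnt_modulated_rates(off, 1))
  expect_equal(unname(wnt_modulated_rates(off, 1)[["dX"]]),
               signalling_params()$dX_off)
})

test_that("config round-trips through the flat key-value format", {
  p <- signalling_params()
  f <- tempfile()
  write_config(p, f)
  q <- read_config(f)
  expect_equal(q$pH, p$pH)
  expect_equal(q$KH, p$KH)
  expect_equal(length(q), length(p))
})
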