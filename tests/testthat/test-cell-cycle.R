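test_that("G1 exit uses a strict threshold on E2F1 and requires G1", {
  mk <- function(e) cycle_state(c(pRb = 1, E2F1 = e, CycDi = 0.1,
                                  CycDa = 0.02, pRbP = 0.1))
  expect_false(g1_exit_reached(mk(0.99)))
  expect_true(g1_exit_reached(mk(1.01)))
  expect_false(g1_exit_reached(mk(1.0)))  # strict inequality
  s <- cycle_state(phase = "S")
  expect_error(g1_exit_reached(s), "G1")
})

test_that("cycle derivatives are finite and reject negative coupling", {
  cp <- cycle_params()
  st <- cycle_state()
  d <- cycle_rhs(st, CT = 5, params = cp)
  expect_true(all(is.finite(d)))
  expect_error(cycle_rhs(st, CT = -1, cp), "non-negative")
  # doubling CT never decreases the E2F1 derivative at fixed state
  d2 <- cycle_rhs(st, CT = 10, params = cp)
  expect_gte(d2[["E2F1"]], d[["E2F1"]] - 1e-12)
  expect_gt(d2[["CycDi"]], d[["CycDi"]])
})

test_that("proliferative baseline cycles and Wnt-off arrests", {
  d1 <- cycle_duration(W = 1, pH_hat = 0)
  expect_true(is.finite(d1))
  cp <- cycle_params()
  expect_gt(d1, cp$dur_S + cp$dur_G2 + cp$dur_M)
  expect_true(is.na(cycle_duration(W = 0, pH_hat = 0)))
})

test_that("duration is non-decreasing in the Hippo rate at full Wnt", {
  durs <- vapply(c(0, 15000, 26000), function(ph) cycle_duration(1, ph),
                 numeric(1))
  expect_true(all(is.finite(durs[1:2])))
  expect_true(all(diff(durs) > -1e-6 | is.na(diff(durs))))
})

test_that("the default Hippo constants do not arrest the full-Wnt cell", {
  d <- cycle_duration(W = 1, pH_hat = signalling_params()$pH)
  expect_true(is.finite(d))
})

test_that("high Hippo rate above the boundary arrests at reduced Wnt", {
  expect_true(is.na(cycle_duration(W = 0.3, pH_hat = 26000)))
})

test_that("a 1x1 sensitivity grid equals a single duration call", {
  m <- sensitivity_scan(0, 26000, scan = "W_pH")
  expect_equal(dim(m), c(1, 1))
  expect_equal(unname(m[1, 1]), cycle_duration(0, 26000))
})

test_that("scan rows reproduce the arrest-boundary structure", {
  # along increasing pH at fixed KH = 20: non-decreasing durations, then NA
  m <- sensitivity_scan(c(0, 20000, 40000, 60000), c(20), scan = "pH_KH",
                        W = 0.7)
  v <- m[, 1]
  fin <- which(is.finite(v))
  expect_gt(length(fin), 0)
  expect_true(all(diff(v[fin]) > -1e-6))
  if (any(is.na(v))) expect_true(all(which(is.na(v)) > max(fin)))
  # along increasing W at fixed pH: arrest region shrinks (durations appear)
  m2 <- sensitivity_scan(c(0.1, 0.5, 1), c(26000), scan = "W_pH")
  v2 <- m2[, 1]
  expect_true(is.na(v2[1]) && is.finite(v2[3]))
})

test_that("arrest matrix CSV encodes arrested cells as empty", {
  m <- sensitivity_scan(c(0.1, 1), c(26000), scan = "W_pH")
  expect_true(is.na(m[1, 1]) && is.finite(m[2, 1]))
  f <- tempfile(fileext = ".csv")
  write_scan_csv(m, f)
  txt <- readLines(f)
  expect_true(any(grepl(",$|,,", txt)))  # empty cell present (W = 0.1 arrested)
})
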