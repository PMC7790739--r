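test_that("imposed gradient is linear with the documented boundary values", {
  cfg04 <- wnt_config("ME1", theta_W = 0.4)
  cfg10 <- wnt_config("ME1", theta_W = 1.0)
  expect_equal(external_wnt(0, cfg04), 1)
  expect_equal(external_wnt(0, cfg10), 1)
  expect_equal(external_wnt(0.4, cfg04), 0)
  expect_equal(external_wnt(0.2, cfg04), 0.5)
  expect_equal(external_wnt(0.7, cfg04), 0)  # zero above the extent
  expect_equal(external_wnt(0.5, cfg10), 0.5)
  expect_error(external_wnt(1.2, cfg04), "height")
  expect_error(external_wnt(0.5, wnt_config("MI")), "external")
})

test_that("cell_wnt follows the static / dynamic / internal semantics", {
  me1 <- wnt_config("ME1", theta_W = 1)
  me2 <- wnt_config("ME2", theta_W = 1)
  mi <- wnt_config("MI")
  # a cell born at h = 0.1 (stored W = 0.9) later sitting at h = 0.5
  expect_equal(cell_wnt(0.9, 0.5, me1), 0.9)       # static: birth value
  expect_equal(cell_wnt(0.9, 0.5, me2), 0.5)       # dynamic: re-read
  expect_equal(cell_wnt(0.37, 0.5, mi), 0.37)      # internal cargo
})

test_that("division splits Wnt exactly and symmetrically at zero noise", {
  w <- divide_wnt(1.0, 0)
  expect_equal(w, c(0.5, 0.5))
  expect_error(divide_wnt(1, -0.1), "sigma")
})

test_that("division split conserves Wnt to machine precision at any noise", {
  set.seed(42)
  for (i in 1:200) {
    wm <- runif(1, 0, 1)
    w <- divide_wnt(wm, 0.2)
    expect_identical(sum(w), wm)
    expect_true(all(w >= 0))
  }
})

test_that("split fractions have the requested mean and spread", {
  set.seed(99)
  f <- replicate(1e5, divide_wnt(1, 0.1)[1])
  # truncation at sigma = 0.1 is negligible: mean 0.5, sd close to 0.1
  expect_lt(abs(mean(f) - 0.5), 0.001)
  expect_gt(sd(f), 0.095)
  expect_lt(sd(f), 0.1005)
})

test_that("reservoir refresh touches only cells at the crypt base", {
  cfg <- wnt_config("MI", rho = 0.1)
  y <- c(0.5, 1.5, 3, 10)
  W <- c(0.2, 0.3, 0.3, 0.8)
  out <- apply_reservoir(W, y, H = 20, cfg)
  expect_equal(out, c(1, 1, 0.3, 0.8))
  cfg0 <- wnt_config("MI", rho = 0)
  expect_equal(apply_reservoir(W, y, 20, cfg0), W)
  expect_error(apply_reservoir(W, y, 20, wnt_config("ME1")), "internal")
})
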