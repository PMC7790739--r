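snap <- function(t, y, phase = "G1", W = 1, id = seq_along(y), x = 1,
                 mutant = FALSE) {
  data.frame(t = t, id = id, lineage = id, mutant = mutant, x = x, y = y,
             volume = 0.8, W = W, phase = phase, E2F1 = 0.5, clipped = FALSE)
}

test_that("mitotic index is the per-bin fraction in M phase", {
  # 10 cells in bin 3 of 10 (h in [0.2, 0.3)), one of them mitotic
  tr <- snap(20, y = seq(4.1, 5.9, length.out = 10),
             phase = c("M", rep("G1", 9)))
  p <- mitotic_index_profile(tr, H = 20, n_bins = 10, burn_in = 10)
  expect_equal(p$value[3], 0.1)
  expect_true(all(is.na(p$value[-3])))  # empty bins are NA, not 0
  expect_equal(p$n[3], 10)
})

test_that("an all-quiescent population has zero mitotic index everywhere", {
  tr <- rbind(snap(11, seq(0.5, 19.5, 1)), snap(12, seq(0.5, 19.5, 1)))
  p <- mitotic_index_profile(tr, H = 20, n_bins = 20, burn_in = 10)
  expect_true(all(p$value == 0))
})

test_that("profiles are invariant to id relabelling and x-translation", {
  set.seed(5)
  y <- runif(40, 0, 20)
  tr1 <- snap(15, y, phase = sample(c("G1", "M"), 40, TRUE))
  tr2 <- tr1
  tr2$id <- rev(tr2$id)
  tr2$x <- (tr2$x + 7) %% 16
  p1 <- mitotic_index_profile(tr1, 20, 10, 10)
  p2 <- mitotic_index_profile(tr2, 20, 10, 10)
  expect_equal(p1$value, p2$value)
})

test_that("velocity profile follows the linear-interpolation quartile convention", {
  # one cell per speed value 1..5, all in the same bin; three snapshots so
  # central differences exist, constant speed upward
  rows <- list()
  for (s in 1:5) for (tt in 0:2)
    rows[[length(rows) + 1]] <- snap(10 + tt, y = 10 + s * 0.01 * tt, id = s)
  tr <- do.call(rbind, rows)
  p <- velocity_profile(tr, H = 20, W_c = 16, n_bins = 4, burn_in = 0)
  b <- 3  # y ~ 10 is bin 3 of 4
  expect_equal(p$value[b], 0.03)
  expect_equal(p$q25[b], 0.02)
  expect_equal(p$q75[b], 0.04)
  expect_equal(p$lo[b], 0.01); expect_equal(p$hi[b], 0.05)
  expect_error(velocity_profile(snap(1, 1:3), 20, 16), "2 snapshots")
})

test_that("wnt profile reports pooled mean and sd", {
  tr <- rbind(snap(11, c(1, 1.2, 15), W = c(1, 1, 0.25)),
              snap(12, c(1, 1.2, 15), W = c(1, 1, 0.25)))
  p <- wnt_profile(tr, H = 20, n_bins = 4, burn_in = 10)
  expect_equal(p$value[1], 1)
  expect_equal(p$sd[1], 0)
  expect_equal(p$value[4], 0.25)
})

test_that("washout probability reproduces the printed CI formula", {
  out <- c(rep("WASHOUT", 75), rep("TAKEOVER", 75))
  w <- washout_probability(out)
  expect_equal(w$p, 0.5)
  expect_equal(w$ci_high - w$p, 1.959964 * sqrt(0.25 / 150), tolerance = 1e-9)
  expect_equal(round(w$ci_high - w$p, 4), 0.08)
})

test_that("degenerate counts clip the interval to [0, 1]", {
  w <- washout_probability(rep("TAKEOVER", 50))
  expect_equal(w$p, 0)
  expect_equal(w$ci_low, 0); expect_equal(w$ci_high, 0)
})

test_that("normal-approximation CI brackets the exact binomial centre", {
  out <- c(rep("WASHOUT", 30), rep("TAKEOVER", 70))
  w <- washout_probability(out)
  exact <- stats::binom.test(30, 100)$conf.int
  expect_lt(abs(mean(c(w$ci_low, w$ci_high)) - mean(exact)), 0.02)
})

test_that("timeouts are excluded from the denominator", {
  out <- c(rep("WASHOUT", 10), rep("TAKEOVER", 10), rep("TIMEOUT", 5))
  w <- washout_probability(out)
  expect_equal(w$n, 20)
  expect_equal(w$n_timeout, 5)
  expect_error(washout_probability(rep("TIMEOUT", 3)), "valid")
  expect_error(washout_probability("WASHED"), "unknown")
})

test_that("relative change is the percent reduction from the reference", {
  expect_equal(relative_change(10, 10), 0)
  expect_equal(relative_change(10, 3.7), 63)
  expect_equal(relative_change(10, 4.7), 53)
  expect_error(relative_change(0, 1), "non-zero")
})
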