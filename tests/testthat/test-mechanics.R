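dom <- crypt_domain(16, 20)

test_that("three nearby cells form a single triangle", {
  pos <- rbind(c(5, 5), c(6, 5.1), c(5.5, 5.9))
  e <- neighbour_graph(pos, dom, cutoff = 1.5)
  expect_equal(nrow(e), 3)
  expect_true(all(e[, 1] < e[, 2]))
})

test_that("cells connect across the periodic wrap", {
  pos <- rbind(c(0.1, 5), c(15.9, 5), c(0.5, 6), c(15.5, 6), c(8, 5.5))
  e <- neighbour_graph(pos, dom, cutoff = 1.5)
  pairs <- paste(e[, 1], e[, 2])
  expect_true("1 2" %in% pairs)  # 0.2 apart through the wrap
})

test_that("interior lattice cells keep four short neighbours after pruning", {
  set.seed(3)
  g <- expand.grid(x = 4:11, y = 4:11)
  pos <- as.matrix(g) + matrix(runif(nrow(g) * 2, -0.02, 0.02), ncol = 2)
  e <- neighbour_graph(pos, dom, cutoff = 1.2)
  # the centre cell of the patch: 4 axis neighbours at ~1, diagonals ~1.41 cut
  centre <- which(g$x == 8 & g$y == 8)
  deg <- sum(e == centre)
  expect_equal(deg, 4)
})

test_that("hexagonal Voronoi areas match the closed form and partition the band", {
  pos <- hex_lattice(dom)
  v <- cell_volumes(pos, dom)
  inner <- !v$clipped & pos[, 2] > 2 & pos[, 2] < dom$height - 2
  expect_true(sum(inner) > 100)
  expect_lt(max(abs(v$areas[inner] - sqrt(3) / 2)), 1e-3)
  expect_equal(sum(v$areas), dom$width * dom$ytop, tolerance = 1e-9)
})

test_that("spring forces obey Hooke's law and Newton's third law", {
  pos <- rbind(c(5, 5), c(5.8, 5))
  e <- matrix(c(1L, 2L), 1)
  F0 <- spring_forces(pos, e, rest = 0.8, mu = 45, dom)
  expect_lt(max(abs(F0)), 1e-12)            # at rest length: no force
  F <- spring_forces(pos, e, rest = 1, mu = 45, dom)
  expect_equal(F[1, 1], -45 * 0.2, tolerance = 1e-12)  # repulsion, compressed 0.2
  expect_equal(colSums(F), c(0, 0))         # equal and opposite
  pos2 <- rbind(c(5, 5), c(5, 5))
  expect_error(spring_forces(pos2, e, 1, 45, dom), "coincident")
})

test_that("forces equal minus the finite-difference energy gradient", {
  set.seed(11)
  pos <- cbind(runif(20, 0, 16), runif(20, 2, 10))
  e <- neighbour_graph(pos, dom, cutoff = 2)
  rest <- runif(nrow(e), 0.8, 1.2)
  F <- spring_forces(pos, e, rest, mu = 45, dom)
  Ffd <- fd_forces(pos, e, rest, mu = 45, W_c = 16)
  expect_lt(max(abs(F - Ffd)), 1e-5)
})

test_that("position update clamps, wraps and preserves still cells", {
  pos <- rbind(c(15.9, 0.05), c(2, 5))
  F0 <- matrix(0, 2, 2)
  expect_equal(step_positions(pos, F0, 1, 0.01, dom), pos)
  Fdown <- rbind(c(30, -30), c(0, 0))
  p <- step_positions(pos, Fdown, eta = 1, dt = 0.01, dom)
  expect_gte(p[1, 2], 0)                     # clamped at the base
  expect_lt(p[1, 1], 16); expect_gte(p[1, 1], 0)  # wrapped
  Fbig <- rbind(c(0, 300), c(0, 0))
  expect_error(step_positions(pos, Fbig, 1, 0.01, dom), "instability")
})

test_that("a compressed pair relaxes exponentially toward rest length", {
  mu <- 45; eta <- 1; dt <- 1 / 500
  pos <- rbind(c(5, 5), c(5.5, 5))
  e <- matrix(c(1L, 2L), 1)
  t_end <- 0.05
  for (i in seq_len(round(t_end / dt))) {
    F <- spring_forces(pos, e, 1, mu, dom)
    pos <- step_positions(pos, F, eta, dt, dom)
  }
  d <- pos[2, 1] - pos[1, 1]
  # two-body overdamped closed form: d(t) - 1 = (d0 - 1) exp(-2 mu t / eta)
  d_exact <- 1 + (0.5 - 1) * exp(-2 * mu * t_end / eta)
  expect_equal(d, d_exact, tolerance = 5e-3)
  # monotone approach
  expect_gt(d, 0.5); expect_lt(d, 1)
})

test_that("cell speeds use minimum-image displacements", {
  hist0 <- rbind(c(3, 5), c(3, 5), c(3, 5))
  expect_equal(cell_velocity(hist0, dt = 1, dom), 0)
  drift <- rbind(c(3, 5), c(3, 5.4), c(3, 5.8))
  expect_equal(cell_velocity(drift, dt = 1, dom), 0.4)
  # crossing the wrap: x goes 15.9 -> 0.1, a displacement of 0.2, not 15.8
  wrap <- rbind(c(15.8, 5), c(15.9, 5), c(0.1, 5))
  expect_equal(cell_velocity(wrap, dt = 1, dom), 0.3 / 2)
  expect_error(cell_velocity(matrix(1, 1, 2), 1, dom), "2 samples")
})
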