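th <- thermo_params(300)

test_that("exponential and Maclaurin weights match hand-computed values", {
  b <- boost_from_dv(c(0, 1, 2) * th$kT)
  w_exp <- frame_weights(b, th, "exponential")
  expect_equal(w_exp$w, exp(c(0, 1, 2)), tolerance = 1e-9)
  expect_equal(w_exp$method, "exponential")

  w_m2 <- frame_weights(b, th, "maclaurin", k = 2)
  expect_equal(w_m2$w, c(1, 2.5, 5.0))   # 1 + x + x^2/2
  expect_equal(w_m2$method, "maclaurin:2")

  w_m0 <- frame_weights(b, th, "maclaurin", k = 0)
  expect_equal(w_m0$w, rep(1, 3))
  expect_true(all(w_exp$w >= 1) && all(w_m2$w >= 1))
})

test_that("Maclaurin weights converge monotonically to the exponential", {
  set.seed(1)
  x <- runif(10000, 0, 3)
  b <- boost_from_dv(x * th$kT)
  w_exp <- frame_weights(b, th, "exponential")$w
  prev <- Inf
  for (k in 1:10) {
    wk <- frame_weights(b, th, "maclaurin", k = k)$w
    rel <- max(abs(wk - w_exp) / w_exp)
    expect_lte(rel, prev + 1e-15)
    prev <- rel
  }
  expect_lt(prev, 5e-4)  # k = 10 within 0.05% everywhere on [0, 3]
})

test_that("weighted histogram reduces to counting and tallies by hand", {
  v <- c(0.5, 1.5, 1.5)
  h <- weighted_histogram(v, c(1, 2, 3), edges = c(0, 1, 2))
  expect_equal(h$sums, c(1, 5))
  expect_equal(h$counts, c(1L, 2L))
  expect_equal(h$n_excluded, 0)

  set.seed(2)
  x <- rnorm(500)
  h1 <- weighted_histogram(x, rep(1, 500), seq(-3, 3, by = 0.5))
  expect_identical(h1$sums, as.numeric(h1$counts))

  h2 <- weighted_histogram(c(10, 20), c(1, 1), c(0, 1))
  expect_equal(h2$n_excluded, 2)
  expect_equal(h2$sums, 0)
  # right edge is exclusive
  h3 <- weighted_histogram(c(0, 1, 2), c(1, 1, 1), c(0, 1, 2))
  expect_equal(h3$counts, c(1L, 1L))
  expect_equal(h3$n_excluded, 1)
  expect_error(weighted_histogram(1, 1, c(1, 1)), "increasing")
})

test_that("pmf_from_histogram anchors and masks as specified", {
  h <- weighted_histogram(c(0.5, 0.5, 1.5, 2.5), c(2, 2, 2, 2),
                          edges = 0:3)
  fes <- pmf_from_histogram(h, th)
  expect_equal(fes$prob, c(0.5, 0.25, 0.25))
  expect_equal(fes$pmf, c(0, -th$kT * log(0.5), -th$kT * log(0.5)),
               tolerance = 1e-9)
  expect_equal(fes$pmf[2], 0.41323, tolerance = 1e-4)
  expect_fes_invariants(fes)

  # uniform occupancy: flat PMF
  h <- weighted_histogram(c(0.5, 1.5, 2.5, 3.5), rep(1, 4), 0:4)
  expect_equal(pmf_from_histogram(h, th)$pmf, rep(0, 4))

  # empty bin masked, others anchored
  h <- weighted_histogram(c(0.5, 2.5), c(1, 3), 0:3)
  fes <- pmf_from_histogram(h, th)
  expect_true(is.na(fes$pmf[2]))
  expect_identical(min(fes$pmf, na.rm = TRUE), 0)
  expect_error(pmf_from_histogram(weighted_histogram(10, 1, 0:2), th),
               "empty")
})

test_that("2D PMF: single bin, separability, transposition", {
  fes <- pmf_2d(rep(0.5, 4), rep(0.5, 4), rep(1, 4), 0:2, 0:2, th)
  expect_identical(fes$pmf[1, 1], 0)
  expect_true(all(is.na(fes$pmf[-1])))
  expect_fes_invariants(fes)

  # product distribution: 2D PMF equals the sum of the 1D PMFs
  xs <- c(0.5, 1.5, 2.5); px <- c(3, 2, 1)
  ys <- c(0.5, 1.5); py <- c(1, 4)
  grid <- expand.grid(ix = 1:3, iy = 1:2)
  vx <- rep(xs[grid$ix], times = px[grid$ix] * py[grid$iy])
  vy <- rep(ys[grid$iy], times = px[grid$ix] * py[grid$iy])
  f2 <- pmf_2d(vx, vy, rep(1, length(vx)), 0:3, 0:2, th)
  f1x <- pmf_from_histogram(weighted_histogram(vx, rep(1, length(vx)), 0:3), th)
  f1y <- pmf_from_histogram(weighted_histogram(vy, rep(1, length(vy)), 0:2), th)
  expected <- outer(f1x$pmf, f1y$pmf, "+")
  expect_equal(f2$pmf, expected, tolerance = 1e-9)

  ft <- pmf_2d(vy, vx, rep(1, length(vx)), 0:2, 0:3, th)
  expect_equal(ft$pmf, t(f2$pmf))
})

test_that("zero-boost reweighting changes nothing, bitwise", {
  set.seed(3)
  x <- rnorm(1000)
  b <- boost_from_dv(rep(0, 1000))
  for (m in c("exponential", "maclaurin")) {
    w <- frame_weights(b, th, m)
    h <- weighted_histogram(x, w, seq(-4, 4, by = 0.5))
    h0 <- weighted_histogram(x, rep(1, 1000), seq(-4, 4, by = 0.5))
    expect_identical(h$sums, h0$sums)
  }
})

test_that("negative boost in input is rejected", {
  b <- boost_from_dv(c(0, 1))
  b$dV_P[2] <- -1  # corrupt after construction
  expect_error(frame_weights(b, th), "negative")
})

test_that("reweighting recovers the canonical double-well profile", {
  # scaled-down version of the full recovery property (acceptance runs n=2e5)
  kT <- th$kT
  pot <- toy_potential("double_well_1d", barrier = 3)
  amd <- amd_params(1, E_total = 4, alpha_total = 2)
  s <- sample_boosted(pot, sampler_spec(50000, seed = 13, kT = kT, amd = amd))
  w <- frame_weights(s$boost, th, "exponential")
  edges <- seq(-1.75, 1.75, length.out = 41)
  h <- weighted_histogram(s$positions, w, edges)
  fes <- pmf_from_histogram(h, th, coord = "x")
  centers <- fes$centers[[1]]
  # analytic reference, anchored on the same counted-bin support
  ok <- h$counts >= 200
  Fa <- pot$free_energy(centers)
  Fa <- Fa - min(Fa[ok])
  expect_gt(sum(ok), 20)
  expect_lt(max(abs(fes$pmf[ok] - Fa[ok])), 0.35)  # looser at n = 5e4
  amin_set <- which(Fa <= min(Fa) + 1e-9)
  expect_true(which.min(fes$pmf) %in% amin_set)
})
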