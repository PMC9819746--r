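# Histograms, circular recentring, Gaussian mode fits, correlation.

test_that("1D histograms are normalised probability histograms", {
  h <- histogram1d(rep(1.5, 100), bin_width = 0.1)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(max(h$prob), 1)
  expect_error(histogram1d(numeric(0), 0.1), "empty")
  expect_error(histogram1d(1:5, 0), "bin_width")

  # uniform circular draws: every 10-degree bin near 1/36 (binomial 3-sigma)
  set.seed(1)
  u <- stats::runif(10000, -180, 180)
  hu <- histogram1d(u, bin_width = 10, circular = TRUE)
  expect_length(hu$prob, 36)
  p0 <- 1 / 36
  tol <- 3 * sqrt(p0 * (1 - p0) / 10000)
  expect_true(all(abs(hu$prob - p0) < tol))
  expect_equal(sum(hu$prob), 1, tolerance = 1e-12)
})

test_that("2D histograms normalise and report the modal cell", {
  h <- histogram2d(rep(-31, 50), rep(-48, 50), bins = c(90, 90))
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(sum(h$prob > 0), 1)
  expect_lt(abs(h$argmax["alpha"] + 31), 2)
  expect_lt(abs(h$argmax["beta"] + 48), 4)
  h2 <- histogram2d(c(rep(-40, 50), rep(30, 50)), c(rep(-90, 50), rep(90, 50)))
  expect_equal(sort(unique(as.numeric(h2$prob)))[sum(h2$prob > 0)], 0.5)
  expect_error(histogram2d(1:3, 1:4), "lengths differ")
})

test_that("circular recentring heals the wrap and inverts exactly", {
  set.seed(3)
  x <- wrap_angle(stats::rnorm(500, 179, 3))
  rc <- recenter_circular(x)
  # contiguous after the shift: range no longer straddles the wrap
  expect_lt(diff(range(rc$shifted)), 50)
  expect_lt(max(abs(wrap_angle(uncenter_circular(rc$shifted, rc$offset) - x))),
            1e-12)
  # cluster at 0: offset near 180 (the identity shift) barely moves the data
  y <- stats::rnorm(500, 0, 5)
  rcy <- recenter_circular(y)
  expect_lt(circ_diff(rcy$offset, 180), 20)
  expect_lt(max(abs(rcy$shifted - y)), 20)
  expect_lt(max(abs(wrap_angle(uncenter_circular(rcy$shifted, rcy$offset) - y))),
            1e-12)
  # antipodal clusters survive as two modes
  z <- wrap_angle(c(stats::rnorm(300, 90, 4), stats::rnorm(300, -90, 4)))
  rcz <- recenter_circular(z)
  f <- fit_modes(rcz$shifted, seed = 1)
  expect_equal(f$k, 2)
})

test_that("mode fits recover known mixtures and flag minor modes", {
  set.seed(10)
  x1 <- stats::rnorm(2000, 1.29, 0.13)
  f1 <- fit_modes(x1, seed = 1)
  expect_equal(f1$k, 1)
  expect_lt(abs(f1$modes$mean[1] - 1.29), 0.01)
  expect_lt(abs(f1$modes$sd[1] - 0.13), 0.01)

  x2 <- c(stats::rnorm(1000, 1.78, 0.20), stats::rnorm(1000, 2.27, 0.18))
  f2 <- fit_modes(x2, seed = 1)
  expect_equal(f2$k, 2)
  expect_lt(max(abs(sort(f2$modes$mean) - c(1.78, 2.27))), 0.05)
  expect_true(all(diff(f2$modes$weight) <= 0))  # ordered by weight

  x3 <- c(stats::rnorm(1700, 0, 1), stats::rnorm(300, 6, 1))
  f3 <- fit_modes(x3, seed = 1)
  expect_equal(f3$k, 2)
  minor <- which.min(f3$modes$weight)
  expect_true(f3$modes$low_population[minor])
  expect_false(any(f3$modes$low_population[-minor]))

  expect_error(fit_modes(rep(1, 100)), "zero-variance")
  expect_error(fit_modes(stats::rnorm(10)), "at least 30")
  expect_error(fit_modes(c(stats::rnorm(50), NA)), "non-finite")
})

test_that("mixture recovery holds across seeded replicates for k = 1..3", {
  set.seed(20)
  ok <- c(k1 = 0, k2 = 0, k3 = 0)
  reps <- 20
  for (r in seq_len(reps)) {
    y1 <- stats::rnorm(500, 0, 1)
    f <- fit_modes(y1, seed = r)
    ok["k1"] <- ok["k1"] + (f$k == 1)
    y2 <- c(stats::rnorm(250, 0, 1), stats::rnorm(250, 4, 1))
    f <- fit_modes(y2, seed = r)
    ok["k2"] <- ok["k2"] + (f$k == 2 && max(abs(sort(f$modes$mean) - c(0, 4))) < 0.5)
    y3 <- c(stats::rnorm(200, 0, 1), stats::rnorm(200, 5, 1),
            stats::rnorm(200, 10, 1))
    f <- fit_modes(y3, seed = r)
    ok["k3"] <- ok["k3"] + (f$k == 3)
  }
  expect_true(all(ok >= 0.95 * reps))
})

test_that("circular fits agree across recenterings within half a degree", {
  set.seed(30)
  b <- wrap_angle(c(stats::rnorm(800, 170, 6), stats::rnorm(800, -120, 8)))
  f <- fit_modes(b, seed = 1, circular = TRUE)
  expect_equal(f$k, 2)
  # fit the same data rotated to a different wrap point, then map back
  shift <- 77
  b2 <- wrap_angle(b + shift)
  f2 <- fit_modes(b2, seed = 1, circular = TRUE)
  m1 <- sort(wrap_angle(f$modes$mean))
  m2 <- sort(wrap_angle(f2$modes$mean - shift))
  expect_lt(max(circ_diff(m1, m2)), 0.5)
})

test_that("pearson matches the textbook formula on published-style inputs", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_error(pearson(1:3, rep(1, 3)), "degenerate")
  expect_error(pearson(1:4, 1:5), "lengths differ")
  # linker lengths vs major-mode COM heights; oracle = explicit sum formula
  x <- c(0, 11, 20, 24, 5, 8)
  y <- c(1.43, 1.93, 1.62, 2.00, 1.78, 1.29)
  n <- length(x)
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pearson(x, y), r_oracle, tolerance = 1e-12)
})
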