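test_that("rate maps are occupancy-normalised with missing unvisited bins", {
  # hand-built 3-bin toy series: bins (1,1), (2,1) visited
  x <- c(1, 1, 6, 6, 6); y <- rep(1, 5)
  a <- c(2, 4, 1, 2, 3)
  rm <- rate_map(x, y, a, L = 10, bin_size = 5, smooth_sd = 0)
  expect_equal(rm$rate[1, 1], 3)          # mean of 2, 4
  expect_equal(rm$rate[2, 1], 2)          # mean of 1, 2, 3
  expect_true(is.na(rm$rate[1, 2]))
  expect_true(is.na(rm$rate[2, 2]))
  # constant activity gives the constant in every visited bin
  set.seed(1)
  xs <- runif(500, 0, 100); ys <- runif(500, 0, 100)
  rm2 <- rate_map(xs, ys, rep(7, 500), L = 100, smooth_sd = 0)
  expect_equal(unique(stats::na.omit(as.numeric(rm2$rate))), 7)
  expect_error(rate_map(numeric(0), numeric(0), numeric(0), 100), "empty")
})

test_that("autocorrelograms are 1 at zero lag and centro-symmetric", {
  set.seed(3)
  m <- matrix(runif(400), 20, 20)
  m[sample(400, 40)] <- NA
  ac <- autocorrelogram(m, min_overlap = 20)
  ctr <- (dim(ac) + 1) / 2
  expect_equal(ac[ctr[1], ctr[2]], 1, tolerance = 1e-10)
  # point reflection through the center
  flipped <- ac[rev(seq_len(nrow(ac))), rev(seq_len(ncol(ac)))]
  expect_equal(unclass(ac), unclass(flipped), tolerance = 1e-10)
  expect_true(all(abs(ac) <= 1 + 1e-12, na.rm = TRUE))
  # lag-wise values agree with a direct Pearson computation
  direct <- function(du, dv) {
    n <- nrow(m)
    i <- seq_len(n); j <- seq_len(n)
    ii <- i[i + du >= 1 & i + du <= n]; jj <- j[j + dv >= 1 & j + dv <= n]
    a <- m[ii, jj]; b <- m[ii + du, jj + dv]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 20) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  for (lag in list(c(0, 3), c(-2, 5), c(7, -4))) {
    expect_equal(ac[ctr[1] + lag[1], ctr[2] + lag[2]],
                 direct(lag[1], lag[2]), tolerance = 1e-8)
  }
})

test_that("a hexagonal field map shows six peaks at 60-degree spacing", {
  m <- lattice_rate_map("hex", spacing = 20)
  ac <- autocorrelogram(m)
  pk <- placegrid:::autocorr_peaks(ac)
  pk <- pk[order(pk[, "dist"]), , drop = FALSE]
  six <- pk[1:6, , drop = FALSE]
  ctr <- (dim(ac) + 1) / 2
  ang <- sort(atan2(six[, "i"] - ctr[1], six[, "j"] - ctr[2]) %% (2 * pi))
  gaps <- diff(c(ang, ang[1] + 2 * pi)) * 180 / pi
  expect_equal(gaps, rep(60, 6), tolerance = 8)
})

test_that("gridness vanishes under rotational symmetry", {
  # algebra: equal correlations at every rotation give exactly zero
  for (c0 in c(-0.4, 0, 0.7, 1)) {
    expect_equal(placegrid:::gridness_combine_hex(rep(c0, 5)), 0,
                 tolerance = 1e-12)
    expect_equal(placegrid:::gridness_combine_square(rep(c0, 3)), 0,
                 tolerance = 1e-12)
  }
  # a discretised radial map scores near zero (pixel-grid anisotropy only)
  ac <- autocorrelogram(radial_map())
  expect_lt(abs(gridness_hex(ac)), 0.1)
  expect_lt(abs(gridness_square(ac)), 0.1)
})

test_that("lattice fixtures are classified by the right score", {
  hex <- autocorrelogram(lattice_rate_map("hex", spacing = 20))
  sqm <- autocorrelogram(lattice_rate_map("square", spacing = 20))
  expect_gt(gridness_hex(hex), 1)
  expect_lt(gridness_square(hex), gridness_hex(hex))
  expect_gt(gridness_square(sqm), 0.5)
  expect_lt(gridness_hex(sqm), 0)
  # orientation sweep: the correct score wins for every rotation
  for (ang in seq(0, pi / 3, length.out = 10)) {
    h <- autocorrelogram(lattice_rate_map("hex", spacing = 20, angle = ang))
    s <- autocorrelogram(lattice_rate_map("square", spacing = 20,
                                          angle = ang))
    expect_gt(gridness_hex(h), gridness_square(h))
    expect_gt(gridness_square(s), gridness_hex(s))
  }
})

test_that("gridness is invariant to uniform rescaling of the rate map", {
  m <- lattice_rate_map("hex", spacing = 18, angle = 0.3)
  g1 <- gridness_hex(autocorrelogram(m))
  g2 <- gridness_hex(autocorrelogram(5 * m))
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("entropy suite matches closed forms and its identities", {
  es <- entropy_suite(rep(0.25, 4), dx = 20)
  expect_equal(es$H, log(4))
  expect_equal(es$r, 1)
  expect_equal(es$R, 0)
  expect_equal(es$I, 0)
  es2 <- entropy_suite(c(1, 0, 0), dx = 20)
  expect_equal(es2$H, 0)
  expect_equal(es2$R, 1)
  # printed decomposition on an uneven case
  es3 <- entropy_suite(c(0.5, 0.25, 0.25), dx = c(2, 1, 1))
  expect_equal(es3$S + es3$Z, es3$H, tolerance = 1e-12)
  expect_equal(es3$S, -(0.5 * log(0.5 / 2) + 0.25 * log(0.25) +
                          0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(entropy_suite(c(0.5, 0.2)), "sum to 1")
  expect_error(entropy_suite(c(1.5, -0.5)), "nonnegative")
})

test_that("entropy identities hold to 1e-12 on random distributions", {
  set.seed(8)
  for (k in 1:200) {
    n <- sample(2:50, 1)
    p <- rgamma(n, 1); p <- p / sum(p)
    dx <- runif(n, 0.5, 40)
    es <- entropy_suite(p, dx)
    expect_lt(abs(es$S + es$Z - es$H), 1e-12)
    expect_lt(abs(es$R - (1 - es$H / log(n))), 1e-12)
    expect_lt(abs(es$I - (log(n) - es$H)), 1e-12)
    expect_true(es$H >= -1e-12 && es$H <= log(n) + 1e-12)
  }
})

test_that("cross-entropy measures behave as stated", {
  p <- rep(0.25, 4)
  cm <- cross_entropy_measures(p, p)
  expect_equal(cm$Hp, cm$Hq)
  expect_equal(cm$Hpq, 0)
  expect_equal(cm$I, 0)
  cm2 <- cross_entropy_measures(c(1, 0), c(0.5, 0.5))
  expect_equal(cm2$Hp, log(2))
  expect_error(cross_entropy_measures(c(1, 0), c(0, 1)), "support")
  # KL-style information difference is nonnegative
  set.seed(9)
  for (k in 1:50) {
    n <- sample(2:20, 1)
    p <- rgamma(n, 1); p <- p / sum(p)
    q <- rgamma(n, 1); q <- q / sum(q)
    expect_gte(cross_entropy_measures(p, q)$I, 0)
  }
})

test_that("error summaries match hand computations", {
  truth <- cbind(c(0, 1, 2), c(0, 0, 0))
  est <- list(truth, truth + matrix(rep(c(3, 4), each = 3), 3, 2))
  es <- error_summaries(est, truth, n_bins = 3)
  expect_equal(es$error[, 1], rep(0, 3))
  expect_equal(es$error[, 2], rep(5, 3))          # 3-4-5 offset
  # variance with the n-1 convention
  ex <- cbind(truth[, 1], truth[, 1] + 3)
  expect_equal(es$variance,
               apply(ex, 1, var) + apply(cbind(truth[, 2], truth[, 2] + 4),
                                         1, var))
  expect_equal(es$E_error, sqrt(es$variance))
  expect_equal(nrow(es$binned), 6)                # 3 bins x 2 modules
  expect_error(error_summaries(list(truth[1:2, ]), truth), "lengths differ")
})
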