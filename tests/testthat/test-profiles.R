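# Line profiles, trilinear interpolation and prominence-based peak counting.

test_that("profile of a constant field is constant", {
  st <- structure(list(A = array(3.7, c(10, 10, 10)),
                       H = array(3.7, c(10, 10, 10)),
                       step = 0L, t = 0), class = "rd_state")
  prof <- extract_profile(st, c(2, 2, 2), c(9, 8, 7), n_samples = 50)
  expect_equal(prof$A, rep(3.7, 50))
  expect_equal(prof$H, rep(3.7, 50))
  expect_equal(nrow(prof), 50L)
})

test_that("sampling on integer coordinates reproduces voxel values exactly", {
  set.seed(9)
  A <- array(runif(1000), c(10, 10, 10))
  st <- structure(list(A = A, step = 0L, t = 0), class = "rd_state")
  prof <- extract_profile(st, c(1, 4, 5), c(10, 4, 5), n_samples = 10,
                          fields = "A")
  expect_equal(prof$A, A[, 4, 5])
})

test_that("a separable Gaussian bump peaks at the line center", {
  dm <- c(21, 21, 21)
  idx <- expand.grid(x = 1:21, y = 1:21, z = 1:21)
  g <- exp(-((idx$x - 11)^2 + (idx$y - 11)^2 + (idx$z - 11)^2) / 18)
  A <- array(g, dm)
  st <- structure(list(A = A, step = 0L, t = 0), class = "rd_state")
  prof <- extract_profile(st, c(2, 11, 11), c(20, 11, 11), n_samples = 101,
                          fields = "A")
  expect_equal(which.max(prof$A), 51L)
  expect_equal(count_peaks(prof$A), 1L)
})

test_that("degenerate lines and out-of-domain endpoints are errors", {
  st <- structure(list(A = array(0, c(5, 5, 5)), step = 0L, t = 0),
                  class = "rd_state")
  expect_error(extract_profile(st, c(2, 2, 2), c(2, 2, 2), fields = "A"),
               "degenerate")
  expect_error(extract_profile(st, c(0, 2, 2), c(4, 2, 2), fields = "A"),
               "outside")
})

test_that("peak counting matches the analytic two-Gaussian cases", {
  k <- seq(-15, 15, length.out = 301)
  one <- exp(-k^2 / 2)
  expect_equal(count_peaks(one), 1L)
  expect_equal(count_peaks(rep(1, 100)), 0L)  # flat
  sep6 <- exp(-(k - 3)^2 / 2) + exp(-(k + 3)^2 / 2)   # 6 sigma apart
  expect_equal(count_peaks(sep6), 2L)
  merged <- exp(-(k - 0.25)^2 / 2) + exp(-(k + 0.25)^2 / 2)  # 0.5 sigma
  expect_equal(count_peaks(merged), 1L)
  expect_equal(count_peaks(c(1, 2)), 0L)  # shorter than 3 samples
})

test_that("plateau peaks count once and prominence filtering works", {
  x <- c(0, 1, 3, 3, 3, 1, 0.5, 1.2, 0.2)
  expect_equal(count_peaks(x, prominence = 0.1), 2L)
  expect_equal(count_peaks(x, prominence = 0.5), 1L)  # small bump filtered
  pk <- find_peaks(x, prominence = 0.1)
  expect_equal(pk$index[1], 4L)  # plateau center
})

test_that("peak counter equals an independent brute-force scan on random profiles", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(10:80, 1)
    base <- cumsum(rnorm(n))
    x <- as.numeric(stats::filter(base, rep(1 / 5, 5), sides = 2))
    x[is.na(x)] <- base[is.na(x)]
    prom <- sample(c(0, 0.05, 0.1, 0.3), 1)
    expect_equal(count_peaks(x, prom), brute_force_peaks(x, prom))
  }
})

test_that("auto profile line crosses the distal tip transversely", {
  vol <- make_fixture(fixture_spec("cylinder", radius = 4, length = 30,
                                   dim = c(40, 40, 40)))
  reg <- extract_tissue(vol)
  sk <- skeletonize_region(reg, root_hint = c(20, 20, 5))
  line <- auto_profile_line(reg, sk)
  # the stalk runs along z, so the transverse line must be nearly normal to z
  expect_lt(abs((line$to - line$from)[3]) /
              sqrt(sum((line$to - line$from)^2)), 0.3)
  # chord width through the tip is about the tube diameter
  expect_gt(line$width, 4)
  expect_lt(line$width, 14)
})
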