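make_series <- function(X, tr = 2, d = NULL) {
  # X: t x V matrix laid out into a (V,1,1,t) grid
  nt <- nrow(X); nv <- ncol(X)
  if (is.null(d)) d <- c(nv, 1, 1)
  bold_series(array(t(X), dim = c(d, nt)), tr = tr,
              brain_mask = array(TRUE, dim = d))
}

test_that("pairwise averaging halves length and doubles TR", {
  s <- make_series(matrix(rnorm(3000 * 4), 3000, 4), tr = 2)
  out <- pairwise_average(s)
  expect_equal(n_volumes(out), 1500)
  expect_equal(out$tr, 4)
  # constant series unchanged, alternating series becomes the pair mean
  cs <- make_series(matrix(5, 10, 2))
  expect_true(all(pairwise_average(cs)$data == 5))
  alt <- make_series(matrix(rep(c(1, 3), 5), 10, 1))
  expect_true(all(pairwise_average(alt)$data == 2))
  odd <- make_series(matrix(rnorm(7 * 2), 7, 2))
  expect_warning(o <- pairwise_average(odd), "odd")
  expect_equal(n_volumes(o), 3)
  expect_error(pairwise_average(make_series(matrix(1, 1, 2))), "at least 2")
})

test_that("discarding initial volumes shifts the timing metadata", {
  s <- make_series(matrix(rnorm(300 * 3), 300, 3), tr = 2)
  out <- discard_initial(s, 2)
  expect_equal(n_volumes(out), 298)
  expect_equal(out$time_offset, 4)
  expect_identical(discard_initial(s, 0), s)
  b <- discard_initial(s, 299)
  expect_equal(n_volumes(b), 1)
  expect_error(discard_initial(s, 300), "discard")
})

test_that("slice-time correction aligns interleaved slice phases", {
  # sinusoid of period 40 s sampled at TR 2 s on 22 interleaved slices
  nt <- 100; nz <- 22; tr <- 2
  tgrid <- (seq_len(nt) - 1) * tr
  acq_rank <- order(c(seq(1, nz, 2), seq(2, nz, 2)))
  arr <- array(0, dim = c(2, 2, nz, nt))
  for (z in seq_len(nz)) {
    off <- (acq_rank[z] - 1) / nz * tr
    arr[, , z, ] <- rep(sin(2 * pi * (tgrid + off) / 40), each = 4)
  }
  s <- bold_series(arr, tr = tr)
  out <- slice_time_correct(s, "ascending_interleaved")
  # phase per slice by sin/cos regression over the interior
  interior <- 10:(nt - 10)
  phases <- vapply(seq_len(nz), function(z) {
    y <- out$data[1, 1, z, interior]
    fit <- lm(y ~ sin(2 * pi * tgrid[interior] / 40) +
                cos(2 * pi * tgrid[interior] / 40))
    atan2(coef(fit)[3], coef(fit)[2])
  }, numeric(1))
  expect_lt(max(abs(phases - phases[1])), 0.05)
  # identity cases
  expect_identical(slice_time_correct(s, "none"), s)
  one <- make_series(matrix(rnorm(20), 20, 1))
  expect_identical(slice_time_correct(one, "ascending_interleaved"), one)
})

test_that("in-plane Gaussian smoothing matches the analytic kernel", {
  d <- c(17, 17, 1)
  arr <- array(0, dim = c(d, 1))
  arr[9, 9, 1, 1] <- 1
  s <- bold_series(arr, tr = 2)
  out <- gaussian_smooth(s, 2)
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  ratio_obs <- out$data[10, 9, 1, 1] / out$data[9, 9, 1, 1]
  ratio_th <- dnorm(1, sd = sigma) / dnorm(0, sd = sigma)
  expect_lt(abs(ratio_obs / ratio_th - 1), 0.01)
  # identity and constant cases
  expect_identical(gaussian_smooth(s, 0), s)
  cs <- bold_series(array(7, dim = c(9, 9, 1, 2)), tr = 2)
  sm <- gaussian_smooth(cs, 2)
  expect_lt(max(abs(sm$data[5, 5, 1, ] - 7)), 1e-10)
})

test_that("the high-pass filter removes drift and slow cycles only", {
  nt <- 200; tr <- 2
  run <- nt * tr
  tgrid <- (seq_len(nt) - 1) * tr
  cutoff <- 9 / run
  ramp <- 3 + 0.01 * tgrid
  fast <- sin(2 * pi * (2 * cutoff) * tgrid)       # passband
  slow <- sin(2 * pi * (0.5 * cutoff) * tgrid)     # stopband
  s <- make_series(cbind(ramp, 10 + fast, 10 + slow), tr = tr)
  out <- temporal_highpass(s, cycles = 9)
  X <- series_matrix(out)
  expect_lt(max(abs(X[, 1] - mean(ramp))), 1e-8)   # pure ramp -> mean
  amp_at <- function(y, f) {
    fit <- lm(y ~ sin(2 * pi * f * tgrid) + cos(2 * pi * f * tgrid))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_lt(abs(amp_at(X[, 2], 2 * cutoff) - 1), 0.05)
  expect_lt(amp_at(X[, 3], 0.5 * cutoff), 0.1)
  # voxel mean restored
  expect_equal(mean(X[, 2]), 10, tolerance = 1e-6)
})

test_that("the FFT low-pass keeps slow and kills fast oscillations", {
  nt <- 200; tr <- 2
  tgrid <- (seq_len(nt) - 1) * tr
  s <- make_series(cbind(rep(4, nt),
                         sin(2 * pi * 0.05 * tgrid),
                         sin(2 * pi * 0.2 * tgrid)), tr = tr)
  out <- temporal_lowpass(s, 0.1)
  X <- series_matrix(out)
  expect_lt(max(abs(X[, 1] - 4)), 1e-10)
  expect_lt(abs(sd(X[, 2]) / sd(sin(2 * pi * 0.05 * tgrid)) - 1), 0.02)
  expect_lt(sd(X[, 3]) / sd(sin(2 * pi * 0.2 * tgrid)), 0.02)
  expect_error(temporal_lowpass(s, 0.3), "Nyquist")
})

test_that("temporal filters are linear operators", {
  set.seed(1)
  X <- matrix(rnorm(80 * 3), 80, 3)
  Y <- matrix(rnorm(80 * 3), 80, 3)
  comb <- 2 * X - 3 * Y
  f <- function(M) series_matrix(temporal_highpass(make_series(M), cycles = 5))
  g <- function(M) series_matrix(temporal_lowpass(make_series(M), 0.1))
  expect_equal(f(comb), 2 * f(X) - 3 * f(Y), tolerance = 1e-9)
  expect_equal(g(comb), 2 * g(X) - 3 * g(Y), tolerance = 1e-9)
})

test_that("motion correction recovers injected translations", {
  a <- build_synthetic_atlas(c(16, 16, 4), 5, seed = 3)
  m <- quiet_model(n = 5, responsive_structures = integer(0))
  # anatomically structured, motion-free phantom
  base <- array(0, dim = c(16, 16, 4))
  base[a$brain_mask] <- 100 + 10 * a$labels[a$brain_mask]
  arr <- array(rep(base, 6), dim = c(16, 16, 4, 6))
  s <- bold_series(arr, tr = 2)
  still <- rigid_motion_correct(s)
  expect_equal(nrow(still$motion), 6)
  expect_lt(max(abs(as.matrix(still$motion[, c("tx", "ty", "tz")]))), 0.1)
  # inject a 1-voxel x-shift on the last three volumes
  shifted <- arr
  for (i in 4:6) {
    shifted[, , , i] <- 0
    shifted[2:16, , , i] <- arr[1:15, , , i]
  }
  s2 <- bold_series(shifted, tr = 2)
  mc <- rigid_motion_correct(s2)
  est <- mc$motion$tx[4:6]
  expect_true(all(abs(abs(est) - 1) < 0.2))
})
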