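test_that("a three-set design has eight temperature columns plus intercept", {
  p <- build_stimulus_protocol(3, seed = 2)
  d <- build_design(p, n_volumes = 1470, tr_eff = 4)
  expect_equal(ncol(d$X), 9)
  expect_equal(length(d$predictor_names), 8)
  expect_true(all(d$X[, "intercept"] == 1))
  # empty protocol: intercept only
  p0 <- single_temp_protocol()
  p0$events <- p0$events[0, ]
  d0 <- build_design(p0, n_volumes = 100, tr_eff = 4)
  expect_equal(colnames(d0$X), "intercept")
  # events outside the run are rejected
  expect_error(build_design(p, n_volumes = 100, tr_eff = 4), "design error")
})

test_that("regressor peak time matches a dense-grid convolution oracle", {
  p <- single_temp_protocol(temps = 54, onsets = 100)
  d <- build_design(p, n_volumes = 100, tr_eff = 4)
  t_peak_sampled <- d$times[which.max(d$X[, "T54"])]
  # oracle: continuous convolution at dt = 0.01
  dt <- 0.01
  tf <- seq(0, 300, dt)
  box <- as.numeric(tf >= 100 & tf < 120)
  kern <- two_gamma_hrf(hrf_params(), dt = dt)
  conv <- convolve(box, rev(kern), type = "open")[seq_along(tf)]
  t_peak_true <- tf[which.max(conv)]
  expect_lte(abs(t_peak_sampled - t_peak_true), 4)
})

test_that("noiseless phantoms return the planted betas to within 1%", {
  a <- tiny_atlas()
  m <- quiet_model(n = 8, responsive_structures = c(2, 5),
                   gain_range = c(1, 1))
  p <- build_stimulus_protocol(1, seed = 4)
  s <- simulate_session(a, p, m, tr = 2, n_volumes = 1020, seed = 1)
  s <- preprocess_stimulus(s, preprocess_config(smoothing_fwhm = 0,
                                                highpass_cycles = 0))
  d <- build_design(p, n_volumes = n_volumes(s), tr_eff = s$tr,
                    t0 = s$time_offset)
  spm <- fit_glm(s, d)
  planted <- model_amplitude(m, 54)[2]
  vox <- structure_voxels(a, 2)[1]
  idx <- arrayInd(vox, dim(a$labels))
  est <- spm$beta[idx[1], idx[2], idx[3], match("T54", spm$predictor_names)]
  expect_lt(abs(est - planted) / planted, 0.01)
  # non-responsive structure: beta ~ 0
  vox0 <- structure_voxels(a, 3)[1]
  i0 <- arrayInd(vox0, dim(a$labels))
  expect_lt(abs(spm$beta[i0[1], i0[2], i0[3],
                         match("T54", spm$predictor_names)]), 0.02)
})

test_that("GLM residuals are orthogonal to the design and betas scale", {
  set.seed(7)
  p <- build_stimulus_protocol(1, seed = 4)
  d <- build_design(p, n_volumes = 510, tr_eff = 4)
  arr <- array(100 + rnorm(4 * 510), dim = c(4, 1, 1, 510))
  s <- bold_series(arr, tr = 4)
  spm <- fit_glm(s, d)
  Y <- series_matrix(s)
  Y <- 100 * sweep(Y, 2, colMeans(Y), "/") - 100
  B <- vapply(seq_along(spm$predictor_names), function(k)
    spm$beta[, 1, 1, k], numeric(4))
  # reconstruct residuals and check orthogonality
  Xp <- d$X[, spm$predictor_names, drop = FALSE]
  fit <- lm.fit(d$X, Y)
  expect_lt(max(abs(crossprod(d$X, fit$residuals))), 1e-8)
  # scaling the series scales betas (per % convention: scale-invariant)
  s2 <- s; s2$data <- s2$data * 3
  spm2 <- fit_glm(s2, d)
  expect_equal(spm2$beta, spm$beta, tolerance = 1e-10)
})

test_that("a voxel equal to a design column yields a capped t and p = 0", {
  p <- single_temp_protocol(temps = 54, onsets = 40)
  d <- build_design(p, n_volumes = 60, tr_eff = 4)
  y <- 100 + 5 * d$X[, "T54"]
  s <- bold_series(array(y, dim = c(1, 1, 1, 60)), tr = 4)
  spm <- fit_glm(s, d)
  expect_gte(abs(spm$tstat[1, 1, 1, 1]), 1e6)
  expect_equal(spm$p[1, 1, 1, 1], 0)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  p <- single_temp_protocol(temps = 54, onsets = 40)
  d <- build_design(p, n_volumes = 60, tr_eff = 4)
  d$X <- cbind(d$X, dup = d$X[, "T54"])
  s <- bold_series(array(rnorm(60, 100), dim = c(1, 1, 1, 60)), tr = 4)
  expect_error(fit_glm(s, d), "collinear")
})

test_that("the voxel test holds its nominal size on white-noise phantoms", {
  p <- build_stimulus_protocol(1, seed = 9)
  d <- build_design(p, n_volumes = 510, tr_eff = 4)
  set.seed(42)
  arr <- array(100 * (1 + 0.01 * rnorm(1000 * 510)),
               dim = c(10, 10, 10, 510))
  s <- bold_series(arr, tr = 4)
  spm <- fit_glm(s, d)
  frac <- mean(spm$p[, , , 1] < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("BH-FDR matches the brute-force step-up on a worked example", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.074, 0.205, 0.212,
         0.216)
  vol <- array(p, dim = c(10, 1, 1))
  mask <- array(TRUE, dim = c(10, 1, 1))
  got <- fdr_correct(vol, 0.05, mask)
  expect_equal(as.vector(got), bh_oracle(p, 0.05))
  # degenerate inputs
  expect_true(all(fdr_correct(array(0, dim = c(5, 1, 1)), 0.05,
                              array(TRUE, dim = c(5, 1, 1)))))
  expect_false(any(fdr_correct(array(1, dim = c(5, 1, 1)), 0.05,
                               array(TRUE, dim = c(5, 1, 1)))))
  expect_warning(fdr_correct(vol, 0.05, array(FALSE, dim = c(10, 1, 1))),
                 "empty")
})

test_that("enlarging q never shrinks the BH rejection set", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(50)^2
    vol <- array(p, dim = c(50, 1, 1))
    mask <- array(TRUE, dim = c(50, 1, 1))
    r1 <- fdr_correct(vol, 0.03, mask)
    r2 <- fdr_correct(vol, 0.10, mask)
    expect_true(all(r2[r1]))
  }
})
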