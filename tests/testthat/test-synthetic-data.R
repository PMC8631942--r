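test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 7), "sim_config")
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(image_shape = c(8, 64)), "16 px")
})

test_that("gen_isotherm reproduces the Langmuir curve", {
  # half-saturation and saturation limits, noiseless
  g <- gen_isotherm(kd = 100, r_max = 100, concentrations = c(20, 50, 100, 1e9),
                    noise_sd = 0)
  expect_equal(g$isotherm$response_RU[g$isotherm$concentration_nM == 100], 50)
  expect_equal(g$isotherm$response_RU[4], 100, tolerance = 1e-6)
  # noisy responses stay within 4 sd of the noiseless curve (oracle: direct
  # Langmuir evaluation at kd = 0.10 uM)
  g2 <- gen_isotherm(kd = 100, r_max = 200, noise_sd = 2, seed = 1)
  expected <- oracle_langmuir(100, 200, g2$isotherm$concentration_nM)
  expect_true(all(abs(g2$isotherm$response_RU - expected) < 8))
  expect_length(g2$isotherm$response_RU, 6)
})

test_that("gen_isotherm rejects invalid parameters", {
  expect_error(gen_isotherm(kd = -1, r_max = 100), "positive")
  expect_error(gen_isotherm(kd = 100, r_max = 100, concentrations = c(1, 2, 3)),
               ">= 4")
})

test_that("generators are deterministic given the seed", {
  a <- gen_isotherm(100, 100, noise_sd = 2, seed = 42)
  b <- gen_isotherm(100, 100, noise_sd = 2, seed = 42)
  expect_identical(a, b)
  cfg <- sim_config(seed = 11, image_shape = c(32, 32), gaussian_sd = 2)
  ta <- gen_trajectory(0.5, 0.5, duration = 10, config = cfg)
  tb <- gen_trajectory(0.5, 0.5, duration = 10, config = cfg)
  expect_identical(ta, tb)
  ma <- gen_two_channel_movie(3, n_frames = 5, config = cfg)
  mb <- gen_two_channel_movie(3, n_frames = 5, config = cfg)
  expect_identical(ma, mb)
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_isotherm(100, 100, noise_sd = 2, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("gen_trajectory produces a two-level telegraph signal", {
  cfg <- sim_config(seed = 2)
  g <- gen_trajectory(0.5, 0.5, mu_unbound = 0, mu_bound = 100, sigma = 0,
                      duration = 60, config = cfg)
  expect_setequal(unique(g$trajectory$intensities), c(0, 100))
  # absorbing unbound state
  g0 <- gen_trajectory(0, 0.5, duration = 10, config = cfg,
                       start_state = "unbound")
  expect_true(all(g0$states == 1L))
  expect_error(gen_trajectory(0.5, 0.5, mu_unbound = 10, mu_bound = 5),
               "mu_bound")
})

test_that("bound dwells pooled over seeds have mean 1/k_off", {
  # long trajectories keep the window-truncation bias of complete interior
  # dwells below 1% (interior dwells in a window of length T are length
  # biased: E = (T/k - 2/k^2)/(T - 1/k))
  k_off <- 0.2
  dwells <- c()
  for (s in 1:10) {
    g <- gen_trajectory(0.5, k_off, duration = 500,
                        config = sim_config(seed = s))
    r <- rle(g$states)
    keep <- r$values == 2L & seq_along(r$values) > 1 &
      seq_along(r$values) < length(r$values)
    dwells <- c(dwells, r$lengths[keep] * 0.05)
  }
  expect_gt(length(dwells), 200)
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 1 / k_off), 2 * se + 0.1)
})

test_that("two-channel movie matches its ground truth", {
  cfg0 <- sim_config(seed = 5, image_shape = c(48, 48), gaussian_sd = 0)
  # no receptors: pure noise frames
  m0 <- gen_two_channel_movie(0, n_frames = 3,
                              config = sim_config(seed = 5, image_shape = c(48, 48),
                                                  gaussian_sd = 1))
  expect_equal(dim(m0$receptor), c(48, 48, 3))
  expect_lt(max(abs(m0$receptor)), 6)
  # noiseless: exactly n local maxima at ground-truth positions
  m5 <- gen_two_channel_movie(5, n_frames = 2, amplitude = 100, config = cfg0)
  fr <- m5$receptor[, , 1]
  at_truth <- mapply(function(x, y) fr[round(y) + 1, round(x) + 1],
                     m5$ground_truth$x, m5$ground_truth$y)
  expect_true(all(at_truth > 50))
  # lit fraction of the ligand channel approximates the stationary bound
  # fraction k_on/(k_on+k_off) = 0.3
  cfg <- sim_config(seed = 6, image_shape = c(64, 64), gaussian_sd = 0)
  mv <- gen_two_channel_movie(12, k_on_eff = 0.3, k_off = 0.7,
                              n_frames = 400, config = cfg)
  lit <- mean(mv$ground_truth$states == 2L)
  expect_lt(abs(lit - 0.3), 0.08)
})

test_that("movie placement respects the minimum-distance precondition", {
  cfg <- sim_config(seed = 1, image_shape = c(20, 20))
  expect_error(gen_two_channel_movie(50, n_frames = 1, psf_sigma = 2,
                                     config = cfg, max_attempts = 200),
               "density")
  m <- gen_two_channel_movie(4, n_frames = 1, psf_sigma = 1.3,
                             config = sim_config(seed = 2, image_shape = c(64, 64)))
  d <- as.matrix(dist(cbind(m$ground_truth$x, m$ground_truth$y)))
  diag(d) <- Inf
  expect_gt(min(d), 4 * 1.3)
})

test_that("gen_cluster_image encodes the enrichment factor exactly when noiseless", {
  cfg <- sim_config(seed = 3, image_shape = c(96, 96), gaussian_sd = 0)
  ci <- gen_cluster_image(5, enrichment = 3, footprint_level = 0,
                          effector_background = 0, config = cfg)
  on_blob <- ci$receptor > 1
  expect_true(any(on_blob))
  expect_equal(ci$effector[on_blob], 3 * ci$receptor[on_blob], tolerance = 1e-12)
  # enrichment 0: effector flat over blob mask vs off-blob (within noise)
  cfgn <- sim_config(seed = 4, image_shape = c(96, 96), gaussian_sd = 1)
  c0 <- gen_cluster_image(5, enrichment = 0, config = cfgn)
  blob <- c0$receptor > c0$ground_truth$footprint_level +
    0.3 * c0$ground_truth$cluster_amplitude
  inside_off <- c0$footprint & !blob
  expect_lt(abs(mean(c0$effector[blob]) - mean(c0$effector[inside_off])), 1)
})

test_that("ground truth round-trips through JSON serialization", {
  g <- gen_isotherm(100, 150, noise_sd = 2, seed = 13)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(g$ground_truth), path, auto_unbox = TRUE,
                       digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$kd, g$ground_truth$kd)
  expect_equal(back$r_max, g$ground_truth$r_max)
  expect_equal(back$noise_sd, g$ground_truth$noise_sd)
  expect_equal(back$seed, g$ground_truth$seed, ignore_attr = TRUE)
})
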