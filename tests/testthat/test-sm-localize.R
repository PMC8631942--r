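render <- sh2spec:::render_spots

test_that("blank noise frames yield essentially no detections at 5 sigma", {
  set.seed(15)
  n_spots <- sum(vapply(1:20, function(i) {
    fr <- matrix(rnorm(64 * 64), 64, 64)
    nrow(detect_spots(fr, threshold_sigmas = 5))
  }, 0L))
  expect_lte(n_spots, 1)
  expect_warning(detect_spots(matrix(1, 32, 32)), "constant")
})

test_that("a noiseless Gaussian spot localizes to < 0.05 px", {
  img <- render(32, 32, 10.3, 20.7, 100, 1.3)
  set.seed(1)
  sp <- detect_spots(img + matrix(rnorm(1024, 0, 1e-8), 32, 32))
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x - 10.3), 0.05)
  expect_lt(abs(sp$y - 20.7), 0.05)
  expect_equal(sp$amplitude, 100, tolerance = 1e-3)
})

test_that("five well-separated spots at SNR 10 localize within 0.5 px", {
  set.seed(33)
  gx <- c(8.2, 25.7, 40.1, 12.9, 50.4)
  gy <- c(9.5, 14.3, 30.8, 44.2, 52.6)
  img <- render(64, 64, gx, gy, rep(100, 5), 1.3) +
    matrix(rnorm(64 * 64, 0, 10), 64, 64)
  sp <- detect_spots(img, threshold_sigmas = 5)
  expect_equal(nrow(sp), 5)
  for (i in 1:5) {
    d <- sqrt(min((sp$x - gx[i])^2 + (sp$y - gy[i])^2))
    expect_lt(d, 0.5)
  }
})

test_that("localization is translation equivariant under integer shifts", {
  set.seed(4)
  base <- render(64, 64, c(20.4, 35.1), c(22.7, 40.2), c(90, 110), 1.3) +
    matrix(rnorm(64 * 64, 0, 3), 64, 64)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  sp0 <- detect_spots(base)
  sp1 <- detect_spots(shift(base, 5, 7))
  sp0 <- sp0[order(sp0$x), ]; sp1 <- sp1[order(sp1$x), ]
  expect_equal(sp1$x, sp0$x + 7, tolerance = 1e-3)
  expect_equal(sp1$y, sp0$y + 5, tolerance = 1e-3)
})

test_that("detection on generator movies matches ground truth at high SNR", {
  cfg <- sim_config(seed = 21, image_shape = c(96, 96), gaussian_sd = 2)
  mv <- gen_two_channel_movie(10, n_frames = 3, amplitude = 100, config = cfg)
  missed <- 0; false_pos <- 0
  for (f in 1:3) {
    sp <- detect_spots(mv$receptor[, , f])
    for (i in 1:10) {
      d2 <- (sp$x - mv$ground_truth$x[i])^2 + (sp$y - mv$ground_truth$y[i])^2
      if (!length(d2) || min(d2) > 1) missed <- missed + 1
    }
    false_pos <- false_pos + max(0, nrow(sp) - 10)
  }
  expect_lte(missed / 30, 0.02)
  expect_lte(false_pos / 30, 0.02)
})

test_that("intensity histogram model selection distinguishes one from two populations", {
  set.seed(6)
  one <- rnorm(400, 100, 15)
  f1 <- intensity_histogram_fit(one)
  expect_equal(f1$n_components, 1L)
  expect_lt(abs(f1$means - 100), 3 * 15 / sqrt(400))
  two <- c(rnorm(200, 50, 10), rnorm(200, 150, 10))
  f2 <- intensity_histogram_fit(two)
  expect_equal(f2$n_components, 2L)
  expect_equal(sort(f2$means), c(50, 150), tolerance = 0.05)
  # constant plus tiny noise: one component at the constant
  tiny <- 80 + rnorm(100, 0, 1e-3)
  f3 <- intensity_histogram_fit(tiny)
  expect_equal(f3$n_components, 1L)
  expect_equal(unname(f3$means), 80, tolerance = 1e-3)
  expect_error(intensity_histogram_fit(rep(5, 100)), "degenerate")
  expect_error(intensity_histogram_fit(rnorm(10)), ">= 50")
})

test_that("bleach step counting finds single and double steps and ignores flat traces", {
  flat <- make_step_trace(100, 200, sd = 8, seed = 2)
  expect_equal(count_bleach_steps(flat)$step_count, 0)
  one <- make_step_trace(c(100, 0), c(120, 80), sd = 100 / 8, seed = 3)
  bp1 <- count_bleach_steps(one)
  expect_equal(bp1$step_count, 1)
  expect_true(all(bp1$step_sizes < 0))
  two <- make_step_trace(c(200, 100, 0), c(70, 70, 60), sd = 100 / 8, seed = 4)
  expect_equal(count_bleach_steps(two)$step_count, 2)
})

test_that("the sum of two single-step traces has two steps (noiseless)", {
  a <- rep(c(100, 0), c(50, 150))
  b <- rep(c(100, 0), c(120, 80))
  y <- a + b + rnorm(200, 0, 1e-3)
  expect_equal(count_bleach_steps(y)$step_count, 2)
})

test_that("single-step classification succeeds in >= 90% of replicates at SNR 8", {
  hits <- vapply(1:40, function(s) {
    set.seed(s + 7000)
    bleach_at <- sample(60:140, 1)
    y <- make_step_trace(c(100, 0), c(bleach_at, 200 - bleach_at),
                         sd = 100 / 8, seed = s)
    count_bleach_steps(y)$step_count == 1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("colocalization has the right limits and monotonicity", {
  spots <- structure(data.frame(frame = 1L, channel = 1L,
                                x = c(5, 15, 25), y = c(5, 15, 25),
                                amplitude = 100, sigma = 1.3),
                     class = c("spot_table", "data.frame"))
  empty <- spots[0, ]
  expect_equal(as.numeric(colocalization_rate(spots, spots)), 1)
  expect_equal(as.numeric(colocalization_rate(spots, empty)), 0)
  expect_error(colocalization_rate(empty, spots), "undefined")
  # monotone in radius
  lig <- spots; lig$x <- lig$x + c(0.5, 2.5, 6)
  r1 <- as.numeric(colocalization_rate(spots, lig, radius = 1))
  r3 <- as.numeric(colocalization_rate(spots, lig, radius = 3))
  r10 <- as.numeric(colocalization_rate(spots, lig, radius = 10))
  expect_true(r1 <= r3 && r3 <= r10)
  expect_equal(c(r1, r3, r10), c(1/3, 2/3, 1))
})

test_that("colocalization rate matches the analytic window-binding probability", {
  # 0.5-s acquisition (10 frames): P(bound at least once) = 0.30 analytically
  k_on <- 0.3; k_off <- 1.2
  p_exp <- oracle_p_bound_once(k_on, k_off, 10, 0.05)
  expect_equal(p_exp, 0.30, tolerance = 0.01)
  hits <- 0; total <- 0
  for (s in 1:4) {
    cfg <- sim_config(seed = 6000 + s, image_shape = c(128, 128), gaussian_sd = 2)
    mv <- gen_two_channel_movie(60, k_on_eff = k_on, k_off = k_off,
                                n_frames = 10, amplitude = 100, config = cfg,
                                max_attempts = 20000)
    rec <- detect_spots(mv$receptor[, , 1])
    lig <- detect_spots_stack(mv$ligand, frame_rate = 20)
    r <- colocalization_rate(rec, lig, radius = 2, window = 0.5)
    hits <- hits + as.numeric(r) * attr(r, "n_receptors")
    total <- total + attr(r, "n_receptors")
  }
  expect_gt(total, 200)
  se <- sqrt(p_exp * (1 - p_exp) / total)
  expect_lt(abs(hits / total - p_exp), 3 * se + 0.03)
})

test_that("image stacks and spot tables round-trip through text files", {
  cfg <- sim_config(seed = 12, image_shape = c(24, 24), gaussian_sd = 1)
  mv <- gen_two_channel_movie(2, n_frames = 3, config = cfg)
  p <- tempfile(fileext = ".txt")
  write_image_stack(mv$receptor, p)
  back <- read_image_stack(p)
  expect_equal(dim(back), dim(mv$receptor))
  expect_equal(back, mv$receptor, tolerance = 1e-6)
  sp <- detect_spots(mv$receptor[, , 1])
  p2 <- tempfile(fileext = ".csv")
  write_spot_table(sp, p2)
  sp2 <- read_spot_table(p2)
  expect_equal(sp2$x, sp$x)
  expect_equal(sp2$amplitude, sp$amplitude)
})
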