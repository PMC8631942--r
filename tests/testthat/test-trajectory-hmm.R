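make_trajs <- function(n, k_on, k_off, sigma = 10, duration = 100, seed0 = 100) {
  out <- lapply(seq_len(n), function(i)
    gen_trajectory(k_on, k_off, mu_unbound = 0, mu_bound = 100, sigma = sigma,
                   duration = duration, config = sim_config(seed = seed0 + i)))
  list(trajs = lapply(out, `[[`, "trajectory"),
       states = lapply(out, `[[`, "states"))
}

test_that("containers validate their invariants", {
  expect_error(trajectory(1:5), ">= 10")
  expect_error(hmm_params(c(5, 1), c(1, 1), diag(2)), "mu_bound")
  expect_error(hmm_params(c(0, 1), c(1, 1), matrix(c(0.5, 0.4, 0.4, 0.6), 2)),
               "sum to 1")
})

test_that("Baum-Welch recovers generating parameters within 5% (pooled trajectories)", {
  sim <- make_trajs(15, k_on = 0.4, k_off = 1.0, seed0 = 300)
  fit <- fit_hmm(sim$trajs)
  p <- fit$params
  expect_lt(abs(p$mu[1] - 0) , 1)            # absolute: mu_unbound = 0
  expect_lt(abs(p$mu[2] - 100) / 100, 0.05)
  expect_lt(abs(p$sigma[1] - 10) / 10, 0.05)
  expect_lt(abs(p$sigma[2] - 10) / 10, 0.05)
  # per-frame stay probabilities approx exp(-rate*dt)
  expect_lt(abs(p$A[1, 2] - (1 - exp(-0.4 * 0.05))), 0.005)
  expect_lt(abs(p$A[2, 1] - (1 - exp(-1.0 * 0.05))), 0.01)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  sim <- make_trajs(3, 0.5, 0.5, seed0 = 40)
  fit <- fit_hmm(sim$trajs, max_iter = 50)
  expect_true(all(diff(fit$loglik_trace) > -1e-7 * abs(fit$loglik_trace[-1])))
})

test_that("noiseless two-level trace gives exact means and empirical switch counts", {
  g <- gen_trajectory(0.5, 0.5, mu_unbound = 0, mu_bound = 100, sigma = 0,
                      duration = 50, config = sim_config(seed = 9))
  # add negligible jitter so the likelihood stays proper
  y <- g$trajectory$intensities + rnorm(length(g$trajectory$intensities), 0, 1e-4)
  tr <- trajectory(y, 0.05)
  fit <- fit_hmm(tr, sigma_floor = 1e-6)
  expect_equal(fit$params$mu, c(0, 100), tolerance = 1e-3)
  s <- g$states
  n12 <- sum(s[-length(s)] == 1 & s[-1] == 2)
  n11 <- sum(s[-length(s)] == 1 & s[-1] == 1)
  expect_equal(fit$params$A[1, 2], n12 / (n11 + n12), tolerance = 1e-3)
  # degenerate single-level data errors
  expect_error(fit_hmm(trajectory(rep(5, 300), 0.05)), "degenerate")
})

test_that("Viterbi decoding is exact on noiseless traces and matches exhaustive search", {
  g <- gen_trajectory(0.5, 0.5, sigma = 0, duration = 50,
                      config = sim_config(seed = 5))
  params <- hmm_params(c(0, 100), c(1, 1),
                       matrix(c(0.975, 0.025, 0.025, 0.975), 2, byrow = TRUE))
  dec <- viterbi_decode(g$trajectory, params)
  expect_identical(dec$states, g$states)
  # brute force over all 2^12 paths of a short noisy trace
  set.seed(8)
  y <- c(rnorm(6, 0, 15), rnorm(6, 100, 15))[sample(12)]
  tr <- trajectory(y, 0.05)
  p2 <- hmm_params(c(0, 100), c(15, 15),
                   matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                   pi0 = c(0.6, 0.4))
  dec2 <- viterbi_decode(tr, p2)
  oracle <- oracle_viterbi_exhaustive(y, p2$mu, p2$sigma, p2$A, p2$pi0)
  expect_identical(dec2$states, oracle$path)
  expect_equal(dec2$loglik, oracle$logprob, tolerance = 1e-9)
})

test_that("decoding accuracy is >= 99% at SNR 10", {
  sim <- make_trajs(10, 0.3, 0.5, sigma = 10, seed0 = 500)
  fit <- fit_hmm(sim$trajs)
  acc <- mean(unlist(lapply(seq_along(sim$trajs), function(i)
    viterbi_decode(sim$trajs[[i]], fit$params)$states == sim$states[[i]])))
  expect_gte(acc, 0.99)
})

test_that("relabeling symmetry: negated intensities with swapped labels mirror the decoding", {
  sim <- make_trajs(1, 0.4, 0.6, seed0 = 77)
  tr <- sim$trajs[[1]]
  p <- hmm_params(c(0, 100), c(10, 12),
                  matrix(c(0.98, 0.02, 0.03, 0.97), 2, byrow = TRUE))
  dec <- viterbi_decode(tr, p)
  neg <- trajectory(-tr$intensities, tr$frame_interval)
  p_mirror <- hmm_params(c(-100, 0), rev(p$sigma), p$A[2:1, 2:1], rev(p$pi0))
  dec_m <- viterbi_decode(neg, p_mirror)
  expect_identical(dec_m$states, 3L - dec$states)
})

test_that("dwell_times run-length encodes with censoring flags", {
  # alternating states: every dwell one frame
  alt <- rep(c(2L, 1L), 10)
  dw <- dwell_times(alt, frame_interval = 0.05)
  expect_true(all(c(dw$bound, dw$unbound) == 0.05))
  # total time conserved
  expect_equal(sum(dw$bound) + sum(dw$unbound), length(alt) * 0.05)
  # all-bound: one doubly censored dwell
  ab <- dwell_times(rep(2L, 40), frame_interval = 0.05)
  expect_length(ab$bound, 1)
  expect_equal(ab$bound, 2)
  expect_true(all(ab$bound_censored))
  expect_length(ab$unbound, 0)
})

test_that("pooled decoded dwells give the exponential mean 1/k_off", {
  sim <- make_trajs(20, 0.5, 0.2, duration = 100, seed0 = 900)
  fit <- fit_hmm(sim$trajs)
  dw <- do.call(c, lapply(sim$trajs, function(tr)
    dwell_times(viterbi_decode(tr, fit$params))))
  b <- dw$bound[!dw$bound_censored]
  expect_gt(length(b), 100)
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b) - 5), 2 * se + 0.2)
})

test_that("estimate_rates inverts dwell means with censored dwells excluded", {
  states <- c(rep(1L, 10), rep(c(rep(2L, 20), rep(1L, 10)), 4))
  dw <- dwell_times(states, frame_interval = 0.05)
  r <- estimate_rates(dw, min_dwells = 3)
  expect_equal(r$k_off, 1.0)       # four exact 1-s bound dwells
  expect_equal(r$k_on_eff, 2.0)    # three 0.5-s unbound dwells
  expect_equal(r$k_off_se, 1 / sqrt(4))
  expect_error(estimate_rates(dw, min_dwells = 10), "BOUND")
})

test_that("rate recovery from simulation is within 10% and frame-rate invariant", {
  sim <- make_trajs(25, 0.1, 0.5, duration = 200, seed0 = 1200)
  fit <- fit_hmm(sim$trajs)
  dw <- do.call(c, lapply(sim$trajs, function(tr)
    dwell_times(viterbi_decode(tr, fit$params))))
  r <- estimate_rates(dw)
  expect_gt(r$n_bound + r$n_unbound, 500)
  expect_lt(abs(r$k_off - 0.5) / 0.5, 0.10)
  expect_lt(abs(r$k_on_eff - 0.1) / 0.1, 0.10)
  # halving the frame interval (40 Hz) leaves estimates consistent
  out40 <- lapply(1:25, function(i)
    gen_trajectory(0.1, 0.5, sigma = 10, duration = 200,
                   config = sim_config(seed = 3000 + i, frame_rate = 40)))
  fit40 <- fit_hmm(lapply(out40, `[[`, "trajectory"))
  dw40 <- do.call(c, lapply(out40, function(o)
    dwell_times(viterbi_decode(o$trajectory, fit40$params))))
  r40 <- estimate_rates(dw40)
  expect_lt(abs(r40$k_off - r$k_off) / r$k_off, 0.15)
  expect_lt(abs(r40$k_on_eff - r$k_on_eff) / r$k_on_eff, 0.15)
})

test_that("decoded occupancy matches the stationary bound fraction", {
  sim <- make_trajs(20, 0.3, 0.7, duration = 100, seed0 = 2000)
  fit <- fit_hmm(sim$trajs)
  occ <- mean(unlist(lapply(sim$trajs, function(tr)
    viterbi_decode(tr, fit$params)$states == 2L)))
  p_b <- 0.3 / (0.3 + 0.7)
  n <- 20 * 2000
  expect_lt(abs(occ - p_b), 5 * sqrt(p_b * (1 - p_b) / n) + 0.02)
})

test_that("trajectories round-trip through CSV with decoded states", {
  sim <- make_trajs(2, 0.5, 0.5, duration = 10, seed0 = 60)
  sim$trajs[[1]]$molecule_id <- "m1"; sim$trajs[[2]]$molecule_id <- "m2"
  fit <- fit_hmm(sim$trajs)
  decs <- lapply(sim$trajs, viterbi_decode, params = fit$params)
  path <- tempfile(fileext = ".csv")
  write_trajectories(sim$trajs, path, states = decs)
  back <- read_trajectories(path)
  expect_length(back, 2)
  expect_equal(back$m1$intensities, sim$trajs[[1]]$intensities)
  expect_equal(back$m2$frame_interval, 0.05, tolerance = 1e-9)
  expect_true("state" %in% names(utils::read.csv(path)))
})
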