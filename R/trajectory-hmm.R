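#' Single-molecule intensity trajectory
#'
#' Per-frame fluorescence intensities of one molecule, with the frame
#' interval in seconds (default 0.05 s, i.e. 20 Hz acquisition).
#'
#' @param intensities numeric vector, >= 10 finite values.
#' @param frame_interval seconds per frame.
#' @param molecule_id label.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(intensities, frame_interval = 0.05,
                       molecule_id = "mol") {
  assert_that(length(intensities) >= 10, "trajectory needs >= 10 frames")
  assert_that(all(is.finite(intensities)), "intensities must be finite")
  assert_that(frame_interval > 0, "frame_interval must be positive")
  structure(list(intensities = as.numeric(intensities),
                 frame_interval = frame_interval,
                 molecule_id = molecule_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s: %d frames at %g s/frame (%.1f s)\n",
              x$molecule_id, length(x$intensities), x$frame_interval,
              length(x$intensities) * x$frame_interval))
  invisible(x)
}

#' Two-state Gaussian HMM parameters
#'
#' Parameters of the bound/unbound hidden Markov model: state emission
#' means and standard deviations, a row-stochastic 2x2 transition matrix
#' and an initial distribution. State 1 is UNBOUND, state 2 is BOUND; the
#' label convention `mu_bound > mu_unbound` is enforced.
#'
#' @param mu length-2 means `c(unbound, bound)`.
#' @param sigma length-2 standard deviations, positive.
#' @param A 2x2 transition matrix, rows summing to 1.
#' @param pi0 initial distribution, summing to 1.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, A, pi0 = c(0.5, 0.5)) {
  assert_that(length(mu) == 2 && mu[2] > mu[1],
              "mu must be length 2 with mu_bound > mu_unbound")
  assert_that(all(sigma > 0), "sigmas must be positive")
  assert_that(all(abs(rowSums(A) - 1) < 1e-12), "transition rows must sum to 1")
  assert_that(abs(sum(pi0) - 1) < 1e-12 && all(pi0 >= 0), "pi0 must be a distribution")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 A = matrix(as.numeric(A), 2, 2), pi0 = as.numeric(pi0)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Two-state Gaussian HMM\n")
  cat(sprintf("  unbound: mu = %.3g, sigma = %.3g\n", x$mu[1], x$sigma[1]))
  cat(sprintf("  bound:   mu = %.3g, sigma = %.3g\n", x$mu[2], x$sigma[2]))
  cat(sprintf("  A = [%.4f %.4f; %.4f %.4f], pi0 = (%.3f, %.3f)\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$pi0[1], x$pi0[2]))
  invisible(x)
}

as_traj_list <- function(trajs) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  lapply(trajs, function(tr) {
    stopifnot(inherits(tr, "trajectory"))
    tr
  })
}

# deterministic 2-means split of pooled intensities (single 1-D Lloyd run
# started from the 10% / 90% quantiles)
two_means_init <- function(y) {
  cen <- stats::quantile(y, c(0.1, 0.9), names = FALSE)
  if (diff(cen) == 0) cen <- cen + c(-1, 1) * max(1e-6, stats::sd(y), na.rm = TRUE)
  for (i in 1:50) {
    lab <- (abs(y - cen[2]) < abs(y - cen[1])) + 1L
    new_cen <- c(mean(y[lab == 1L]), mean(y[lab == 2L]))
    if (anyNA(new_cen) || all(abs(new_cen - cen) < 1e-10)) break
    cen <- new_cen
  }
  lab <- (abs(y - cen[2]) < abs(y - cen[1])) + 1L
  list(centers = cen, labels = lab)
}

#' Fit a two-state Gaussian HMM by Baum-Welch
#'
#' Maximum-likelihood estimation of the bound/unbound HMM from one or more
#' intensity trajectories (pooled). Initialization is a deterministic
#' 2-means split of the pooled intensities, so the fit is reproducible
#' without a random seed. The EM log-likelihood is non-decreasing by
#' construction; emission variances are untied between states.
#'
#' @param trajs a [trajectory()] or list of them; >= 200 pooled frames.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param sigma_floor lower bound on emission s.d. to keep the likelihood
#'   bounded (default 1e-3 in intensity units).
#' @return a list: `params` ([hmm_params()]), `loglik` (final), `loglik_trace`,
#'   `converged`, `n_iter`.
#' @export
fit_hmm <- function(trajs, max_iter = 500, tol = 1e-8, sigma_floor = 1e-3) {
  trajs <- as_traj_list(trajs)
  ys <- lapply(trajs, `[[`, "intensities")
  pooled <- unlist(ys)
  assert_that(length(pooled) >= 200, "need >= 200 pooled frames")
  if (stats::sd(pooled) < sigma_floor)
    stop_invalid("degenerate fit: trajectory has a single intensity level")

  km <- two_means_init(pooled)
  mu <- sort(km$centers)
  sigma <- pmax(c(stats::sd(pooled[km$labels == which.min(km$centers)]),
                  stats::sd(pooled[km$labels == which.max(km$centers)])),
                sigma_floor)
  sigma[is.na(sigma)] <- sigma_floor
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  pi0 <- c(0.5, 0.5)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # E-step over all trajectories
    ll <- 0
    g_sum <- numeric(2); g1_sum <- numeric(2)
    wy <- numeric(2); wy2 <- numeric(2)
    xi <- matrix(0, 2, 2)
    gammas <- vector("list", length(ys))
    for (i in seq_along(ys)) {
      fb <- fb_gauss(ys[[i]], mu, sigma, A, pi0)
      ll <- ll + fb$loglik
      g <- fb$gamma
      gammas[[i]] <- g
      g_sum <- g_sum + colSums(g)
      g1_sum <- g1_sum + g[1, ]
      wy <- wy + colSums(g * ys[[i]])
      xi <- xi + fb$xi_sum
    }
    ll_trace <- c(ll_trace, ll)
    # M-step
    mu_new <- wy / g_sum
    for (k in 1:2) {
      s2 <- 0
      for (i in seq_along(ys))
        s2 <- s2 + sum(gammas[[i]][, k] * (ys[[i]] - mu_new[k])^2)
      sigma[k] <- max(sqrt(s2 / g_sum[k]), sigma_floor)
    }
    mu <- mu_new
    A <- xi / rowSums(xi)
    pi0 <- g1_sum / sum(g1_sum)
    # enforce label convention
    if (mu[1] > mu[2]) {
      mu <- rev(mu); sigma <- rev(sigma); pi0 <- rev(pi0)
      A <- A[2:1, 2:1]
    }
    n_ll <- length(ll_trace)
    if (n_ll >= 2 &&
        abs(ll_trace[n_ll] - ll_trace[n_ll - 1]) <
          tol * (abs(ll_trace[n_ll - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(params = hmm_params(mu, sigma, A, pi0),
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = iter)
}

#' Viterbi decoding of a trajectory
#'
#' Most-probable bound/unbound state path under a fitted HMM. Ties are
#' broken toward UNBOUND.
#'
#' @param traj a [trajectory()].
#' @param params an [hmm_params()].
#' @return a `state_sequence`: list with `states` (integer, 1 = UNBOUND,
#'   2 = BOUND), `labels` (factor), `loglik` of the decoded path, and the
#'   `frame_interval`.
#' @export
viterbi_decode <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "hmm_params"))
  v <- viterbi_gauss(traj$intensities, params$mu, params$sigma,
                     params$A, params$pi0)
  structure(list(states = as.integer(v$path),
                 labels = factor(c("UNBOUND", "BOUND")[v$path],
                                 levels = c("UNBOUND", "BOUND")),
                 loglik = v$logprob,
                 frame_interval = traj$frame_interval,
                 molecule_id = traj$molecule_id),
            class = "state_sequence")
}

#' Dwell times from a decoded state sequence
#'
#' Run-length encodes the state path and converts run lengths to seconds.
#' The first and last dwells of a trajectory are censored (their true
#' extent is unobserved) and flagged as such.
#'
#' @param seq a `state_sequence` from [viterbi_decode()], or a plain
#'   integer vector of states (1/2).
#' @param frame_interval seconds per frame (taken from `seq` if absent).
#' @return a `dwell_times` list: `bound`, `unbound` (seconds),
#'   `bound_censored`, `unbound_censored` (logical flags, same order).
#' @export
dwell_times <- function(seq, frame_interval = NULL) {
  if (inherits(seq, "state_sequence")) {
    states <- seq$states
    frame_interval <- frame_interval %||% seq$frame_interval
  } else {
    states <- as.integer(seq)
    assert_that(!is.null(frame_interval), "frame_interval required for raw state vectors")
  }
  r <- rle(states)
  n <- length(r$lengths)
  censored <- seq_len(n) %in% c(1L, n)
  dur <- r$lengths * frame_interval
  is_bound <- r$values == 2L
  structure(list(bound = dur[is_bound], unbound = dur[!is_bound],
                 bound_censored = censored[is_bound],
                 unbound_censored = censored[!is_bound],
                 frame_interval = frame_interval),
            class = "dwell_times")
}

# concatenate dwell_times objects (pooling across molecules)
#' @export
c.dwell_times <- function(...) {
  parts <- list(...)
  structure(list(bound = unlist(lapply(parts, `[[`, "bound")),
                 unbound = unlist(lapply(parts, `[[`, "unbound")),
                 bound_censored = unlist(lapply(parts, `[[`, "bound_censored")),
                 unbound_censored = unlist(lapply(parts, `[[`, "unbound_censored")),
                 frame_interval = parts[[1]]$frame_interval),
            class = "dwell_times")
}

#' Estimate binding rates from dwell times
#'
#' Exponential-dwell maximum likelihood: `k_off` is the reciprocal mean of
#' uncensored bound dwells and `k_on_eff` (pseudo-first-order, at the
#' working ligand concentration) the reciprocal mean of uncensored unbound
#' dwells. Standard errors use the exponential-mean formula
#' \eqn{se(k) = k/\sqrt{n}}. Dwells shorter than about two frames are
#' undersampled by the camera, biasing rates upward when dwell times
#' approach the frame interval.
#'
#' @param dwells a `dwell_times` object (possibly pooled with `c()`).
#' @param min_dwells minimum number of uncensored dwells per state
#'   (default 10).
#' @return a `kinetic_rates` list: `k_off`, `k_on_eff` (1/s), `k_off_se`,
#'   `k_on_eff_se`, `n_bound`, `n_unbound`.
#' @export
estimate_rates <- function(dwells, min_dwells = 10) {
  stopifnot(inherits(dwells, "dwell_times"))
  b <- dwells$bound[!dwells$bound_censored]
  u <- dwells$unbound[!dwells$unbound_censored]
  if (length(b) < min_dwells)
    stop_invalid("insufficient uncensored BOUND dwells (", length(b), " < ", min_dwells, ")")
  if (length(u) < min_dwells)
    stop_invalid("insufficient uncensored UNBOUND dwells (", length(u), " < ", min_dwells, ")")
  k_off <- 1 / mean(b)
  k_on <- 1 / mean(u)
  structure(list(k_off = k_off, k_on_eff = k_on,
                 k_off_se = k_off / sqrt(length(b)),
                 k_on_eff_se = k_on / sqrt(length(u)),
                 n_bound = length(b), n_unbound = length(u)),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf("k_off = %.4g 1/s (se %.2g, n=%d); k_on_eff = %.4g 1/s (se %.2g, n=%d)\n",
              x$k_off, x$k_off_se, x$n_bound,
              x$k_on_eff, x$k_on_eff_se, x$n_unbound))
  invisible(x)
}

#' Read / write trajectories (CSV)
#'
#' Long-format CSV `molecule_id,time_s,intensity` (plus `state` when
#' decoded sequences are written alongside).
#'
#' @param path file path.
#' @return list of [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$molecule_id), function(sub) {
    sub <- sub[order(sub$time_s), ]
    dt <- stats::median(diff(sub$time_s))
    trajectory(sub$intensity, frame_interval = dt,
               molecule_id = sub$molecule_id[1])
  })
}

#' @rdname read_trajectories
#' @param trajs list of [trajectory()] objects (or one).
#' @param states optional list of `state_sequence`s matching `trajs`.
#' @export
write_trajectories <- function(trajs, path, states = NULL) {
  trajs <- as_traj_list(trajs)
  rows <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    out <- data.frame(molecule_id = tr$molecule_id,
                      time_s = (seq_along(tr$intensities) - 1) * tr$frame_interval,
                      intensity = tr$intensities)
    if (!is.null(states)) out$state <- as.character(states[[i]]$labels)
    out
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
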