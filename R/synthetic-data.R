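#' Simulation configuration
#'
#' Bundles acquisition parameters shared by the synthetic-data generators:
#' the pseudorandom seed, camera frame rate, pixel size, image geometry and
#' the noise model. Defaults mirror the acquisition settings the analysis
#' pipeline is designed for: 20 Hz TIRF movies of sparse single molecules.
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across calls.
#' @param frame_rate acquisition rate in frames per second (default 20).
#' @param pixel_size pixel pitch in nm (default 160, a typical 100x
#'   EMCCD configuration; only metadata for downstream tables).
#' @param image_shape integer vector `c(rows, cols)`, each >= 16.
#' @param gaussian_sd additive Gaussian noise s.d. in intensity units.
#' @param poisson_scaling if positive, photon shot noise is simulated by
#'   scaling intensities to counts, Poisson sampling, and rescaling;
#'   0 (default) disables shot noise.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, frame_rate = 20, pixel_size = 160,
                       image_shape = c(64L, 64L),
                       gaussian_sd = 1, poisson_scaling = 0) {
  assert_that(is.numeric(seed) && length(seed) == 1, "seed must be a single integer")
  assert_that(frame_rate > 0, "frame_rate must be > 0")
  assert_that(length(image_shape) == 2 && all(image_shape >= 16),
              "image_shape must be two dimensions, each >= 16 px")
  assert_that(gaussian_sd >= 0 && poisson_scaling >= 0,
              "noise parameters must be non-negative")
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 noise_model = list(gaussian_sd = gaussian_sd,
                                    poisson_scaling = poisson_scaling)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed=%d, %g fps, %g nm/px, %dx%d px, noise sd=%g\n",
              x$seed, x$frame_rate, x$pixel_size, x$image_shape[1],
              x$image_shape[2], x$noise_model$gaussian_sd))
  invisible(x)
}

new_ground_truth <- function(...) {
  gt <- list(...)
  structure(gt, class = "ground_truth")
}

#' Simulate an equilibrium binding isotherm
#'
#' Generates equilibrium SPR responses from the 1:1 Langmuir relation
#' \eqn{R_{eq} = R_{max} C / (K_d + C)} with additive Gaussian noise.
#' The default concentration grid is the six-injection series used for
#' SH2:phosphopeptide affinity measurements (20-1000 nM).
#'
#' @param kd dissociation constant, same units as `concentrations` (nM).
#' @param r_max saturation response in RU.
#' @param concentrations analyte concentrations in nM; >= 4 strictly
#'   positive values.
#' @param noise_sd additive response noise s.d. in RU; 0 gives the exact
#'   Langmuir curve.
#' @param seed integer seed.
#' @param analyte_id,ligand_id labels carried into the isotherm.
#' @return a list with `isotherm` (class `isotherm`, see [isotherm()]) and
#'   `ground_truth` recording the generating parameters.
#' @examples
#' gi <- gen_isotherm(kd = 100, r_max = 100, noise_sd = 0)
#' gi$isotherm
#' @export
gen_isotherm <- function(kd, r_max,
                         concentrations = c(20, 50, 100, 200, 500, 1000),
                         noise_sd = 0, seed = 1L,
                         analyte_id = "analyte", ligand_id = "ligand") {
  assert_that(is.numeric(kd) && length(kd) == 1 && kd > 0, "kd must be a positive scalar")
  assert_that(r_max > 0, "r_max must be positive")
  assert_that(length(concentrations) >= 4 && all(concentrations > 0),
              "need >= 4 strictly positive concentrations")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  conc <- sort(concentrations)
  mu <- r_max * conc / (kd + conc)
  eps <- if (noise_sd > 0) {
    withr_seed(seed, stats::rnorm(length(conc), 0, noise_sd))
  } else rep(0, length(conc))
  iso <- isotherm(conc, mu + eps, analyte_id = analyte_id, ligand_id = ligand_id)
  list(isotherm = iso,
       ground_truth = new_ground_truth(kd = kd, r_max = r_max,
                                       noise_sd = noise_sd, seed = seed))
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a two-state single-molecule binding trajectory
#'
#' Draws a continuous-time two-state (unbound/bound) Markov chain with
#' pseudo-first-order on-rate `k_on_eff` and off-rate `k_off`, samples it at
#' the camera frame rate, and adds Gaussian emission noise. The state
#' reported for a frame is the state occupying the majority of that frame
#' interval, emulating camera integration rather than instantaneous
#' sampling (dwells shorter than half a frame can be missed; this
#' discretization bias is intentional and documented).
#'
#' @param k_on_eff pseudo-first-order binding rate, 1/s (k_on x [ligand]).
#' @param k_off unbinding rate, 1/s.
#' @param mu_unbound,mu_bound emission means (a.u.); `mu_bound` must exceed
#'   `mu_unbound`.
#' @param sigma emission noise s.d. (a.u.), applied to both states.
#' @param duration trajectory length in seconds (default 100 s = 2000
#'   frames at 20 Hz).
#' @param config a [sim_config()]; supplies frame rate and seed.
#' @param bleach_rate if > 0, the bound fluorophore photobleaches with this
#'   exponential rate (1/s of *bound* time); after bleaching the trace
#'   stays at the unbound level. Default 0 (no bleaching).
#' @param start_state optionally force the initial state ("stationary",
#'   "unbound", "bound").
#' @return a list with `trajectory` (class `trajectory`: intensities,
#'   frame_interval, molecule id), `states` (true per-frame state, 1 =
#'   unbound, 2 = bound) and `ground_truth`.
#' @export
gen_trajectory <- function(k_on_eff, k_off, mu_unbound = 0, mu_bound = 100,
                           sigma = 10, duration = 100,
                           config = sim_config(),
                           bleach_rate = 0,
                           start_state = c("stationary", "unbound", "bound")) {
  start_state <- match.arg(start_state)
  assert_that(k_on_eff >= 0 && k_off >= 0, "rates must be non-negative")
  assert_that(mu_bound > mu_unbound, "mu_bound must exceed mu_unbound")
  dt <- 1 / config$frame_rate
  n_frames <- round(duration / dt)
  assert_that(n_frames >= 10, "duration x frame_rate must be >= 10 frames")

  sim <- withr_seed(config$seed, {
    s0 <- switch(start_state,
                 stationary = if (k_on_eff + k_off == 0) 1L else
                   if (stats::runif(1) < k_on_eff / (k_on_eff + k_off)) 2L else 1L,
                 unbound = 1L, bound = 2L)
    states <- sample_ctmc_majority(s0, k_on_eff, k_off, n_frames, dt)
    bleach_t <- if (bleach_rate > 0) stats::rexp(1, bleach_rate) else Inf
    noise <- if (sigma > 0) stats::rnorm(n_frames, 0, sigma) else numeric(n_frames)
    list(states = states, bleach_t = bleach_t, noise = noise)
  })
  states <- sim$states
  if (is.finite(sim$bleach_t)) {
    # bleach clock runs only while bound; find frame where cumulative bound
    # time exceeds the bleach lifetime and darken from there on
    bound_time <- cumsum((states == 2L) * dt)
    dead <- which(bound_time >= sim$bleach_t)
    if (length(dead)) states[dead[1]:length(states)] <- 1L
  }
  mu <- c(mu_unbound, mu_bound)[states]
  traj <- trajectory(mu + sim$noise, frame_interval = dt, molecule_id = "sim")
  list(trajectory = traj, states = states,
       ground_truth = new_ground_truth(
         k_on_eff = k_on_eff, k_off = k_off, mu_unbound = mu_unbound,
         mu_bound = mu_bound, sigma = sigma, bleach_rate = bleach_rate,
         seed = config$seed))
}

# exact continuous-time simulation of the two-state chain; per-frame label is
# the majority-occupancy state within [t, t+dt)
sample_ctmc_majority <- function(s0, k_on, k_off, n_frames, dt) {
  t_end <- n_frames * dt
  times <- numeric(0)   # switch times
  state0 <- s0
  t <- 0
  s <- s0
  repeat {
    rate <- if (s == 1L) k_on else k_off
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= t_end) break
    times <- c(times, t)
    s <- 3L - s
  }
  # occupancy of state 2 within each frame
  edges <- c(0, times, t_end)
  seg_state <- rep(c(state0, 3L - state0), length.out = length(edges) - 1)
  frame_occ2 <- numeric(n_frames)
  for (i in seq_along(seg_state)) {
    if (seg_state[i] != 2L) next
    a <- edges[i]; b <- edges[i + 1]
    f0 <- floor(a / dt); f1 <- ceiling(b / dt) - 1
    for (f in f0:f1) {
      lo <- max(a, f * dt); hi <- min(b, (f + 1) * dt)
      if (hi > lo) frame_occ2[f + 1] <- frame_occ2[f + 1] + (hi - lo)
    }
  }
  ifelse(frame_occ2 > dt / 2, 2L, 1L)
}

# render 2-D Gaussian spots onto a rows x cols canvas (vectorized)
render_spots <- function(rows, cols, x, y, amplitude, psf_sigma) {
  img <- matrix(0, rows, cols)
  if (!length(x)) return(img)
  win <- ceiling(4 * psf_sigma)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    c0 <- max(0, floor(cx) - win); c1 <- min(cols - 1, ceiling(cx) + win)
    r0 <- max(0, floor(cy) - win); r1 <- min(rows - 1, ceiling(cy) + win)
    if (c1 < c0 || r1 < r0) next
    xs <- c0:c1; ys <- r0:r1
    gx <- exp(-(xs - cx)^2 / (2 * psf_sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * psf_sigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amplitude[i] * outer(gy, gx)
  }
  img
}

add_camera_noise <- function(img, noise_model) {
  if (noise_model$poisson_scaling > 0) {
    counts <- stats::rpois(length(img), pmax(img, 0) * noise_model$poisson_scaling)
    img <- matrix(counts / noise_model$poisson_scaling, nrow(img), ncol(img))
  }
  if (noise_model$gaussian_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_model$gaussian_sd),
                        nrow(img), ncol(img))
  img
}

#' Simulate a two-channel single-molecule movie
#'
#' Emulates the single-molecule TIRF assay: immobile receptors sparsely
#' attached to a coverslip imaged in one channel, and a ligand channel in
#' which each receptor position lights up only while a ligand molecule is
#' bound (per-receptor two-state trajectories). Spots are diffraction
#' limited 2-D Gaussians; placements are rejection-sampled so that the
#' minimum pairwise distance exceeds `4 * psf_sigma`.
#'
#' @param n_receptors number of receptor molecules (may be 0).
#' @param k_on_eff,k_off binding kinetics per receptor (1/s).
#' @param n_frames number of frames (default 2000).
#' @param amplitude peak spot amplitude above background (a.u.).
#' @param psf_sigma PSF Gaussian sigma in pixels.
#' @param config a [sim_config()]; geometry, frame rate, noise, seed.
#' @param receptor_bleach_rate optional single-step photobleaching rate of
#'   receptor fluorophores (1/s); 0 disables.
#' @param max_attempts rejection-sampling budget for spot placement.
#' @return a list with `receptor` and `ligand` (rows x cols x n_frames
#'   arrays), `ground_truth` (positions, per-receptor state matrices,
#'   kinetics), and `config`.
#' @export
gen_two_channel_movie <- function(n_receptors, k_on_eff = 0.2, k_off = 0.5,
                                  n_frames = 2000, amplitude = 100,
                                  psf_sigma = 1.3, config = sim_config(),
                                  receptor_bleach_rate = 0,
                                  max_attempts = 5000) {
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  dt <- 1 / config$frame_rate
  withr_seed(config$seed, {
    margin <- 4 * psf_sigma
    xs <- numeric(0); ys <- numeric(0); attempts <- 0
    while (length(xs) < n_receptors) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop_invalid("spot density infeasible: could not place ",
                     n_receptors, " receptors with min spacing ", 4 * psf_sigma)
      px <- stats::runif(1, margin, cols - 1 - margin)
      py <- stats::runif(1, margin, rows - 1 - margin)
      if (!length(xs) || min((xs - px)^2 + (ys - py)^2) > (4 * psf_sigma)^2) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    # per-receptor bound/unbound state over time
    states <- matrix(1L, n_receptors, max(n_frames, 1))
    if (n_receptors > 0) {
      for (i in seq_len(n_receptors)) {
        s0 <- if (k_on_eff + k_off == 0) 1L else
          if (stats::runif(1) < k_on_eff / (k_on_eff + k_off)) 2L else 1L
        states[i, ] <- sample_ctmc_majority(s0, k_on_eff, k_off, n_frames, dt)
      }
    }
    # receptor channel: constant spots, optional one-step bleach
    bleach_frame <- rep(Inf, n_receptors)
    if (receptor_bleach_rate > 0 && n_receptors > 0)
      bleach_frame <- ceiling(stats::rexp(n_receptors, receptor_bleach_rate) / dt)
    receptor <- array(0, c(rows, cols, n_frames))
    ligand <- array(0, c(rows, cols, n_frames))
    for (f in seq_len(n_frames)) {
      alive <- which(bleach_frame >= f)
      receptor[, , f] <- add_camera_noise(
        render_spots(rows, cols, xs[alive], ys[alive],
                     rep(amplitude, length(alive)), psf_sigma),
        config$noise_model)
      bound <- if (n_receptors > 0) which(states[, f] == 2L) else integer(0)
      ligand[, , f] <- add_camera_noise(
        render_spots(rows, cols, xs[bound], ys[bound],
                     rep(amplitude, length(bound)), psf_sigma),
        config$noise_model)
    }
    list(receptor = receptor, ligand = ligand,
         ground_truth = new_ground_truth(
           x = xs, y = ys, states = states, k_on_eff = k_on_eff,
           k_off = k_off, amplitude = amplitude, psf_sigma = psf_sigma,
           bleach_frame = bleach_frame, seed = config$seed),
         config = config)
  })
}

#' Simulate a two-channel microcluster image pair
#'
#' Emulates a TIRF image of a bilayer-attached cell: the receptor channel
#' is a diffuse cell footprint with bright Gaussian microclusters, and the
#' effector channel carries a background plus an `enrichment`-scaled copy of
#' the cluster signal, modelling effector recruitment to receptor
#' microclusters.
#'
#' @param n_clusters number of microclusters.
#' @param enrichment effector/receptor amplitude ratio at clusters (>= 0).
#' @param footprint_level diffuse receptor intensity inside the cell
#'   footprint (a.u.).
#' @param effector_background diffuse effector intensity inside the
#'   footprint (a.u.).
#' @param cluster_amplitude receptor cluster peak amplitude above the
#'   footprint (a.u.).
#' @param cluster_sigma cluster Gaussian sigma in pixels.
#' @param edge_margin minimum distance of cluster centers from the
#'   footprint rim, px; keeps clusters clear of the zone where rolling-ball
#'   background estimates degrade (default `4 * cluster_sigma + 12`).
#' @param config a [sim_config()].
#' @return list with `receptor`, `effector` (matrices), `footprint`
#'   (logical mask) and `ground_truth`.
#' @export
gen_cluster_image <- function(n_clusters = 8, enrichment = 1.5,
                              footprint_level = 20, effector_background = 10,
                              cluster_amplitude = 150, cluster_sigma = 2,
                              edge_margin = 4 * cluster_sigma + 12,
                              config = sim_config()) {
  assert_that(enrichment >= 0, "enrichment must be >= 0")
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  withr_seed(config$seed, {
    # circular cell footprint centred in the field
    cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
    rad <- 0.42 * min(rows, cols)
    d2 <- outer((0:(rows - 1) - cy)^2, (0:(cols - 1) - cx)^2, `+`)
    footprint <- d2 <= rad^2
    r_inner <- max(rad - edge_margin, 2)
    # rejection-sample centers so blobs stay resolvable as separate clusters
    min_spacing <- 7 * cluster_sigma
    xs <- numeric(0); ys <- numeric(0); attempts <- 0
    while (length(xs) < n_clusters) {
      attempts <- attempts + 1
      if (attempts > 20000)
        stop_invalid("cluster density infeasible: could not place ",
                     n_clusters, " clusters with spacing ", min_spacing)
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- r_inner * sqrt(stats::runif(1))
      px <- cx + rr * cos(ang); py <- cy + rr * sin(ang)
      if (!length(xs) || min((xs - px)^2 + (ys - py)^2) > min_spacing^2) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    blobs <- render_spots(rows, cols, xs, ys,
                          rep(cluster_amplitude, n_clusters), cluster_sigma)
    receptor <- footprint * footprint_level + blobs
    effector <- footprint * effector_background + enrichment * blobs
    receptor <- add_camera_noise(receptor, config$noise_model)
    effector <- add_camera_noise(effector, config$noise_model)
    list(receptor = receptor, effector = effector, footprint = footprint,
         ground_truth = new_ground_truth(
           x = xs, y = ys, enrichment = enrichment,
           cluster_amplitude = cluster_amplitude,
           cluster_sigma = cluster_sigma, footprint_level = footprint_level,
           effector_background = effector_background, seed = config$seed))
  })
}
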