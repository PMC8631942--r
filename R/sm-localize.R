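# ---- image primitives -----------------------------------------------------

# separable Gaussian blur with replicate padding, via banded kernel matrices
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {  # blur along rows (dim 1)
    n <- nrow(m)
    idx <- outer(seq_len(n), -r:r, `+`)
    idx[idx < 1] <- 1; idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Write / read an image stack as plain text
#'
#' Serialization for simulated movies: a one-line header
#' `rows cols frames` followed by frames in row-major order, whitespace
#' delimited. Chosen over TIFF so that stacks remain diffable text.
#'
#' @param stack rows x cols (x frames) numeric array.
#' @param path file path.
#' @export
write_image_stack <- function(stack, path) {
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1)
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d[1], d[2], d[3]), con)
  for (f in seq_len(d[3]))
    write(t(stack[, , f]), file = con, ncolumns = d[2])
  invisible(path)
}

#' @rdname write_image_stack
#' @return `read_image_stack` returns a rows x cols x frames array.
#' @export
read_image_stack <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  d <- scan(con, integer(), n = 3, quiet = TRUE)
  vals <- scan(con, double(), quiet = TRUE)
  arr <- array(0, d)
  per <- d[1] * d[2]
  for (f in seq_len(d[3]))
    arr[, , f] <- matrix(vals[((f - 1) * per + 1):(f * per)], d[1], d[2],
                         byrow = TRUE)
  arr
}

# ---- spot detection -------------------------------------------------------

#' Detect diffraction-limited spots in one frame
#'
#' Single-molecule spot detector: a difference-of-Gaussians band-pass
#' (sigma, 1.6 sigma), local maxima above `threshold_sigmas` times the
#' robust noise of the filtered image, then sub-pixel refinement by
#' least-squares fitting of a 2-D Gaussian plus offset in a window around
#' each maximum. Coordinates are 0-based with the origin at the center of
#' the top-left pixel; `x` runs along columns, `y` along rows. The
#' procedure is deterministic.
#'
#' @param frame 2-D numeric matrix.
#' @param threshold_sigmas detection threshold in robust-noise units
#'   (default 5).
#' @param psf_sigma_guess expected PSF sigma in pixels (default 1.3).
#' @param frame_index,channel metadata copied into the result.
#' @return a `spot_table` data.frame: `frame`, `channel`, `x`, `y`,
#'   `amplitude`, `sigma`. Zero rows if nothing is found (a constant
#'   image warns).
#' @export
detect_spots <- function(frame, threshold_sigmas = 5, psf_sigma_guess = 1.3,
                         frame_index = 1L, channel = 1L) {
  assert_that(is.matrix(frame), "frame must be a 2-D matrix")
  assert_that(threshold_sigmas > 0, "threshold_sigmas must be positive")
  empty <- data.frame(frame = integer(0), channel = integer(0),
                      x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0))
  if (stats::sd(frame) == 0) {
    warning("constant image: no spots detectable")
    return(structure(empty, class = c("spot_table", "data.frame")))
  }
  dog <- gaussian_blur(frame, psf_sigma_guess) -
    gaussian_blur(frame, 1.6 * psf_sigma_guess)
  noise <- robust_sigma(as.vector(dog))
  thr <- threshold_sigmas * max(noise, .Machine$double.eps)
  nr <- nrow(frame); nc <- ncol(frame)
  # strict local maxima over the 3x3 neighborhood, excluding a 1-px border
  inner <- dog[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & inner >= dog[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(structure(empty, class = c("spot_table", "data.frame")))
  rows <- idx[, 1] + 1L  # back to full-image indices
  cols <- idx[, 2] + 1L

  win <- max(2L, ceiling(3 * psf_sigma_guess))
  fits <- lapply(seq_along(rows), function(i) {
    r0 <- max(1L, rows[i] - win); r1 <- min(nr, rows[i] + win)
    c0 <- max(1L, cols[i] - win); c1 <- min(nc, cols[i] + win)
    patch <- frame[r0:r1, c0:c1]
    ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
    grid_y <- matrix(ys, length(ys), length(xs))
    grid_x <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    bg0 <- stats::median(patch)
    p0 <- c(amp = max(patch) - bg0, x = cols[i] - 1, y = rows[i] - 1,
            s = psf_sigma_guess, bg = bg0)
    obj <- function(p) {
      mdl <- p[5] + p[1] * exp(-((grid_x - p[2])^2 + (grid_y - p[3])^2) /
                                 (2 * p[4]^2))
      sum((patch - mdl)^2)
    }
    op <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B",
                                lower = c(0, min(xs), min(ys), 0.3, -Inf),
                                upper = c(Inf, max(xs), max(ys), 4 * psf_sigma_guess, Inf)),
                   error = function(e) NULL)
    if (is.null(op)) return(NULL)
    data.frame(frame = frame_index, channel = channel,
               x = op$par[2], y = op$par[3],
               amplitude = op$par[1], sigma = op$par[4])
  })
  out <- do.call(rbind, fits[!vapply(fits, is.null, TRUE)])
  if (is.null(out)) out <- empty
  # merge detections closer than one PSF sigma (keep the brighter)
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$amplitude)
    for (i in seq_along(ord)) {
      if (!keep[ord[i]]) next
      d2 <- (out$x - out$x[ord[i]])^2 + (out$y - out$y[ord[i]])^2
      close_by <- which(d2 < psf_sigma_guess^2 & seq_len(nrow(out)) != ord[i])
      keep[close_by] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("spot_table", "data.frame"))
}

#' Detect spots across a stack
#'
#' Applies [detect_spots()] to each frame of a movie and row-binds the
#' results, sorted by (frame, channel).
#'
#' @param stack rows x cols x frames array.
#' @param frame_rate frames/s, stored as metadata.
#' @inheritParams detect_spots
#' @return a `spot_table` with attribute `frame_rate`.
#' @export
detect_spots_stack <- function(stack, threshold_sigmas = 5,
                               psf_sigma_guess = 1.3, channel = 1L,
                               frame_rate = 20) {
  frames <- lapply(seq_len(dim(stack)[3]), function(f)
    suppressWarnings(detect_spots(stack[, , f], threshold_sigmas,
                                  psf_sigma_guess, frame_index = f,
                                  channel = channel)))
  out <- do.call(rbind, frames)
  out <- out[order(out$frame, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_rate") <- frame_rate
  structure(out, class = c("spot_table", "data.frame"))
}

# ---- intensity histogram --------------------------------------------------

#' Fit a 1- or 2-component Gaussian mixture to spot intensities
#'
#' Maximum-likelihood fits of one- and two-component Gaussian mixtures
#' (EM with a deterministic quantile initialization) compared by BIC.
#' Used to check whether a spot-intensity histogram is consistent with a
#' single fluorophore population.
#'
#' @param intensities >= 50 numeric values.
#' @param max_iter,tol EM controls.
#' @return list: `n_components` (1 or 2), `means`, `sds`, `weights`,
#'   `loglik`, `bic` (named vector for both model orders).
#' @export
intensity_histogram_fit <- function(intensities, max_iter = 500, tol = 1e-8) {
  y <- as.numeric(intensities)
  assert_that(length(y) >= 50, "need >= 50 intensity values")
  if (stats::sd(y) == 0) stop_invalid("degenerate (zero-variance) intensity data")
  n <- length(y)
  # 1-component MLE
  m1 <- mean(y); s1 <- sqrt(mean((y - m1)^2))
  ll1 <- sum(stats::dnorm(y, m1, s1, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  # 2-component EM, initialized from the 2-means split
  km <- two_means_init(y)
  mu <- sort(km$centers)
  sd2 <- rep(max(stats::sd(y) / 2, 1e-8), 2)
  w <- c(mean(km$labels == which.min(km$centers)),
         mean(km$labels == which.max(km$centers)))
  w <- pmin(pmax(w, 0.05), 0.95); w <- w / sum(w)
  ll2 <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(y, mu[1], sd2[1])
    d2 <- w[2] * stats::dnorm(y, mu[2], sd2[2])
    tot <- pmax(d1 + d2, 1e-300)
    r2 <- d2 / tot
    ll_new <- sum(log(tot))
    if (is.finite(ll2) && abs(ll_new - ll2) < tol * (abs(ll2) + 1e-12)) {
      ll2 <- ll_new; break
    }
    ll2 <- ll_new
    w <- c(mean(1 - r2), mean(r2))
    mu <- c(sum((1 - r2) * y) / sum(1 - r2), sum(r2 * y) / sum(r2))
    sd2 <- sqrt(c(sum((1 - r2) * (y - mu[1])^2) / sum(1 - r2),
                  sum(r2 * (y - mu[2])^2) / sum(r2)))
    sd2 <- pmax(sd2, 1e-8 * stats::sd(y))
  }
  bic2 <- -2 * ll2 + 5 * log(n)
  if (bic2 < bic1) {
    list(n_components = 2L, means = mu, sds = sd2, weights = w,
         loglik = ll2, bic = c(one = bic1, two = bic2))
  } else {
    list(n_components = 1L, means = m1, sds = s1, weights = 1,
         loglik = ll1, bic = c(one = bic1, two = bic2))
  }
}

# ---- photobleaching step counting -----------------------------------------

# greedy binary segmentation on segment means; returns changepoint indices
# (last index of each left segment). penalty per changepoint (BIC-style).
binary_segment <- function(y, penalty) {
  best_split <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 4) return(NULL)
    seg <- y[lo:hi]
    cs <- cumsum(seg); cs2 <- cumsum(seg^2)
    tot <- cs2[n] - cs[n]^2 / n
    ks <- 2:(n - 2)
    left <- cs2[ks] - cs[ks]^2 / ks
    right <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
    gain <- tot - (left + right)
    k <- ks[which.max(gain)]
    list(gain = max(gain), at = lo + k - 1)
  }
  cps <- integer(0)
  queue <- list(c(1L, length(y)))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    sp <- best_split(seg[1], seg[2])
    if (is.null(sp) || sp$gain < penalty) next
    cps <- c(cps, sp$at)
    queue <- c(queue, list(c(seg[1], sp$at)), list(c(sp$at + 1L, seg[2])))
  }
  sort(cps)
}

#' Count photobleaching steps in an intensity trace
#'
#' Penalized least-squares change-point segmentation (greedy binary
#' segmentation with a BIC-style penalty of `2 sigma^2 log(n)` per
#' change-point, noise estimated robustly from first differences) followed
#' by counting downward jumps between segment means. A single fluorophore
#' bleaches in one step; the step count therefore reports the oligomeric
#' state of a spot.
#'
#' @param traj a [trajectory()] or numeric vector with >= 20 frames.
#' @param min_step smallest intensity drop that counts as a step, in
#'   robust-noise units (default 3).
#' @return a `bleach_profile` list: `step_count` (downward steps),
#'   `step_frames`, `step_sizes` (negative), `segment_means`.
#' @export
count_bleach_steps <- function(traj, min_step = 3) {
  y <- if (inherits(traj, "trajectory")) traj$intensities else as.numeric(traj)
  assert_that(length(y) >= 20, "need >= 20 frames")
  sig <- max(diff_sigma(y), 1e-12)
  penalty <- 2 * sig^2 * log(length(y))
  cps <- binary_segment(y, penalty)
  bounds <- c(0L, cps, length(y))
  means <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(y[(bounds[i] + 1):bounds[i + 1]]), 0)
  jumps <- diff(means)
  down <- which(jumps < -min_step * sig)
  structure(list(step_count = length(down),
                 step_frames = cps[down],
                 step_sizes = jumps[down],
                 segment_means = means,
                 changepoints = cps),
            class = "bleach_profile")
}

# ---- colocalization -------------------------------------------------------

#' Two-channel colocalization rate
#'
#' Fraction of receptor spots with at least one ligand-channel detection
#' within `radius` pixels during the observation window. With
#' `window_mode = "any"` (default) the window slides over the whole
#' acquisition, so any ligand detection at any frame colocalizes its
#' receptor; with `"first"` only ligand detections within the first
#' `window` seconds count.
#'
#' @param receptor_spots `spot_table` of receptor positions (typically the
#'   first frame of the static channel).
#' @param ligand_spots `spot_table` of ligand detections across frames.
#' @param radius matching radius in pixels (default 2).
#' @param window window length in seconds (default 0.5).
#' @param window_mode `"any"` or `"first"`.
#' @param frame_rate frames/s used to convert `window` to frames; taken
#'   from the ligand table's `frame_rate` attribute when absent.
#' @return fraction in [0, 1], with attribute `n_receptors`.
#' @export
colocalization_rate <- function(receptor_spots, ligand_spots, radius = 2,
                                window = 0.5,
                                window_mode = c("any", "first"),
                                frame_rate = NULL) {
  window_mode <- match.arg(window_mode)
  assert_that(radius > 0, "radius must be positive")
  if (!nrow(receptor_spots)) stop_invalid("empty receptor table: rate undefined")
  frame_rate <- frame_rate %||% attr(ligand_spots, "frame_rate") %||% 20
  lig <- ligand_spots
  if (window_mode == "first" && nrow(lig)) {
    n_win <- max(1L, round(window * frame_rate))
    lig <- lig[lig$frame <= min(lig$frame, na.rm = TRUE) + n_win - 1L, ,
               drop = FALSE]
  }
  hit <- vapply(seq_len(nrow(receptor_spots)), function(i) {
    if (!nrow(lig)) return(FALSE)
    any((lig$x - receptor_spots$x[i])^2 +
          (lig$y - receptor_spots$y[i])^2 <= radius^2)
  }, TRUE)
  structure(mean(hit), n_receptors = nrow(receptor_spots))
}

#' Write a spot table (CSV)
#'
#' Columns `frame,channel,x_px,y_px,amplitude,sigma_px`.
#'
#' @param spots a `spot_table`.
#' @param path file path.
#' @export
write_spot_table <- function(spots, path) {
  out <- data.frame(frame = spots$frame, channel = spots$channel,
                    x_px = spots$x, y_px = spots$y,
                    amplitude = spots$amplitude, sigma_px = spots$sigma)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(data.frame(frame = df$frame, channel = df$channel,
                       x = df$x_px, y = df$y_px,
                       amplitude = df$amplitude, sigma = df$sigma_px),
            class = c("spot_table", "data.frame"))
}
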