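# ---- morphology -----------------------------------------------------------

disk_offsets <- function(radius) {
  r <- floor(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs[offs$dr^2 + offs$dc^2 <= radius^2, , drop = FALSE]
}

# grayscale erosion/dilation with an arbitrary offset set, replicate padding
morph_filter <- function(img, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img)
  acc <- NULL
  combine <- if (op == "erode") pmin else pmax
  row_idx <- seq_len(nr); col_idx <- seq_len(nc)
  for (i in seq_len(nrow(offsets))) {
    ri <- row_idx + offsets$dr[i]; ri[ri < 1] <- 1; ri[ri > nr] <- nr
    ci <- col_idx + offsets$dc[i]; ci[ci < 1] <- 1; ci[ci > nc] <- nc
    shifted <- img[ri, ci, drop = FALSE]
    acc <- if (is.null(acc)) shifted else combine(acc, shifted)
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of an image as its grayscale
#' morphological opening with a flat disk structuring element of the given
#' radius (erosion followed by dilation) and subtracts it. Structures
#' smaller than the ball — microclusters, single-molecule spots — survive;
#' broad illumination and cytosolic signal are removed. The operation is
#' idempotent up to numerical tolerance and its output is non-negative.
#'
#' @param image 2-D numeric matrix.
#' @param ball_radius structuring-element radius in pixels (default 50,
#'   the common default of interactive background subtraction tools).
#' @return matrix of the same shape, `>= 0`.
#' @export
subtract_background <- function(image, ball_radius = 50) {
  assert_that(is.matrix(image), "image must be a matrix")
  assert_that(ball_radius >= 1, "ball_radius must be >= 1")
  assert_that(2 * ball_radius + 1 <= min(dim(image)),
              "ball_radius too large for the image")
  offs <- disk_offsets(ball_radius)
  bg <- morph_filter(morph_filter(image, offs, "erode"), offs, "dilate")
  pmax(image - bg, 0)
}

# 4-connected component labelling (iterative flood fill)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    while (length(stack)) {
      px <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (labels[px] != 0L) next
      labels[px] <- current
      r <- ((px - 1L) %% nr) + 1L
      c <- ((px - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1) px - 1L, if (r < nr) px + 1L,
                   if (c > 1) px - nr, if (c < nc) px + nr)) {
        if (mask[nb] && labels[nb] == 0L) stack <- c(stack, nb)
      }
    }
  }
  labels
}

#' Build a microcluster mask from a receptor image
#'
#' Background-subtracts the receptor channel, thresholds at
#' `threshold_sigmas` times the robust noise (1.4826 x MAD) of the
#' subtracted image, and keeps 4-connected components of at least
#' `min_area` pixels.
#'
#' @param receptor_image 2-D matrix (raw receptor channel).
#' @param ball_radius background-subtraction radius (px).
#' @param threshold_sigmas threshold in robust-noise units (default 3).
#' @param min_area minimum cluster area in pixels (default 4).
#' @param footprint optional logical cell-footprint mask; clusters outside
#'   it are discarded. The footprint is first eroded by `ball_radius`
#'   because the rolling-ball background estimate is unreliable within one
#'   ball radius of the footprint rim (the ball samples dark pixels beyond
#'   the cell there, leaving a spurious bright ring).
#' @return a `cluster_mask` list: `mask` (logical matrix), `labels`
#'   (integer matrix), `n_clusters`, and the background-subtracted image.
#' @export
make_cluster_mask <- function(receptor_image, ball_radius = 50,
                              threshold_sigmas = 3, min_area = 4,
                              footprint = NULL) {
  sub <- subtract_background(receptor_image, ball_radius)
  fp <- NULL
  if (!is.null(footprint))
    fp <- morph_filter(footprint * 1, disk_offsets(ball_radius), "erode") > 0.5
  # noise scale from within the footprint when one is given: the clamped
  # zeros outside the cell would otherwise collapse the MAD to ~0
  noise <- if (!is.null(fp) && any(fp)) robust_sigma(sub[fp]) else
    robust_sigma(as.vector(sub))
  mask <- sub > threshold_sigmas * max(noise, .Machine$double.eps)
  if (!is.null(fp)) mask <- mask & fp
  labels <- label_components(mask)
  if (max(labels) > 0) {
    sizes <- tabulate(labels)
    small <- which(sizes < min_area)
    if (length(small)) {
      mask[labels %in% small] <- FALSE
      labels <- label_components(mask)
    }
  }
  structure(list(mask = mask, labels = labels, n_clusters = max(labels),
                 subtracted = sub),
            class = "cluster_mask")
}

#' Effector enrichment at receptor microclusters
#'
#' The per-cell enrichment statistic: the ratio of summed
#' background-subtracted effector fluorescence to summed
#' background-subtracted receptor fluorescence over the microcluster mask
#' (effector FI normalized to receptor FI). Summed rather than mean
#' intensities are used, so the cell-level ratio is the intensity-weighted
#' mean of per-cluster ratios; `statistic = "mean"` switches to the
#' unweighted mean-over-mask convention.
#'
#' @param receptor_image,effector_image 2-D matrices (raw channels).
#' @param mask a `cluster_mask` from [make_cluster_mask()].
#' @param ball_radius background-subtraction radius applied to both
#'   channels (px).
#' @param statistic `"sum"` (default) or `"mean"`.
#' @return an `enrichment_result` list: `ratio`, `n_clusters`,
#'   `per_cluster` data.frame (`cluster`, `area`, `ratio`).
#' @export
enrichment_ratio <- function(receptor_image, effector_image, mask,
                             ball_radius = 50, statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(mask, "cluster_mask"))
  assert_that(all(dim(receptor_image) == dim(effector_image)),
              "channel shapes differ")
  if (!any(mask$mask)) stop_invalid("empty cluster mask: ratio undefined")
  rec <- subtract_background(receptor_image, ball_radius)
  eff <- subtract_background(effector_image, ball_radius)
  agg <- if (statistic == "sum") sum else mean
  rec_tot <- agg(rec[mask$mask]); eff_tot <- agg(eff[mask$mask])
  if (rec_tot <= 0) stop_invalid("zero receptor signal in mask: ratio undefined")
  per <- do.call(rbind, lapply(seq_len(mask$n_clusters), function(k) {
    px <- mask$labels == k
    r <- agg(rec[px])
    data.frame(cluster = k, area = sum(px),
               ratio = if (r > 0) agg(eff[px]) / r else NA_real_)
  }))
  structure(list(ratio = eff_tot / rec_tot, n_clusters = mask$n_clusters,
                 per_cluster = per %||% data.frame()),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment ratio %.3f over %d cluster(s)\n", x$ratio, x$n_clusters))
  invisible(x)
}

#' Compare enrichment between conditions
#'
#' Descriptive statistics per condition plus pairwise Welch two-sample
#' t-tests on per-cell enrichment ratios.
#'
#' @param ratios named list: one numeric vector of per-cell ratios per
#'   condition (each n >= 2).
#' @return list with `summary` (condition, n, mean, sd) and `pairwise`
#'   (condition_a, condition_b, t, df, p_value, mean_diff).
#' @export
compare_groups <- function(ratios) {
  assert_that(is.list(ratios) && length(ratios) >= 1 && !is.null(names(ratios)),
              "ratios must be a named list of numeric vectors")
  lapply(ratios, function(v) assert_that(length(v) >= 2, "each group needs n >= 2"))
  summ <- data.frame(condition = names(ratios),
                     n = vapply(ratios, length, 0L),
                     mean = vapply(ratios, mean, 0),
                     sd = vapply(ratios, stats::sd, 0),
                     row.names = NULL)
  combs <- if (length(ratios) >= 2) utils::combn(names(ratios), 2) else
    matrix(character(0), 2, 0)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    tt <- stats::t.test(ratios[[a]], ratios[[b]])
    data.frame(condition_a = a, condition_b = b,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               mean_diff = mean(ratios[[a]]) - mean(ratios[[b]]))
  }))
  list(summary = summ,
       pairwise = pw %||% data.frame())
}
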