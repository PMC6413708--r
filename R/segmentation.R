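#' Pixel-wise dF sequence against the bleach fit
#'
#' The activation-map pipeline works on plain differences
#' `p_i[n] - f_i[n]` (counts), not fractions: pixels with no evoked signal
#' average to zero while responding pixels go negative during
#' depolarization (raw convention).
#'
#' @inheritParams compute_dff
#' @return A `dff_movie`-like `delta_f` stack (counts) with movie metadata.
#' @export
delta_f_sequence <- function(movie, bleach) {
  d <- dim(movie$data)
  if (!identical(dim(bleach$slope), d[1:2]))
    abort("bleach field and movie shapes differ.")
  f <- bleach_fitted(bleach, seq_len(d[3]))
  df <- movie$data - f
  df[array(bleach$flagged, dim = d)] <- NA_real_
  structure(list(data = df, frame_rate = movie$frame_rate,
                 pixel_size = movie$pixel_size, n_trials = movie$n_trials),
            class = c("delta_f", "dff_movie"))
}

#' Downsample and filter a dF sequence for mapping
#'
#' Temporal block-averaging to 50 Hz (improving per-frame SNR), followed by
#' mode-specific filtering: `"visualization"` applies a spatiotemporal
#' Gaussian with sigma of 1 time point and 1 pixel (20 ms / 1.04 um at the
#' default geometry) for maps meant for display and segmentation;
#' `"spread"` applies only a 3-point temporal median filter, leaving the
#' spatial structure untouched for autocorrelation analysis.
#'
#' @param seq A `delta_f` stack (from [delta_f_sequence()]).
#' @param mode `"visualization"` or `"spread"`.
#' @param target_rate Hz after downsampling; the input rate must be an
#'   integer multiple of it. Default 50.
#' @return A filtered `delta_f` stack at `target_rate`.
#' @export
preprocess_map_sequence <- function(seq, mode = c("visualization", "spread"),
                                    target_rate = 50) {
  mode <- match.arg(mode)
  rate <- seq$frame_rate
  if (rate < target_rate || abs(rate / target_rate - round(rate / target_rate)) > 1e-9)
    abort(sprintf("input rate (%g Hz) must be an integer multiple of %g Hz.",
                  rate, target_rate))
  fac <- as.integer(round(rate / target_rate))
  d <- dim(seq$data)
  nb <- d[3] %/% fac
  a <- seq$data[, , seq_len(nb * fac), drop = FALSE]
  dim(a) <- c(d[1] * d[2], fac, nb)
  down <- array(colMeans(aperm(a, c(2, 1, 3))), dim = c(d[1], d[2], nb))
  if (mode == "visualization") {
    sig <- 1
    for (n in seq_len(nb)) down[, , n] <- gauss_blur2d(down[, , n], sig)
    down <- gauss_blur_time(down, sig)
  } else {
    down <- median3_time(down)
  }
  structure(list(data = down, frame_rate = target_rate,
                 pixel_size = seq$pixel_size, n_trials = seq$n_trials),
            class = c("delta_f", "dff_movie"))
}

#' Stimulus-evoked activation map
#'
#' Sums the frames collected during stimulation periods into a single 2-D
#' response image. Under the raw convention, responding pixels are negative
#' (donor fluorescence decreases on depolarization) while noise-only pixels
#' average toward zero; the map reveals the active cell's morphology.
#'
#' @param seq A (filtered) `delta_f` stack.
#' @param stim_frames Integer frame indices falling inside stimulation
#'   periods (at the stack's rate).
#' @return An `activation_map`: matrix with `pixel_size`, sign `convention`
#'   ("raw") and the frame indices used.
#' @export
activation_map <- function(seq, stim_frames) {
  d <- dim(seq$data)
  stim_frames <- unique(as.integer(stim_frames))
  if (length(stim_frames) == 0) abort("`stim_frames` must be non-empty.")
  if (any(stim_frames < 1 | stim_frames > d[3]))
    abort("`stim_frames` out of range.")
  m <- apply(seq$data[, , stim_frames, drop = FALSE], c(1, 2), sum)
  structure(list(map = m, pixel_size = seq$pixel_size, convention = "raw",
                 stim_frames = stim_frames),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d x %d px (%.2f um/px, %s convention, %d frames summed)\n",
              nrow(x$map), ncol(x$map), x$pixel_size, x$convention,
              length(x$stim_frames)))
  invisible(x)
}

# sign-corrected (depolarization-positive) map values
map_positive <- function(map) {
  if (map$convention == "raw") -map$map else map$map
}

#' Yen's automatic threshold
#'
#' Maximum-correlation thresholding on a fixed 256-bin histogram of the
#' min-max scaled input; returns the threshold on the original scale.
#'
#' @param x Numeric vector or matrix (NA dropped).
#' @param n_bins Histogram bins (default 256).
#' @return Threshold value; foreground is `x > threshold`.
#' @export
yen_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) abort("constant input has no threshold.")
  u <- (v - rng[1]) / diff(rng)
  h <- tabulate(pmin(floor(u * n_bins) + 1L, n_bins), nbins = n_bins)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1_sq <- cumsum(p^2)
  P2_sq <- rev(cumsum(rev(p^2)))
  k <- seq_len(n_bins - 1L)
  crit <- -log(pmax(P1_sq[k] * P2_sq[k + 1L], 1e-30)) +
    2 * log(pmax(P1[k] * (1 - P1[k]), 1e-30))
  kstar <- which.max(crit)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  rng[1] + centers[kstar] * diff(rng)
}

#' Segment the somatic ROI from an activation map
#'
#' Sign-corrects the map so activity is positive, thresholds it with Yen's
#' automatic criterion, applies one round of binary closing then one of
#' binary dilation (3x3 box), and returns the largest 8-connected component
#' as the somatic ROI. Ties between equal-sized components are broken
#' toward the larger summed activation.
#'
#' A genuine activation is strictly one-sided: depolarization only ever
#' *reduces* donor fluorescence, so sign-corrected signal pixels are
#' strictly positive while noise is symmetric about zero. A map whose
#' positive extreme does not clearly exceed its negative extreme
#' (`max < 1.5 * |min|`) therefore contains no detectable cell and raises
#' an error rather than returning a noise mask.
#'
#' @param map An [activation_map()].
#' @return An `roi_mask`: logical matrix plus pixel count and centroid (um).
#' @export
segment_soma <- function(map) {
  pos <- map_positive(map)
  pos[!is.finite(pos)] <- 0
  if (max(pos) < 1.5 * max(0, -min(pos)))
    abort("no active cell detected: map extremes are noise-symmetric.")
  thr <- yen_threshold(pos)
  fg <- pos > thr
  if (!any(fg)) abort("no active cell detected: empty foreground after thresholding.")
  img <- EBImage::Image(fg * 1)
  brush <- EBImage::makeBrush(3, shape = "box")
  img <- EBImage::dilate(EBImage::closing(img, brush), brush)
  fg <- EBImage::imageData(img) > 0.5
  lab <- label_components(fg)
  if (max(lab) == 0) abort("no active cell detected: empty foreground after morphology.")
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    sums <- vapply(best, function(l) sum(pos[lab == l]), 0)
    best <- best[which.max(sums)]
  }
  mask <- lab == best
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx) * map$pixel_size
  structure(list(mask = mask, n_pixels = sum(mask),
                 centroid_um = unname(centroid), threshold = thr,
                 pixel_size = map$pixel_size),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px, centroid (%.1f, %.1f) um\n",
              x$n_pixels, x$centroid_um[1], x$centroid_um[2]))
  invisible(x)
}

#' ROI-mean fluorescence time course
#'
#' Unweighted mean over the mask pixels, frame by frame; NA (flagged)
#' pixels are excluded from the mean.
#'
#' @param dff A `dff_movie` (fractions) or `delta_f` stack (counts).
#' @param mask An `roi_mask` or logical matrix.
#' @return A [fluor_trace()] in the raw (negative-going) convention.
#' @export
roi_timecourse <- function(dff, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  d <- dim(dff$data)
  if (!identical(dim(m), d[1:2])) abort("mask and movie shapes differ.")
  if (!any(m)) abort("mask is empty.")
  mm <- matrix(dff$data, nrow = prod(d[1:2]), ncol = d[3])[as.logical(m), ,
                                                           drop = FALSE]
  vals <- colMeans(mm, na.rm = TRUE)
  if (all(!is.finite(vals)))
    abort("mask covers only flagged pixels.")
  unit <- if (inherits(dff, "delta_f")) "counts" else "fraction"
  fluor_trace(vals, rate = dff$frame_rate, convention = "raw", unit = unit,
              n_trials = dff$n_trials %||% 1L)
}
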