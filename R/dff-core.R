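#' Average repeated imaging trials
#'
#' Element-wise mean of same-shaped movies acquired under identical
#' conditions. Averaging k trials shrinks shot noise by ~ 1/sqrt(k);
#' evoked responses are analysed on averaged movies only.
#'
#' @param movies List of [gevi_movie()] objects with identical shapes,
#'   frame rates and offsets.
#' @return A [gevi_movie()] whose `n_trials` records the trial count.
#' @export
average_trials <- function(movies) {
  if (length(movies) < 1) abort("need at least one movie.")
  ref <- movies[[1]]
  for (i in seq_along(movies)) {
    m <- movies[[i]]
    if (!identical(dim(m$data), dim(ref$data)))
      abort(sprintf("trial %d: shape mismatch (%s vs %s)", i,
                    paste(dim(m$data), collapse = "x"),
                    paste(dim(ref$data), collapse = "x")))
    if (m$frame_rate != ref$frame_rate)
      abort(sprintf("trial %d: frame-rate mismatch", i))
  }
  acc <- Reduce(`+`, lapply(movies, `[[`, "data")) / length(movies)
  gevi_movie(acc, frame_rate = ref$frame_rate, pixel_size = ref$pixel_size,
             camera_offset = ref$camera_offset,
             n_trials = sum(vapply(movies, function(m) m$n_trials, 1L)))
}

#' Per-pixel linear bleach fit
#'
#' Fits an ordinary-least-squares line `f_i[n] = intercept + slope * n`
#' (n = frame number) to every pixel's time course to control for
#' photobleaching. The derived bleach-rate map is
#' `-slope / (intercept - camera_offset) * frame_rate * 100` in %/s,
#' i.e. the fractional loss per second of offset-corrected fluorescence
#' relative to its initial fitted value. Pixels whose fitted line does not
#' stay above the camera offset carry no usable fluorescence and are
#' flagged; they propagate as NA through downstream stages.
#'
#' @param movie A [gevi_movie()].
#' @param fit_frames Integer frame indices used for the fit; default all
#'   frames. Supply the non-stimulus frames to keep brief evoked transients
#'   from biasing the line. The fitted line is still evaluated at every
#'   frame.
#' @return A `bleach_field`: per-pixel `slope` (counts/frame), `intercept`
#'   (counts, at n = 0), `rate` (%/s, NA where flagged), logical `flagged`
#'   matrix, and the fit metadata.
#' @export
pixel_bleach_fit <- function(movie, fit_frames = NULL) {
  d <- dim(movie$data)
  if (is.null(fit_frames)) fit_frames <- seq_len(d[3])
  fit_frames <- sort(unique(as.integer(fit_frames)))
  if (length(fit_frames) < 10)
    abort("need at least 10 frames for the bleach fit.")
  if (any(fit_frames < 1 | fit_frames > d[3]))
    abort("`fit_frames` out of range.")
  x <- fit_frames
  y <- matrix(movie$data[, , x], nrow = prod(d[1:2]), ncol = length(x))
  xc <- x - mean(x)
  slope <- as.numeric(y %*% xc) / sum(xc^2)
  intercept <- rowMeans(y) - slope * mean(x)
  slope <- matrix(slope, d[1], d[2])
  intercept <- matrix(intercept, d[1], d[2])
  # fitted line must stay above the offset over the whole movie
  fit_lo <- pmin(intercept + slope, intercept + slope * d[3])
  flagged <- fit_lo <= movie$camera_offset
  rate <- -slope / (intercept - movie$camera_offset) * movie$frame_rate * 100
  rate[flagged] <- NA_real_
  structure(list(slope = slope, intercept = intercept, rate = rate,
                 flagged = flagged, frame_rate = movie$frame_rate,
                 camera_offset = movie$camera_offset,
                 fit_frames = fit_frames, n_frames = d[3]),
            class = "bleach_field")
}

#' @export
print.bleach_field <- function(x, ...) {
  cat(sprintf("<bleach_field> %d x %d px; median rate %.3g %%/s; %d flagged px\n",
              nrow(x$slope), ncol(x$slope),
              median(x$rate, na.rm = TRUE), sum(x$flagged)))
  invisible(x)
}

#' @export
tidy.bleach_field <- function(x, ...) {
  tibble(pixel = seq_along(x$slope),
         slope = as.numeric(x$slope),
         intercept = as.numeric(x$intercept),
         rate_pct_per_s = as.numeric(x$rate),
         flagged = as.logical(x$flagged))
}

#' @export
glance.bleach_field <- function(x, ...) {
  tibble(median_rate_pct_per_s = median(x$rate, na.rm = TRUE),
         p10_rate = quantile(x$rate, 0.1, na.rm = TRUE, names = FALSE),
         p90_rate = quantile(x$rate, 0.9, na.rm = TRUE, names = FALSE),
         n_flagged = sum(x$flagged), n_pixels = length(x$flagged))
}

bleach_fitted <- function(bleach, frames = seq_len(bleach$n_frames)) {
  # rows x cols x frames array of the fitted line evaluated per frame
  d <- dim(bleach$slope)
  outer_term <- outer(as.numeric(bleach$slope), frames)
  array(as.numeric(bleach$intercept) + outer_term, dim = c(d, length(frames)))
}

#' Pixel-wise dF/F0 against the bleach fit
#'
#' Computes, per pixel and frame,
#' `(p_i[n] - f_i[n]) / (f_i[n] - camera_offset)`, where `f_i` is the
#' per-pixel fitted bleach line: the fractional fluorescence change relative
#' to the offset-corrected, bleach-corrected baseline. Flagged pixels are NA.
#'
#' @param movie A [gevi_movie()].
#' @param bleach A [pixel_bleach_fit()] result from the same-shaped movie.
#' @param camera_offset Counts; defaults to the movie's recorded offset.
#' @return A `dff_movie`: rows x cols x frames array of fractions with the
#'   movie's metadata. Negative-going for depolarization (raw convention).
#' @export
compute_dff <- function(movie, bleach, camera_offset = movie$camera_offset) {
  d <- dim(movie$data)
  if (!identical(dim(bleach$slope), d[1:2]))
    abort("bleach field and movie shapes differ.")
  f <- bleach_fitted(bleach, seq_len(d[3]))
  unflagged_min <- min(f[!array(bleach$flagged, dim = d)])
  if (camera_offset >= unflagged_min)
    abort("camera offset >= minimum fitted fluorescence on unflagged pixels.")
  dff <- (movie$data - f) / (f - camera_offset)
  dff[array(bleach$flagged, dim = d)] <- NA_real_
  structure(list(data = dff, frame_rate = movie$frame_rate,
                 pixel_size = movie$pixel_size, n_trials = movie$n_trials),
            class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dff_movie> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' @export
dim.dff_movie <- function(x) dim(x$data)

#' Flatten a trace by a polynomial baseline fit
#'
#' Removes residual slow drift (bleaching remnants) from a trace by
#' dividing it by a least-squares polynomial fitted only to frames without
#' voltage signal, then re-expressing the result as deviation from 1. For
#' dF/F traces (baseline ~ 0) the division is applied to the relative
#' fluorescence `1 + trace` so the polynomial is fitted around 1.
#'
#' @param trace A [fluor_trace()].
#' @param signal_frames Integer indices of frames containing voltage signal;
#'   these are excluded from the polynomial fit but still flattened.
#' @param poly_order Polynomial order (default 3).
#' @return A flattened [fluor_trace()] (fraction; baseline ~ 0).
#' @export
flatten_trace <- function(trace, signal_frames = integer(), poly_order = 3) {
  n <- length(trace)
  keep <- setdiff(seq_len(n), signal_frames)
  if (length(keep) < 5 * (poly_order + 1))
    abort(sprintf("need >= %d non-signal frames for an order-%d fit (have %d).",
                  5 * (poly_order + 1), poly_order, length(keep)))
  v <- as.numeric(trace)
  rel <- if (attr(trace, "unit") == "fraction") 1 + v else v
  x <- seq_len(n)
  fit <- lm(y ~ poly(x, degree = poly_order, raw = TRUE),
            data = data.frame(y = rel[keep], x = x[keep]))
  base <- as.numeric(cbind(1, stats::poly(x, degree = poly_order,
                                          raw = TRUE)) %*% coef(fit))
  if (any(base <= 0))
    abort("polynomial baseline crosses zero; cannot flatten by division.")
  retrace(rel / base - 1, trace)
}
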