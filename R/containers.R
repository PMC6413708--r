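#' Movie container for camera-count stacks
#'
#' A `gevi_movie` wraps a rows x cols x frames numeric array of camera counts
#' together with the acquisition metadata every analysis stage needs: frame
#' rate (Hz), pixel size (um) and the camera's fixed digitizer offset
#' (counts). All voltimg stages operate on this container.
#'
#' @param data Numeric array, rows x cols x frames (>= 2 frames), counts >= 0.
#' @param frame_rate Acquisition rate in Hz (> 0).
#' @param pixel_size Pixel pitch at the sample, in um. Default 1.04 um
#'   (sCMOS at 4x4 binning).
#' @param camera_offset Dark offset added by the camera, in counts.
#'   Default 1600 (4x4 binning).
#' @param n_trials Number of trials averaged into this movie (metadata).
#'
#' @return An object of class `gevi_movie`: a list with elements `data`,
#'   `frame_rate`, `pixel_size`, `camera_offset`, `n_trials`.
#' @export
gevi_movie <- function(data, frame_rate, pixel_size = 1.04,
                       camera_offset = 1600, n_trials = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a rows x cols x frames array.")
  if (dim(data)[3] < 2L)
    abort("a movie needs at least 2 frames.")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    abort("`frame_rate` must be a positive number of Hz.")
  if (camera_offset < 0) abort("`camera_offset` must be >= 0 counts.")
  if (min(data) < 0) abort("camera counts must be >= 0.")
  structure(
    list(data = data, frame_rate = frame_rate, pixel_size = pixel_size,
         camera_offset = camera_offset, n_trials = as.integer(n_trials)),
    class = "gevi_movie")
}

#' @export
print.gevi_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<gevi_movie> %d x %d px, %d frames @ %g Hz (%.2f um/px, offset %g, %d trial%s)\n",
    d[1], d[2], d[3], x$frame_rate, x$pixel_size, x$camera_offset,
    x$n_trials, if (x$n_trials == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.gevi_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3]

#' Fluorescence time course
#'
#' A 1-D fluorescence trace with its sampling rate and sign convention.
#' `"raw"` traces follow the camera: depolarization makes the FRET-donor
#' fluorescence *decrease*, so evoked signals are negative-going.
#' `"depol_positive"` traces have been flipped so that depolarization is
#' positive-going (the convention used for thresholding and peak picking).
#'
#' @param values Numeric vector. Dimensionless fraction for dF/F traces, or
#'   counts for raw traces.
#' @param rate Sampling rate, Hz.
#' @param convention `"raw"` or `"depol_positive"`.
#' @param unit `"fraction"` (dF/F) or `"counts"`.
#' @param roi_id,n_trials Optional provenance annotations.
#'
#' @return A numeric vector of class `fluor_trace` with metadata attributes.
#' @export
fluor_trace <- function(values, rate, convention = c("raw", "depol_positive"),
                        unit = c("fraction", "counts"),
                        roi_id = NA_character_, n_trials = 1L) {
  convention <- match.arg(convention)
  unit <- match.arg(unit)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    abort("trace values must be finite and non-missing.")
  if (rate <= 0) abort("`rate` must be positive (Hz).")
  structure(as.numeric(values), rate = rate, convention = convention,
            unit = unit, roi_id = roi_id, n_trials = as.integer(n_trials),
            class = "fluor_trace")
}

trace_rate <- function(trace) attr(trace, "rate")
trace_convention <- function(trace) attr(trace, "convention")

retrace <- function(values, template, rate = trace_rate(template),
                    convention = trace_convention(template)) {
  fluor_trace(values, rate = rate, convention = convention,
              unit = attr(template, "unit") %||% "fraction",
              roi_id = attr(template, "roi_id") %||% NA_character_,
              n_trials = attr(template, "n_trials") %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flip a trace between raw and depolarization-positive conventions
#'
#' @param trace A [fluor_trace()].
#' @return The trace multiplied by -1 with the convention flag flipped.
#' @export
flip_convention <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  newc <- if (trace_convention(trace) == "raw") "depol_positive" else "raw"
  retrace(-unclass(trace), trace, convention = newc)
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples @ %g Hz [%s, %s]\n",
              length(x), trace_rate(x), trace_convention(x),
              attr(x, "unit")))
  invisible(x)
}

#' @export
as_tibble.fluor_trace <- function(x, ...) {
  tibble(time_s = (seq_along(x) - 1) / trace_rate(x),
         value = as.numeric(x))
}

#' @export
autoplot.fluor_trace <- function(object, ...) {
  df <- as_tibble(object)
  ylab <- if (attr(object, "unit") == "fraction") "dF/F (fraction)" else "counts"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab)
  # raw-convention fluorescence is conventionally plotted on an inverted axis
  # so that depolarization points up
  if (trace_convention(object) == "raw") p <- p + ggplot2::scale_y_reverse()
  p
}
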