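# ---- protocol/frame bookkeeping ------------------------------------------

#' Frame indices inside stimulation periods
#'
#' Long depolarizations occupy `[onset, onset + duration]`; spikes occupy
#' the 50 ms stimulus period after onset. A frame is a stimulus frame when
#' its integration interval overlaps a stimulus window.
#'
#' @param protocol A [stim_protocol()].
#' @param rate Frame rate of the sequence, Hz.
#' @param n_frames Number of frames available.
#' @return Sorted integer frame indices.
#' @export
stim_frames_at <- function(protocol, rate, n_frames) {
  out <- integer()
  for (i in seq_len(nrow(protocol))) {
    on <- protocol$onset[i]
    end <- on + if (protocol$kind[i] == "spike") 0.05 else protocol$duration[i]
    lo <- floor(on * rate) + 1L
    hi <- ceiling(end * rate)
    out <- c(out, lo:hi)
  }
  sort(unique(pmin(pmax(out, 1L), n_frames)))
}

#' Frames free of evoked signal
#'
#' Complement of the stimulus windows extended by a decay margin
#' (default 5 indicator time constants) so bleach fits and noise estimates
#' exclude the response tails.
#'
#' @param protocol A [stim_protocol()].
#' @param config A [scene_config()] (for rate, frame count and tau), or
#'   supply `rate`, `n_frames`, `tau` directly.
#' @param rate,n_frames,tau Overrides when no config is given.
#' @return Sorted integer frame indices.
#' @export
nonstim_frames <- function(protocol, config = NULL, rate = config$frame_rate,
                           n_frames = config$n_frames,
                           tau = config$gevi_tau) {
  excl <- integer()
  for (i in seq_len(nrow(protocol))) {
    on <- protocol$onset[i]
    end <- on + (if (protocol$kind[i] == "spike") 0.05 else protocol$duration[i]) +
      5 * tau
    excl <- c(excl, (floor(on * rate) + 1L):ceiling(end * rate))
  }
  setdiff(seq_len(n_frames), excl)
}

# ---- movie / image I/O ----------------------------------------------------

# movies and maps go to multi-page 32-bit TIFF; tiff stores 32-bit samples
# as uint32 scaled to [0,1], so values are quantized on a fixed dyadic grid
# recorded in the sidecar JSON (denom = counts per quantization step^-1).
# integer and quarter-count data round-trip bit-exactly.
MAX_UINT <- 2^32 - 1

#' Write a movie (or dF/F stack) as multi-page TIFF plus sidecar JSON
#'
#' @param movie A [gevi_movie()] or `dff_movie`.
#' @param path Output TIFF path; the sidecar metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  data <- movie$data
  is_dff <- inherits(movie, "dff_movie") && !inherits(movie, "delta_f")
  offset <- if (min(data, na.rm = TRUE) < 0) floor(min(data, na.rm = TRUE)) else 0
  denom <- if (is_dff) 2^30 else 256
  rng <- max(data, na.rm = TRUE) - offset
  if (rng * denom > MAX_UINT)
    denom <- 2^floor(log2(MAX_UINT / rng))
  na_code <- 0
  v <- data
  v[!is.finite(v)] <- offset  # NA pixels recorded in sidecar
  pages <- lapply(seq_len(dim(data)[3]), function(n)
    (v[, , n] - offset) * denom / MAX_UINT)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(class = class(movie)[1],
               frame_rate = movie$frame_rate,
               pixel_size = movie$pixel_size,
               camera_offset = movie$camera_offset %||% NA,
               n_trials = movie$n_trials %||% 1L,
               offset = offset, denom = denom,
               na_pixels = which(!is.finite(data[, , 1])))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a movie written by [write_movie()] (or any grayscale TIFF stack)
#'
#' Metadata comes from the sidecar JSON when present and can be overridden;
#' a missing frame rate is an error, never guessed.
#'
#' @param path TIFF path.
#' @param frame_rate,pixel_size,camera_offset Overrides.
#' @return A [gevi_movie()] (or `dff_movie`, per the sidecar class).
#' @export
load_movie <- function(path, frame_rate = NULL, pixel_size = NULL,
                       camera_offset = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3)
    abort("multi-channel (RGB) TIFF not supported; expected grayscale.")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  frame_rate <- frame_rate %||% meta$frame_rate
  if (is.null(frame_rate))
    abort("frame rate not recorded and not supplied; refusing to guess.")
  pixel_size <- pixel_size %||% meta$pixel_size %||% 1.04
  camera_offset <- camera_offset %||% meta$camera_offset %||% 1600
  offset <- meta$offset %||% 0
  denom <- meta$denom %||% NULL
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (!is.null(denom))
    arr <- round(arr * MAX_UINT) / denom + offset
  cls <- meta$class %||% "gevi_movie"
  if (cls == "gevi_movie")
    gevi_movie(arr, frame_rate = frame_rate, pixel_size = pixel_size,
               camera_offset = as.numeric(camera_offset),
               n_trials = meta$n_trials %||% 1L)
  else
    structure(list(data = arr, frame_rate = frame_rate,
                   pixel_size = pixel_size,
                   n_trials = meta$n_trials %||% 1L),
              class = cls)
}

#' Write / read a trace as two-column CSV
#'
#' @param trace A [fluor_trace()].
#' @param path CSV path (`time_s`, `value`).
#' @return `path` (write) or a [fluor_trace()] (read; rate inferred from
#'   the time column).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as_tibble(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param convention,unit Convention flags for the loaded trace.
#' @export
read_trace <- function(path, convention = "raw", unit = "fraction") {
  df <- utils::read.csv(path)
  rate <- 1 / median(diff(df$time_s))
  fluor_trace(df$value, rate = rate, convention = convention, unit = unit)
}

# ---- end-to-end pipeline --------------------------------------------------

#' Run the full analysis pipeline
#'
#' Trial averaging, per-pixel bleach fit (excluding stimulus windows),
#' dF/F0, activation map, somatic-ROI segmentation, ROI time course and
#' the signal/noise/SNR report; optionally writes every intermediate to
#' `out_dir`. Deterministic for a fixed input.
#'
#' @param movies A list of [gevi_movie()] trials (or a single movie).
#' @param protocol A [stim_protocol()]; required for the metrics stage.
#' @param gevi_tau Indicator decay constant, s (for signal-frame exclusion).
#' @param out_dir Optional output directory for intermediates.
#' @param map_mode Preprocessing mode for the activation map.
#' @return A list: `movie`, `bleach`, `dff`, `map`, `roi`, `trace`,
#'   `report` (tibble), `bleach_rate_roi` (%/s, median over the ROI).
#' @export
run_pipeline <- function(movies, protocol, gevi_tau = 0.02, out_dir = NULL,
                         map_mode = "visualization") {
  if (inherits(movies, "gevi_movie")) movies <- list(movies)
  if (is.null(protocol) || nrow(protocol) == 0)
    abort("protocol required for signal metrics.")
  avg <- average_trials(movies)
  nf <- dim(avg$data)[3]
  fit_frames <- nonstim_frames(protocol, rate = avg$frame_rate,
                               n_frames = nf, tau = gevi_tau)
  bleach <- pixel_bleach_fit(avg, fit_frames)
  dff <- compute_dff(avg, bleach)
  dseq <- delta_f_sequence(avg, bleach)
  filt <- preprocess_map_sequence(dseq, mode = map_mode)
  amap <- activation_map(filt, stim_frames_at(protocol, filt$frame_rate,
                                              dim(filt$data)[3]))
  roi <- segment_soma(amap)
  trace <- roi_timecourse(dff, roi)
  bleach_rate_roi <- median(bleach$rate[roi$mask], na.rm = TRUE)
  report <- snr_report(trace, protocol, bleach_rate = bleach_rate_roi)
  res <- list(movie = avg, bleach = bleach, dff = dff, map = amap,
              roi = roi, trace = trace, report = report,
              bleach_rate_roi = bleach_rate_roi)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_movie(dff, file.path(out_dir, "dff.tif"))
    write_trace(trace, file.path(out_dir, "roi_trace.csv"))
    utils::write.csv(report, file.path(out_dir, "snr_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("voltimg")),
           bleach_rate_roi_pct_s = bleach_rate_roi,
           roi_pixels = roi$n_pixels,
           threshold = roi$threshold),
      file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = 9)
  }
  res
}

#' The Table-1 calibration preset
#'
#' A ready-made scene reproducing the magnitudes of the published
#' 100 Hz recordings: one active layer-2/3-like pyramidal cell (annular
#' soma plus basal/apical dendrites) and, optionally, one inactive
#' neighbour; 0.52 %/s bleaching; indicator kinetics slowed to 20 ms
#' (room temperature); AP and 100-ms-step amplitudes set so that the
#' measured signal sizes land at ~0.14 % and ~0.59 %; photon budget set so
#' that a 4-trial average yields ~0.04 % baseline noise.
#'
#' @param seed Integer seed.
#' @param stimulus `"both"` (default: 100 ms depolarization then one
#'   spike), `"depol"` or `"spike"`.
#' @param with_inactive Include an inactive neighbour neuron.
#' @param fov Field of view in pixels.
#' @param n_frames,frame_rate Movie length and rate.
#' @return List: `geometries`, `config`, `protocol`, `active`.
#' @export
scene_table1 <- function(seed = 1L, stimulus = c("both", "depol", "spike"),
                         with_inactive = TRUE, fov = c(96, 96),
                         n_frames = 320L, frame_rate = 100) {
  stimulus <- match.arg(stimulus)
  tau <- 0.02
  ps <- 1.04
  # ROI-measured amplitudes are diluted by ambient fluorescence; the
  # configured membrane-true amplitudes carry the inverse factor so the
  # measured magnitudes land on the calibration targets
  dilution <- 0.71
  ctr <- c(46, 34) * ps
  g1 <- neuron_geometry(
    soma_center = ctr, soma_radius = 11, membrane_thickness = 3,
    dendrites = list(
      list(from = ctr, to = ctr + c(-28, 18), width = 1.3),
      list(from = ctr, to = ctr + c(30, 8), width = 1.3),
      list(from = ctr, to = ctr + c(8, 38), width = 1.1)),
    defocus_sigma = 0.8)
  geoms <- list(g1)
  active <- TRUE
  if (with_inactive) {
    # neighbours sit off the focal plane; only the patched cell is focused
    ctr2 <- c(22, 74) * ps
    g2 <- neuron_geometry(
      soma_center = ctr2, soma_radius = 9, membrane_thickness = 3,
      dendrites = list(list(from = ctr2, to = ctr2 + c(22, -14), width = 1.3)),
      defocus_sigma = 2.5)
    geoms <- c(geoms, list(g2))
    active <- c(TRUE, FALSE)
  }
  protocol <- switch(stimulus,
    both = stim_protocol(c(1.0, 2.2), c(0.1, 0.002),
                         c("long_depol", "spike")),
    depol = stim_protocol(1.0, 0.1, "long_depol"),
    spike = stim_protocol(2.2, 0.002, "spike"))
  config <- scene_config(
    fov = fov, frame_rate = frame_rate, n_frames = n_frames,
    pixel_size = ps, camera_offset = 1600,
    baseline_photons = 6000, bleach_rate = 0.0052,
    background_fraction = 0.75, gevi_tau = tau,
    ap_amplitude = 0.0014 / (dilution * ap_attenuation(tau, frame_rate)),
    depol_amplitude = 0.0059 / dilution, read_noise_sd = 5, seed = seed)
  list(geometries = geoms, config = config, protocol = protocol,
       active = active)
}
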