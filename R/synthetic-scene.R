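#' Neuron geometry for scene rendering
#'
#' Describes one membrane-labelled neuron: a spherical soma rendered as its
#' wide-field projection (bright membrane annulus, dimmer interior from the
#' top/bottom membrane) plus straight dendritic segments rendered as
#' projected cylinders. All coordinates are in um relative to the field of
#' view origin (top-left pixel corner).
#'
#' @param soma_center Numeric length 2, (row, col) of the soma centre in um.
#' @param soma_radius Soma outer radius, um.
#' @param membrane_thickness Membrane shell thickness, um. Must be positive
#'   and smaller than `soma_radius`. Wide-field projection of a shell this
#'   thick produces the characteristic annulus a few pixels wide.
#' @param dendrites List of dendritic segments, each a list with elements
#'   `from` (um, length 2), `to` (um, length 2) and `width` (um).
#' @param defocus_sigma Gaussian blur sigma in um modelling depth defocus.
#' @param brightness Relative expression level (scales this neuron's map).
#'
#' @return An object of class `neuron_geometry`.
#' @export
neuron_geometry <- function(soma_center, soma_radius = 10,
                            membrane_thickness = 3, dendrites = list(),
                            defocus_sigma = 1.5, brightness = 1) {
  if (soma_radius <= 0) abort("`soma_radius` must be > 0.")
  if (membrane_thickness <= 0 || membrane_thickness >= soma_radius)
    abort("`membrane_thickness` must be in (0, soma_radius).")
  for (d in dendrites)
    if (!all(c("from", "to", "width") %in% names(d)))
      abort("each dendrite needs `from`, `to` and `width`.")
  structure(list(soma_center = as.numeric(soma_center),
                 soma_radius = soma_radius,
                 membrane_thickness = membrane_thickness,
                 dendrites = dendrites, defocus_sigma = defocus_sigma,
                 brightness = brightness),
            class = "neuron_geometry")
}

#' Scene configuration for the synthetic movie generator
#'
#' Holds every acquisition and indicator parameter of a simulated recording.
#' The defaults are the study conditions the package is calibrated for:
#' 1.04 um pixels, camera offset 1600 counts (4x4 binning), negative-going
#' dF/F on depolarization (FRET donor emission), single-exponential decay
#' kinetics, single-exponential photobleaching, Poisson photon shot noise
#' and Gaussian read noise.
#'
#' @param fov Field of view, (rows, cols) in pixels.
#' @param frame_rate Frames per second, Hz.
#' @param n_frames Number of frames per trial.
#' @param pixel_size um per pixel (default 1.04).
#' @param camera_offset Counts (default 1600).
#' @param baseline_photons Expected photons per soma-membrane pixel per frame.
#' @param bleach_rate Initial fractional fluorescence loss per second
#'   (e.g. 0.0052 for 0.52 %/s). The effective rate collapses illumination
#'   intensity and bleaching quantum yield into one number.
#' @param background_fraction Fraction `f_b` in `[0, 1)` of collected
#'   fluorescence arising from non-signaling structures; rendered as a
#'   spatially uniform additive background.
#' @param gevi_tau Indicator decay time constant, s (12 ms at 34 C for the
#'   donor signal modelled here; slower at room temperature).
#' @param ap_amplitude Peak -dF/F fraction of a single action potential
#'   (before frame-integration attenuation).
#' @param depol_amplitude Steady-state -dF/F fraction of a long
#'   depolarizing step.
#' @param read_noise_sd Additive Gaussian read noise, counts.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#'
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(fov, frame_rate, n_frames, pixel_size = 1.04,
                         camera_offset = 1600, baseline_photons = 5000,
                         bleach_rate = 0.0052, background_fraction = 0,
                         gevi_tau = 0.02, ap_amplitude = 0.0018,
                         depol_amplitude = 0.0059, read_noise_sd = 5,
                         seed = 1L) {
  if (length(fov) != 2L || any(fov <= 0))
    abort("`fov` must be two positive pixel counts (rows, cols).")
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  if (gevi_tau <= 0) abort("`gevi_tau` must be > 0.")
  if (camera_offset < 0) abort("`camera_offset` must be >= 0.")
  if (background_fraction < 0 || background_fraction >= 1)
    abort("`background_fraction` must be in [0, 1).")
  for (a in c(ap_amplitude, depol_amplitude))
    if (a <= 0 || a > 0.05)
      abort("amplitudes must be fractions in (0, 0.05].")
  structure(list(fov = as.integer(fov), frame_rate = frame_rate,
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 camera_offset = camera_offset,
                 baseline_photons = baseline_photons,
                 bleach_rate = bleach_rate,
                 background_fraction = background_fraction,
                 gevi_tau = gevi_tau, ap_amplitude = ap_amplitude,
                 depol_amplitude = depol_amplitude,
                 read_noise_sd = read_noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Stimulus protocol
#'
#' @param onset Numeric vector of pulse onsets, s.
#' @param duration Pulse durations, s (recycled).
#' @param kind `"long_depol"` or `"spike"` per pulse (recycled).
#' @param trial_count Number of repeated trials.
#'
#' @return A `stim_protocol`: a tibble of pulses with a `trial_count`
#'   attribute.
#' @export
stim_protocol <- function(onset, duration, kind = "long_depol",
                          trial_count = 1L) {
  p <- tibble(onset = as.numeric(onset),
              duration = rep_len(as.numeric(duration), length(onset)),
              kind = rep_len(kind, length(onset)))
  if (!all(p$kind %in% c("long_depol", "spike")))
    abort("pulse `kind` must be 'long_depol' or 'spike'.")
  p <- arrange(p, .data$onset)
  if (nrow(p) > 1 &&
      any(p$onset[-1] < (p$onset + p$duration)[-nrow(p)]))
    abort("pulses must be non-overlapping.")
  if (any(p$onset < 0)) abort("onsets must be >= 0.")
  if (trial_count < 1) abort("`trial_count` must be >= 1.")
  structure(p, trial_count = as.integer(trial_count),
            class = c("stim_protocol", class(p)))
}

# projected path length through a spherical shell at in-plane radius rho
shell_path <- function(rho, r_out, r_in) {
  outer <- ifelse(rho < r_out, 2 * sqrt(pmax(r_out^2 - rho^2, 0)), 0)
  inner <- ifelse(rho < r_in, 2 * sqrt(pmax(r_in^2 - rho^2, 0)), 0)
  outer - inner
}

render_one <- function(geom, config, index = NA_integer_, blur = TRUE) {
  fov <- config$fov; ps <- config$pixel_size
  lim <- fov * ps
  ctr <- geom$soma_center
  if (any(ctr - geom$soma_radius < 0) ||
      ctr[1] + geom$soma_radius > lim[1] ||
      ctr[2] + geom$soma_radius > lim[2])
    abort(sprintf("neuron %d: soma extends outside the field of view", index))
  rr <- (seq_len(fov[1]) - 0.5) * ps
  cc <- (seq_len(fov[2]) - 0.5) * ps
  rho <- sqrt(outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`))
  r_in <- geom$soma_radius - geom$membrane_thickness
  map <- shell_path(rho, geom$soma_radius, r_in)
  # ground truth uses projection footprints: the soma interior receives
  # top/bottom membrane fluorescence, so the whole disc is soma signal
  soma_mask <- rho <= geom$soma_radius
  membrane_mask <- soma_mask
  for (k in seq_along(geom$dendrites)) {
    d <- geom$dendrites[[k]]
    if (any(unlist(d[c("from", "to")]) < 0) ||
        any(c(d$from[1], d$to[1]) > lim[1]) ||
        any(c(d$from[2], d$to[2]) > lim[2]))
      abort(sprintf("neuron %d: dendrite %d extends outside the field of view",
                    index, k))
    # distance from each pixel centre to the segment
    v <- d$to - d$from; L2 <- sum(v^2)
    pr <- outer(rr - d$from[1], rep(1, fov[2]))
    pc <- outer(rep(1, fov[1]), cc - d$from[2])
    t_ <- if (L2 > 0) pmin(pmax((pr * v[1] + pc * v[2]) / L2, 0), 1) else 0
    dist <- sqrt((pr - t_ * v[1])^2 + (pc - t_ * v[2])^2)
    w <- d$width / 2
    dmap <- ifelse(dist < w, 2 * sqrt(pmax(w^2 - dist^2, 0)), 0)
    membrane_mask <- membrane_mask | dmap > 0
    map <- map + dmap
  }
  # normalize so a soma-membrane pixel averages 1, then apply expression level
  norm <- mean(map[soma_mask])
  map <- map / norm * geom$brightness
  if (blur && geom$defocus_sigma > 0)
    map <- gauss_blur2d(map, geom$defocus_sigma / ps)
  list(map = map, membrane_mask = membrane_mask, soma_mask = soma_mask)
}

#' Render membrane-localized fluorescence for a set of neurons
#'
#' Produces the relative brightness map of the scene: each soma appears as a
#' bright membrane annulus with a darker interior (projection of a spherical
#' shell) and dendrites as projected cylinders, optionally blurred by a
#' Gaussian defocus kernel.
#'
#' @param geometries List of [neuron_geometry()] objects.
#' @param config A [scene_config()].
#' @return A rows x cols matrix of non-negative relative brightness.
#' @export
render_neurons <- function(geometries, config) {
  if (length(geometries) == 0) abort("`geometries` must be non-empty.")
  maps <- lapply(seq_along(geometries), function(i)
    render_one(geometries[[i]], config, i)$map)
  Reduce(`+`, maps)
}

#' Ground-truth -dF/F response waveform for a protocol
#'
#' Evaluates the noiseless indicator response (as a positive,
#' depolarization-positive fraction) at arbitrary time points: spikes decay
#' exponentially from `ap_amplitude` with time constant `gevi_tau`; long
#' depolarizations relax toward `depol_amplitude` with the same constant and
#' decay back after stimulus offset.
#'
#' @param protocol A [stim_protocol()].
#' @param config A [scene_config()] (uses `gevi_tau`, `ap_amplitude`,
#'   `depol_amplitude`).
#' @param times Numeric vector of times, s.
#' @return Numeric vector of -dF/F fractions (>= 0), same length as `times`.
#' @export
response_waveform <- function(protocol, config, times) {
  tau <- config$gevi_tau
  out <- numeric(length(times))
  for (i in seq_len(nrow(protocol))) {
    on <- protocol$onset[i]; dur <- protocol$duration[i]
    if (protocol$kind[i] == "spike") {
      dt <- times - on
      out <- out + ifelse(dt >= 0, config$ap_amplitude * exp(-dt / tau), 0)
    } else {
      amp <- config$depol_amplitude
      dt <- times - on
      during <- dt >= 0 & dt < dur
      after <- dt >= dur
      peak <- amp * (1 - exp(-dur / tau))
      out[during] <- out[during] + amp * (1 - exp(-dt[during] / tau))
      out[after] <- out[after] + peak * exp(-(dt[after] - dur) / tau)
    }
  }
  out
}

#' Frame-integration attenuation of an exponentially decaying transient
#'
#' A camera integrating over the full frame period low-pass filters the
#' indicator response. For an instantaneous-rise transient decaying with
#' time constant `tau`, the best-case frame average (onset aligned to a
#' frame boundary) is `ap_amplitude * tau * rate * (1 - exp(-1/(tau*rate)))`.
#'
#' @param tau Indicator decay constant, s.
#' @param frame_rate Hz.
#' @return Attenuation factor in (0, 1).
#' @export
ap_attenuation <- function(tau, frame_rate) {
  x <- tau * frame_rate
  x * (1 - exp(-1 / x))
}

#' Simulate a wide-field GEVI movie with ground truth
#'
#' Renders the scene, builds per-neuron noiseless -dF/F waveforms
#' (supersampled at >= 10x the frame rate and averaged within each frame
#' period to emulate full-frame-period photon integration), applies a
#' single-exponential bleach decay and a uniform background contributing the
#' configured fraction of total fluorescence, then draws Poisson photon shot
#' noise per pixel per frame and adds Gaussian read noise and the camera
#' offset.
#'
#' @param geometries List of [neuron_geometry()].
#' @param config A [scene_config()].
#' @param protocol A [stim_protocol()]; must fit inside the movie.
#' @param active Logical vector, one flag per neuron; inactive neurons
#'   fluoresce but do not respond.
#' @param trial Trial index (>= 0); the RNG seed used is `seed + trial`.
#'
#' @return A list with elements `movie` (a [gevi_movie()]) and `truth`, a
#'   list holding per-neuron membrane masks, soma masks, brightness maps,
#'   noiseless frame-integrated -dF/F traces, the bleach decay factors and
#'   the noiseless expected movie.
#' @export
simulate_movie <- function(geometries, config, protocol,
                           active = rep(TRUE, length(geometries)),
                           trial = 0L) {
  if (length(active) != length(geometries))
    abort("`active` must have one flag per neuron.")
  dur_movie <- config$n_frames / config$frame_rate
  if (nrow(protocol) > 0 &&
      max(protocol$onset + protocol$duration) > dur_movie)
    abort("protocol extends past the end of the movie.")

  rend <- lapply(seq_along(geometries), function(i)
    render_one(geometries[[i]], config, i))
  nf <- config$n_frames

  # frame-integrated waveform: supersample at >= 10x frame rate
  ss <- 10L
  tt <- (seq_len(nf * ss) - 0.5) / (config$frame_rate * ss)
  frame_idx <- rep(seq_len(nf), each = ss)
  frame_mid <- (seq_len(nf) - 0.5) / config$frame_rate
  wave <- response_waveform(protocol, config, tt)
  dff_frames <- as.numeric(tapply(wave, frame_idx, mean))

  bleach <- exp(-config$bleach_rate * frame_mid)

  fov <- config$fov
  base <- lapply(rend, function(r) r$map * config$baseline_photons)
  total0 <- sum(vapply(base, sum, 0))
  f_b <- config$background_fraction
  bg <- if (f_b > 0) f_b / (1 - f_b) * total0 / prod(fov) else 0

  traces <- lapply(seq_along(geometries), function(i)
    if (active[i]) dff_frames else numeric(nf))

  # the background is other cells' indicator under the same illumination,
  # so it bleaches at the same effective rate
  expected <- array(0, dim = c(fov, nf))
  for (n in seq_len(nf)) {
    fr <- matrix(bg * bleach[n], fov[1], fov[2])
    for (i in seq_along(base))
      fr <- fr + base[[i]] * bleach[n] * (1 - traces[[i]][n])
    expected[, , n] <- fr
  }

  data <- withr::with_seed(config$seed + as.integer(trial), {
    shot <- array(rpois(length(expected), lambda = expected), dim = dim(expected))
    out <- config$camera_offset + shot
    if (config$read_noise_sd > 0)
      out <- out + array(rnorm(length(out), 0, config$read_noise_sd),
                         dim = dim(out))
    out
  })
  data[data < 0] <- 0

  movie <- gevi_movie(data, frame_rate = config$frame_rate,
                      pixel_size = config$pixel_size,
                      camera_offset = config$camera_offset)
  truth <- list(
    background_per_px = bg,
    membrane_masks = lapply(rend, `[[`, "membrane_mask"),
    soma_masks = lapply(rend, `[[`, "soma_mask"),
    brightness = lapply(rend, `[[`, "map"),
    dff_traces = traces,
    bleach = bleach,
    expected = expected,
    active = active)
  list(movie = movie, truth = truth)
}

#' Simulate repeated trials of the same scene
#'
#' @inheritParams simulate_movie
#' @param n_trials Number of trials; trial `k` uses seed `seed + k - 1`.
#' @return List with `movies` (list of [gevi_movie()]) and `truth` (from the
#'   first trial; the noiseless scene is identical across trials).
#' @export
simulate_trials <- function(geometries, config, protocol,
                            active = rep(TRUE, length(geometries)),
                            n_trials = 4L) {
  sims <- lapply(seq_len(n_trials) - 1L, function(k)
    simulate_movie(geometries, config, protocol, active, trial = k))
  list(movies = lapply(sims, `[[`, "movie"), truth = sims[[1]]$truth)
}

#' Simulate a companion electrophysiology trace
#'
#' Produces a stereotyped intracellular voltage trace matching a protocol:
#' spike pulses become template action potentials, long depolarizations
#' become plateau steps, on a resting potential of -65 mV with small
#' Gaussian membrane noise.
#'
#' @param protocol A [stim_protocol()].
#' @param sampling_rate Hz, >= 1000.
#' @param duration Trace duration, s.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `time_s` and `voltage_mv`.
#' @export
simulate_ephys <- function(protocol, sampling_rate = 10000, duration = NULL,
                           seed = 1L) {
  if (sampling_rate < 1000) abort("`sampling_rate` must be >= 1 kHz.")
  if (is.null(duration))
    duration <- if (nrow(protocol)) max(protocol$onset + protocol$duration) + 0.1 else 0.1
  tt <- seq(0, duration, by = 1 / sampling_rate)
  v <- rep(-65, length(tt))
  for (i in seq_len(nrow(protocol))) {
    on <- protocol$onset[i]
    if (protocol$kind[i] == "spike") {
      dt <- tt - on
      up <- dt >= 0 & dt < 0.001
      down <- dt >= 0.001 & dt < 0.003
      v[up] <- v[up] + 95 * (dt[up] / 0.001)
      v[down] <- v[down] + 95 * exp(-(dt[down] - 0.001) / 0.0007) -
        5 * (1 - exp(-(dt[down] - 0.001) / 0.002))
    } else {
      inpulse <- tt >= on & tt < on + protocol$duration[i]
      v[inpulse] <- v[inpulse] + 15
    }
  }
  v <- v + withr::with_seed(seed, rnorm(length(v), 0, 0.2))
  tibble(time_s = tt, voltage_mv = v)
}
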