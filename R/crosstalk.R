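#' 2-D spatial autocorrelation of an activation map
#'
#' Full (zero-padded) autocorrelation of the mean-subtracted map, divided by
#' its zero-lag value; the 1-pixel central peak contributed by per-pixel
#' noise is then removed by replacing the central pixel with the mean of its
#' 8 neighbours, and the image is min-max normalized to `[0, 1]`. The
#' result quantifies how far one cell's optical signal spreads: its value
#' at lag r estimates the fraction of signal power appearing at separation
#' r. Use maps preprocessed in `"spread"` mode (no spatial filtering),
#' otherwise the filter widens the ACF.
#'
#' @param map An [activation_map()] (or plain matrix with a `pixel_size`
#'   argument).
#' @param pixel_size um per pixel (taken from the map when available).
#' @return An `acf_image`: `(2R-1) x (2C-1)` matrix in `[0, 1]` with
#'   `pixel_size`.
#' @export
spatial_acf <- function(map, pixel_size = NULL) {
  m <- if (inherits(map, "activation_map")) map$map else map
  if (is.null(pixel_size))
    pixel_size <- if (inherits(map, "activation_map")) map$pixel_size else 1
  m[!is.finite(m)] <- mean(m[is.finite(m)])
  m <- m - mean(m)
  if (all(m == 0)) abort("constant map has no autocorrelation.")
  d <- dim(m)
  # full correlation via zero padding; identical to the direct sum
  pr <- 2L * d[1] - 1L; pc <- 2L * d[2] - 1L
  pad <- matrix(0, pr, pc)
  pad[seq_len(d[1]), seq_len(d[2])] <- m
  F <- fft(pad)
  ac <- Re(fft(F * Conj(F), inverse = TRUE)) / length(pad)
  # reorder so zero lag sits at the centre
  ac <- ac[c((d[1] + 1):pr, 1:d[1]), c((d[2] + 1):pc, 1:d[2])]
  ac <- ac / ac[d[1], d[2]]
  ctr <- c(d[1], d[2])
  nb <- ac[ctr[1] + (-1:1), ctr[2] + (-1:1)]
  ac[ctr[1], ctr[2]] <- (sum(nb) - nb[2, 2]) / 8
  ac <- (ac - min(ac)) / (max(ac) - min(ac))
  structure(list(acf = ac, pixel_size = pixel_size, angle = 0),
            class = "acf_image")
}

#' @export
print.acf_image <- function(x, ...) {
  cat(sprintf("<acf_image> %d x %d px (%.2f um/px)\n",
              nrow(x$acf), ncol(x$acf), x$pixel_size))
  invisible(x)
}

# orientation (radians, from the column axis) of the >= level region by
# second central moments; ties toward 0
acf_orientation <- function(acf, level = 0.5) {
  idx <- which(acf$acf >= level, arr.ind = TRUE)
  ctr <- (dim(acf$acf) + 1) / 2
  r <- idx[, 1] - ctr[1]; c_ <- idx[, 2] - ctr[2]
  mu20 <- mean(c_^2); mu02 <- mean(r^2); mu11 <- mean(r * c_)
  if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) return(0)
  0.5 * atan2(2 * mu11, mu20 - mu02)
}

#' Rotationally align and average ACF images
#'
#' Rotates each ACF so its principal (longest) axis lies along the
#' horizontal (column) axis, then averages pixel-wise and renormalizes to
#' `[0, 1]`. Averaging over cells removes cell-specific dendritic structure
#' and leaves the generic elliptical falloff.
#'
#' @param acfs List of `acf_image`s with identical pixel size.
#' @return A mean `acf_image`.
#' @export
align_average_acfs <- function(acfs) {
  if (!length(acfs)) abort("need at least one ACF.")
  ps <- vapply(acfs, `[[`, 0, "pixel_size")
  if (length(unique(ps)) != 1) abort("mixed pixel sizes.")
  dims <- vapply(acfs, function(a) dim(a$acf), integer(2))
  if (any(dims != dims[, 1])) abort("ACFs must share dimensions to average.")
  rot <- lapply(acfs, function(a) {
    ang <- acf_orientation(a)
    rotate_bilinear(a$acf, ang, fill = NA_real_)
  })
  # average over defined pixels only: rotation leaves undefined corners
  stack <- array(unlist(rot), dim = c(dim(rot[[1]]), length(rot)))
  avg <- apply(stack, c(1, 2), mean, na.rm = TRUE)
  avg[!is.finite(avg)] <- 0
  avg <- (avg - min(avg)) / (max(avg) - min(avg))
  structure(list(acf = avg, pixel_size = ps[1], angle = NA_real_),
            class = "acf_image")
}

#' Long- and short-axis ACF profiles
#'
#' Values of the ACF against distance (um) along its principal (long) axis
#' and the orthogonal (short) axis, averaging the two opposite rays of each
#' axis (the ACF is 180-degree symmetric up to interpolation error).
#'
#' @param acf An `acf_image`.
#' @param step_px Sampling step along the ray, px.
#' @return An `acf_profile` tibble: `distance_um`, `long`, `short`.
#' @export
acf_axis_profiles <- function(acf, step_px = 0.5) {
  ang <- acf_orientation(acf)
  half <- (max(dim(acf$acf)) - 1) / 2
  dd <- seq(0, half, by = step_px)
  ray <- function(a) {
    v1 <- sample_ray(acf$acf, a, dd)
    v2 <- sample_ray(acf$acf, a + pi, dd)
    rowMeans(cbind(v1, v2), na.rm = TRUE)
  }
  out <- tibble(distance_um = dd * acf$pixel_size,
                long = ray(ang), short = ray(ang + pi / 2))
  structure(out, class = c("acf_profile", class(out)))
}

profile_axis <- function(profile, axis = c("long", "short")) {
  axis <- match.arg(axis)
  list(d = profile$distance_um, v = profile[[axis]])
}

# first distance at which a profile falls below `level` (linear interp)
first_crossing <- function(d, v, level) {
  below <- which(v < level)
  below <- below[below > 1]
  if (!length(below)) return(NA_real_)
  i <- below[1]
  d[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) * (d[i] - d[i - 1])
}

#' 50% cutoff widths of an ACF
#'
#' Distance along the long and short principal axes at which the
#' interpolated ACF profile first falls below `level`. The level-0.5
#' cutoff is the distance at which a neighbour would pick up half of the
#' cell's signal power.
#'
#' @param acf An `acf_image`.
#' @param level Threshold in `(0, 1]`; `level = 1` gives 0 um.
#' @return Tibble: `long_um`, `short_um`.
#' @export
cutoff_widths <- function(acf, level = 0.5) {
  if (level <= 0 || level > 1) abort("`level` must be in (0, 1].")
  if (level == 1) return(tibble(long_um = 0, short_um = 0))
  p <- acf_axis_profiles(acf)
  lo <- first_crossing(p$distance_um, p$long, level)
  sh <- first_crossing(p$distance_um, p$short, level)
  if (is.na(lo) || is.na(sh))
    abort(sprintf(
      "profile never falls below %g within the map; half-width %.1f um is a lower bound.",
      level, max(p$distance_um)))
  tibble(long_um = lo, short_um = sh)
}

# interpolate an axis profile at arbitrary distances; 0 beyond support
profile_value <- function(profile, axis, dist_um) {
  ax <- profile_axis(profile, axis)
  ok <- is.finite(ax$v)
  out <- approx(ax$d[ok], ax$v[ok], xout = dist_um, rule = 1)$y
  miss <- is.na(out)
  if (any(miss)) {
    warn(sprintf("%d neighbour(s) beyond the ACF support; ACF taken as 0.",
                 sum(miss)))
    out[miss] <- 0
  }
  out
}

#' Crosstalk fraction from neighbouring neurons
#'
#' For a target neuron surrounded by similar neurons at distances `r_i`,
#' the fraction of the measured signal amplitude contributed by the
#' neighbours is estimated as `1 - 1 / (1 + 2 * sum_i ACF(r_i))`, with the
#' activity-map spatial autocorrelation evaluated at each separation. A
#' single neighbour sitting at the 50% cutoff (ACF = 0.5) contributes 50%.
#'
#' @param profile An [acf_axis_profiles()] tibble (or NULL when
#'   `acf_values` are given directly).
#' @param scenario Tibble with `distance_um` and optionally `axis`
#'   (`"long"`/`"short"`, default long) describing neighbour positions.
#' @param acf_values Alternatively, the ACF values at the neighbours,
#'   bypassing interpolation.
#' @return Crosstalk fraction in `[0, 1)`.
#' @export
crosstalk_fraction <- function(profile = NULL, scenario = NULL,
                               acf_values = NULL) {
  if (is.null(acf_values)) {
    if (is.null(profile) || is.null(scenario))
      abort("give `profile` + `scenario`, or `acf_values`.")
    if (nrow(scenario) == 0) return(0)
    if (any(scenario$distance_um <= 0)) abort("distances must be > 0.")
    axis <- scenario$axis %||% rep("long", nrow(scenario))
    acf_values <- vapply(seq_len(nrow(scenario)), function(i)
      profile_value(profile, axis[i], scenario$distance_um[i]), 0)
  }
  if (!length(acf_values)) return(0)
  if (any(acf_values < 0)) abort("ACF values must be >= 0.")
  1 - 1 / (1 + 2 * sum(acf_values))
}

# hexagonal-lattice sites of the origin's neighbourhood out to max_radius
hex_neighbors <- function(side, max_radius) {
  kmax <- ceiling(max_radius / side) + 1L
  ij <- expand.grid(i = -kmax:kmax, j = -kmax:kmax)
  x <- side * (ij$i + ij$j / 2)
  y <- side * ij$j * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  sort(d[d > 1e-9 & d <= max_radius + 1e-9])
}

#' Crosstalk for neurons on a hexagonal grid
#'
#' Enumerates all hexagonal-lattice neighbours of a target neuron out to
#' `max_radius` and evaluates [crosstalk_fraction()] with the ACF read
#' along the short axis (best case: narrow signal spread) and along the
#' long axis (worst case).
#'
#' @param profile An [acf_axis_profiles()] tibble.
#' @param side Lattice spacing, um.
#' @param max_radius Truncation radius, um (default `3 * side`; the ACF is
#'   in the noise beyond that in practice).
#' @return Tibble: `best_case`, `worst_case`, `n_neighbors`.
#' @export
hex_grid_crosstalk <- function(profile, side, max_radius = 3 * side) {
  if (side <= 0) abort("`side` must be > 0.")
  if (max_radius < side) abort("`max_radius` must be >= `side`.")
  dists <- hex_neighbors(side, max_radius)
  best <- crosstalk_fraction(profile,
                             tibble(distance_um = dists, axis = "short"))
  worst <- crosstalk_fraction(profile,
                              tibble(distance_um = dists, axis = "long"))
  tibble(best_case = best, worst_case = worst, n_neighbors = length(dists))
}

#' Minimum neighbour distance for a crosstalk budget
#'
#' Inverts the single-pair crosstalk formula on an ACF profile: the
#' smallest nearest-neighbour distance at which one neighbour's crosstalk
#' stays below `max_crosstalk` (worst case: long axis).
#'
#' @param profile An [acf_axis_profiles()] tibble.
#' @param max_crosstalk Tolerated crosstalk fraction in `(0, 1)`.
#' @param axis `"long"` (default, conservative) or `"short"`.
#' @return Distance in um (NA when the budget cannot be met inside the
#'   profile support).
#' @export
plan_sparsity <- function(profile, max_crosstalk, axis = "long") {
  if (max_crosstalk <= 0 || max_crosstalk >= 1)
    abort("`max_crosstalk` must be in (0, 1).")
  # invert 1 - 1/(1 + 2a) = c  ->  a = c / (2 (1 - c))
  a_max <- max_crosstalk / (2 * (1 - max_crosstalk))
  ax <- profile_axis(profile, axis)
  first_crossing(ax$d, ax$v, a_max)
}

#' Empirical crosstalk oracle from a two-neuron simulation
#'
#' Simulates the scene, segments the target neuron's ROI from its
#' activation map and uses the ground-truth per-neuron brightness maps to
#' attribute the ROI-mean signal amplitude: the returned fraction is
#' `1 - own / (own + neighbours)` where `own` is the amplitude contributed
#' by the target's own membrane pixels. This direct measurement validates
#' the autocorrelation-based approximation.
#'
#' @param geometries List of [neuron_geometry()] (>= 2, similar shapes).
#' @param config A [scene_config()].
#' @param protocol A [stim_protocol()].
#' @param target Index of the neuron whose ROI is analysed.
#' @return Empirical crosstalk fraction in `[0, 1)`.
#' @export
mixing_oracle <- function(geometries, config, protocol, target = 1L) {
  sim <- simulate_movie(geometries, config, protocol)
  bl <- pixel_bleach_fit(sim$movie,
                         fit_frames = nonstim_frames(protocol, config))
  seq_ <- delta_f_sequence(sim$movie, bl)
  sp <- preprocess_map_sequence(seq_, mode = "spread")
  amap <- activation_map(sp, stim_frames_at(protocol, sp$frame_rate,
                                            dim(sp$data)[3]))
  # segment around the target neuron only: mask the map to its vicinity
  mask <- segment_target(amap, geometries, config, target)
  own <- sum(sim$truth$brightness[[target]][mask])
  total <- own
  for (i in setdiff(seq_along(geometries), target))
    total <- total + sum(sim$truth$brightness[[i]][mask])
  if (total <= 0) abort("ROI collects no fluorescence.")
  1 - own / total
}

# segment the component nearest the target soma (two-neuron scenes produce
# one component per active cell)
segment_target <- function(amap, geometries, config, target) {
  pos <- map_positive(amap)
  pos[!is.finite(pos)] <- 0
  thr <- yen_threshold(pos)
  fg <- pos > thr
  if (!any(fg)) abort("no active cell detected.")
  img <- EBImage::Image(fg * 1)
  brush <- EBImage::makeBrush(3, shape = "box")
  fg <- EBImage::imageData(EBImage::dilate(EBImage::closing(img, brush),
                                           brush)) > 0.5
  lab <- label_components(fg)
  ctr_px <- geometries[[target]]$soma_center / config$pixel_size
  labs <- setdiff(unique(as.integer(lab)), 0L)
  dists <- vapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    min(sqrt((idx[, 1] - ctr_px[1])^2 + (idx[, 2] - ctr_px[2])^2))
  }, 0)
  lab == labs[which.min(dists)]
}

#' @export
autoplot.acf_profile <- function(object, ...) {
  df <- tidyr_longer(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_um, .data$value,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "distance (um)", y = "ACF", colour = "axis")
}

tidyr_longer <- function(p) {
  bind_rows(tibble(distance_um = p$distance_um, value = p$long, axis = "long"),
            tibble(distance_um = p$distance_um, value = p$short, axis = "short"))
}
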