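#' Phase-aware block downsampling of a trace
#'
#' Downsampling a trace by averaging blocks of `n` frames can start at any
#' of `n` phases; each phase gives a different realization of the slower
#' acquisition. Phase `k` (k = 0..n-1) averages frames
#' `{k+1..k+n}, {k+n+1..k+2n}, ...`; a trailing partial block is dropped.
#'
#' @param trace A [fluor_trace()].
#' @param n Integer downsampling factor (>= 1, <= length/2).
#' @return A list of `n` [fluor_trace()]s at rate `rate/n`.
#' @export
phase_downsample <- function(trace, n) {
  n <- as.integer(n)
  len <- length(trace)
  if (n < 1) abort("`n` must be >= 1.")
  if (n > len / 2) abort("`n` must be <= length(trace)/2.")
  v <- as.numeric(trace)
  lapply(seq_len(n) - 1L, function(k) {
    nb <- (len - k) %/% n
    m <- matrix(v[k + seq_len(nb * n)], nrow = n)
    retrace(colMeans(m), trace, rate = trace_rate(trace) / n)
  })
}

#' Signal, noise and timing jitter versus downsampling factor
#'
#' For each integer factor `n`, forms all `n` phase-downsampled traces and
#' measures per phase: the noise as the SD of `floor(100/n)` signal-free
#' points, the signal as the (sign-corrected) peak during the stimulus
#' window minus the median of the `floor(20/n)` preceding points, and the
#' peak's time mapped back to the original time axis. The AP-timing jitter
#' per factor is the spread (max - min) of the peak time across phases.
#'
#' @param trace A flattened dF/F [fluor_trace()] (see [flatten_trace()]).
#' @param stim_window Integer `c(first, last)` frame of the stimulus window
#'   at the base rate.
#' @param noise_frames Integer frame indices (base rate) with no voltage
#'   signal; needs >= 100 at the base rate.
#' @param factors Integer downsampling factors.
#' @return A `downsample_table`: tibble with columns `factor`, `phase`,
#'   `rate_hz`, `signal_pct`, `noise_pct`, `peak_time_s`, plus attribute
#'   `base_rate`. Factors whose noise or baseline region becomes too short
#'   are omitted with a warning.
#' @export
downsample_metrics <- function(trace, stim_window, noise_frames,
                               factors = c(1, 2, 3, 4, 5, 10, 20)) {
  base_rate <- trace_rate(trace)
  if (length(noise_frames) < 100)
    abort("need >= 100 signal-free points at the base rate.")
  noise_frames <- sort(unique(as.integer(noise_frames)))
  rows <- list()
  for (n in as.integer(factors)) {
    n_noise <- 100L %/% n
    n_base <- 20L %/% n
    if (n_noise < 2L || n_base < 1L) {
      warn(sprintf("factor %d omitted: too few points for noise/baseline.", n))
      next
    }
    phases <- phase_downsample(trace, n)
    for (k in seq_len(n) - 1L) {
      ph <- phases[[k + 1L]]
      v <- as.numeric(ph)
      if (trace_convention(trace) == "raw") v <- -v
      nb <- length(v)
      # base-frame span of downsampled sample j: k + (j-1)*n + 1 .. k + j*n
      first_base <- k + (seq_len(nb) - 1L) * n + 1L
      last_base <- k + seq_len(nb) * n
      in_noise <- first_base %in% noise_frames & last_base %in% noise_frames
      noise_idx <- which(in_noise)[seq_len(min(n_noise, sum(in_noise)))]
      if (length(noise_idx) < n_noise) {
        warn(sprintf("factor %d omitted: noise region too short.", n))
        rows <- rows[!vapply(rows, function(r) r$factor[1] == n, TRUE)]
        break
      }
      noise <- sd(v[noise_idx])
      in_stim <- last_base >= stim_window[1] & first_base <= stim_window[2]
      stim_idx <- which(in_stim)
      if (!length(stim_idx)) abort("stimulus window lost at this factor.")
      pre_idx <- seq_len(min(stim_idx) - 1L)
      pre_idx <- tail(pre_idx, n_base)
      if (!length(pre_idx)) abort("no pre-stimulus baseline at this factor.")
      pk_rel <- which.max(v[stim_idx])           # earliest max on ties
      pk <- stim_idx[pk_rel]
      signal <- max(v[stim_idx]) - median(v[pre_idx])
      peak_time <- (k + (pk - 1) * n + (n + 1) / 2 - 0.5) / base_rate
      rows[[length(rows) + 1L]] <-
        tibble(factor = n, phase = k, rate_hz = base_rate / n,
               signal_pct = 100 * signal, noise_pct = 100 * noise,
               peak_time_s = peak_time)
    }
  }
  out <- bind_rows(rows)
  structure(out, base_rate = base_rate,
            class = c("downsample_table", class(out)))
}

#' Per-factor summary of a downsample table
#'
#' Phase means of signal and noise, plus the AP-timing jitter: the range of
#' the optical peak time across phases (0 by construction for a single
#' phase).
#'
#' @param table A [downsample_metrics()] result.
#' @return Tibble: `factor`, `rate_hz`, `signal_pct`, `noise_pct`,
#'   `jitter_s`.
#' @export
downsample_summary <- function(table) {
  table %>%
    group_by(.data$factor, .data$rate_hz) %>%
    summarise(signal_pct = mean(.data$signal_pct),
              noise_pct = mean(.data$noise_pct),
              jitter_s = diff(range(.data$peak_time_s)),
              .groups = "drop") %>%
    arrange(.data$factor)
}

#' Least-squares power-law fit on log-log axes
#'
#' Fits `y = A * x^b` by a straight line in log-log space. Non-positive
#' values cannot enter the logs and are dropped with a warning.
#'
#' @param x,y Numeric vectors (e.g. effective frame rate and noise SD).
#' @param form Label recorded in the result (`"noise"` or
#'   `"one_minus_signal"`).
#' @return A `power_law_fit`: list with `A`, `b`, `r_squared`, `n`, `form`,
#'   `orientation = "vs_rate"`.
#' @export
fit_power_law <- function(x, y, form = "noise") {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(!keep))
    warn(sprintf("%d non-positive point(s) dropped from the log-log fit.",
                 sum(!keep)))
  if (sum(keep) < 3) abort("need >= 3 positive points for a power-law fit.")
  lx <- log(x[keep]); ly <- log(y[keep])
  fit <- lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(A = exp(coef(fit)[[1]]), b = coef(fit)[[2]],
                 r_squared = r2, n = sum(keep), form = form,
                 orientation = "vs_rate"),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> %s = %.4g * rate^%.4g (r2 = %.4f, n = %d)\n",
              x$form, x$A, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("A", "b"), estimate = c(x$A, x$b))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(A = x$A, b = x$b, r.squared = x$r_squared, nobs = x$n,
         form = x$form, orientation = x$orientation)
}

#' Power-law fits of noise and signal loss versus frame rate
#'
#' Fits `noise = A2 * rate^b2` and `1 - signal = A1 * rate^b1` to the
#' phase-mean columns of a downsample table, both as straight lines on
#' log-log axes. The signal column is first normalized so that its
#' factor-1 value is 1 (set `normalize_signal = FALSE` if the column is
#' already in relative units); the factor-1 point of the signal fit is then
#' `1 - 1 = 0` and is dropped from the log fit.
#'
#' @param table A [downsample_metrics()] result (or its
#'   [downsample_summary()]).
#' @param normalize_signal Divide the signal column by its factor-1 value
#'   first (default TRUE).
#' @return List with elements `noise` and `signal`, both `power_law_fit`s.
#' @export
fit_power_laws <- function(table, normalize_signal = TRUE) {
  summ <- if (all(c("jitter_s") %in% names(table))) table
    else downsample_summary(table)
  sig <- summ$signal_pct
  if (normalize_signal) {
    ref <- sig[summ$factor == 1]
    if (length(ref) != 1) abort("factor 1 required to normalize the signal.")
    sig <- sig / ref
  }
  list(noise = fit_power_law(summ$rate_hz, summ$noise_pct, form = "noise"),
       signal = fit_power_law(summ$rate_hz, 1 - sig,
                              form = "one_minus_signal"))
}

#' Optimal frame rate for spike-detection SNR
#'
#' With `signal(x) = 1 - A1 * x^b1` (b1 < 0) and `noise(x) = A2 * x^b2`
#' (b2 > 0), the SNR `(1 - A1 x^b1) / (A2 x^b2)` has the closed-form
#' stationary point `x* = (b2 / (A1 (b2 - b1)))^(1/b1)`. A dense
#' logarithmic grid search over the range cross-checks the closed form; if
#' the stationary point falls outside the range the grid maximum (a
#' boundary) is returned with a warning.
#'
#' @param noise_fit,signal_fit `power_law_fit`s from [fit_power_laws()].
#' @param range Numeric `c(lo, hi)` search range, Hz.
#' @param grid_n Grid points for the cross-check.
#' @return List: `rate_hz` (the estimate), `closed_form_hz`, `grid_hz`,
#'   `snr_at_optimum`.
#' @export
optimal_rate <- function(noise_fit, signal_fit, range = c(10, 1000),
                         grid_n = 4000) {
  A1 <- signal_fit$A; b1 <- signal_fit$b
  A2 <- noise_fit$A; b2 <- noise_fit$b
  if (!(b2 > 0 && b1 < 0))
    abort("need noise exponent > 0 and signal exponent < 0.")
  snr <- function(x) (1 - A1 * x^b1) / (A2 * x^b2)
  closed <- (b2 / (A1 * (b2 - b1)))^(1 / b1)
  grid <- exp(seq(log(range[1]), log(range[2]), length.out = grid_n))
  gmax <- grid[which.max(snr(grid))]
  if (is.finite(closed) && closed >= range[1] && closed <= range[2]) {
    rate <- closed
  } else {
    warn("no interior SNR maximum in range; returning the boundary optimum.")
    rate <- gmax
  }
  list(rate_hz = rate, closed_form_hz = closed, grid_hz = gmax,
       snr_at_optimum = snr(rate))
}

# power spectrum of a decaying-exponential indicator response in the
# dimensionless frequency u = f/rate: Lorentzian with corner at 1/(2 pi tau)
signal_power <- function(u, rate_tau) 1 / (1 + (2 * pi * u * rate_tau)^2)

#' Fraction of aliased power for integrate-and-sample imaging
#'
#' Models the optical signal as a decaying exponential, whose power
#' spectrum is a Lorentzian with corner frequency `1 / (2 pi tau)`, and
#' returns the fraction of the signal power lying above the Nyquist
#' frequency -- the power that integrate-and-sample acquisition folds back
#' into the pass band as aliasing. Both integrals are evaluated
#' numerically; the fraction depends only on the product
#' `frame_rate * tau` and equals ~0.10 when the sampling period is half
#' the decay constant. (Full-frame-period integration additionally
#' attenuates the folded components through its sinc response, so this
#' fraction is a conservative design metric.)
#'
#' @param tau Indicator decay constant, s.
#' @param frame_rate Hz.
#' @return Fraction in `[0, 1]`.
#' @export
aliased_power_fraction <- function(tau, frame_rate) {
  if (tau <= 0 || frame_rate <= 0) abort("`tau` and `frame_rate` must be > 0.")
  rt <- frame_rate * tau
  total <- integrate(signal_power, 0, Inf, rate_tau = rt,
                     rel.tol = 1e-8, subdivisions = 1000L)$value
  tail_ <- integrate(signal_power, 0.5, Inf, rate_tau = rt,
                     rel.tol = 1e-8, subdivisions = 1000L)$value
  tail_ / total
}

#' Severe-aliasing reference fraction
#'
#' The aliased-power fraction when the sampling period equals half the
#' decay constant (`frame_rate = 2 / tau`); scale invariance of the
#' Lorentzian-times-sinc-squared model makes this a single dimensionless
#' constant (~0.1), used as the calibration point of the half-decay-constant
#' rule.
#'
#' @return Fraction in `[0, 1]`.
#' @export
severe_aliasing_fraction <- function() aliased_power_fraction(1, 2)

#' Minimum alias-free frame rate for an indicator
#'
#' The half-decay-constant rule: sampling periods longer than `tau / 2`
#' alias severely, so the minimum recommended rate is `2 / tau`, reported
#' to the nearest integer Hz together with the aliased-power fraction
#' there (12 ms kinetics gives 167 Hz).
#'
#' @param tau Indicator decay constant, s.
#' @return Tibble: `rate_hz` (integer), `aliased_fraction`.
#' @export
min_alias_free_rate <- function(tau) {
  if (tau <= 0) abort("`tau` must be > 0.")
  rate <- 2 / tau
  tibble(rate_hz = as.integer(round(rate)),
         aliased_fraction = aliased_power_fraction(tau, rate))
}

#' @export
autoplot.downsample_table <- function(object, ...) {
  summ <- downsample_summary(object)
  ref <- summ$signal_pct[summ$factor == 1]
  df <- dplyr::bind_rows(
    tibble(rate_hz = summ$rate_hz, value = summ$signal_pct / ref,
           panel = "signal (rel.)"),
    tibble(rate_hz = summ$rate_hz, value = summ$noise_pct,
           panel = "noise (%)"),
    tibble(rate_hz = summ$rate_hz,
           value = summ$signal_pct / summ$noise_pct, panel = "SNR"))
  ggplot2::ggplot(df, ggplot2::aes(.data$rate_hz, .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "effective frame rate (Hz)", y = NULL)
}
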