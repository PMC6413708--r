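#' Stimulus-evoked signal amplitude of a trace
#'
#' Implements the three published measurement rules on the raw
#' (negative-going) trace and returns the magnitude as a positive
#' percentage:
#'
#' * `"long_depol"` - the 5th-percentile value during the stimulus period,
#'   subtracted from the median of the previous 10 time points.
#' * `"first_spike"` - the signal extremum in the 50 ms after the stimulus
#'   (the stimulus period), subtracted from the median of the preceding
#'   10 time points. The first spike of a train gets its own rule because
#'   the immediately preceding baseline is uncontaminated.
#' * `"later_spike"` - the minimum of the 50 ms following the stimulus,
#'   subtracted from the maximum of the 20 ms preceding it (a conservative
#'   baseline when the previous transient has not fully decayed).
#'
#' The published wording mixes the plotting-inverted and raw sign
#' conventions; here every rule is evaluated on the raw trace with extrema
#' mapped accordingly, and the deliberate asymmetry between the first-spike
#' baseline (median of 10 points) and the later-spike baseline (maximum
#' over 20 ms) is preserved as printed.
#'
#' @param trace A [fluor_trace()] in raw convention (fractions).
#' @param onset_frame 1-based frame index of stimulus onset.
#' @param kind `"long_depol"`, `"first_spike"` or `"later_spike"`.
#' @param duration_s Stimulus duration in s (required for `"long_depol"`;
#'   spike rules use a fixed 50 ms window).
#' @return Signal magnitude, % dF/F.
#' @export
signal_amplitude <- function(trace, onset_frame,
                             kind = c("long_depol", "first_spike",
                                      "later_spike"),
                             duration_s = NULL) {
  kind <- match.arg(kind)
  if (trace_convention(trace) != "raw")
    trace <- flip_convention(trace)
  v <- as.numeric(trace)
  rate <- trace_rate(trace)
  to_frames <- function(t_s) as.integer(floor(t_s * rate + 0.5))
  win_len <- if (kind == "long_depol") {
    if (is.null(duration_s)) abort("`duration_s` required for long_depol.")
    to_frames(duration_s)
  } else to_frames(0.05)
  win <- onset_frame + seq_len(max(win_len, 1L)) - 1L
  if (max(win) > length(v)) abort("stimulus window extends past the trace.")
  if (kind == "later_spike") {
    nb <- max(to_frames(0.02), 1L)
    if (onset_frame <= nb)
      abort(sprintf("need >= %d pre-stimulus frames (20 ms).", nb))
    baseline <- max(v[(onset_frame - nb):(onset_frame - 1L)])
  } else {
    if (onset_frame <= 10)
      abort("need >= 10 pre-stimulus frames.")
    baseline <- median(v[(onset_frame - 10):(onset_frame - 1L)])
  }
  depth <- if (kind == "long_depol")
    quantile(v[win], 0.05, names = FALSE) else min(v[win])
  100 * (baseline - depth)
}

#' Baseline noise level of a trace
#'
#' Standard deviation of exactly the 20 samples immediately preceding the
#' stimulus, as a percentage.
#'
#' @inheritParams signal_amplitude
#' @return Noise level, % dF/F.
#' @export
noise_level <- function(trace, onset_frame) {
  if (onset_frame <= 20)
    abort("need >= 20 pre-stimulus frames for the noise estimate.")
  v <- as.numeric(trace)
  100 * sd(v[(onset_frame - 20):(onset_frame - 1L)])
}

#' Signal, noise, SNR and bleach-corrected SNR report
#'
#' Applies the amplitude rule appropriate to each pulse of a protocol
#' (first spikes of a train vs. later spikes vs. long depolarizations), the
#' 20-sample noise rule ahead of the earliest pulse, and normalizes SNR by
#' the bleach rate. Because both SNR and bleach rate scale with illumination
#' intensity (SNR with its square root via shot noise, the rate linearly),
#' the default normalization `snr / sqrt(bleach_rate in %/s)` is invariant
#' to illumination level; `snr / rate` is selectable.
#'
#' @param trace A raw-convention dF/F [fluor_trace()].
#' @param protocol A [stim_protocol()] (times in s from trace start).
#' @param bleach_rate Bleach rate over the ROI, %/s. Non-positive values
#'   leave the corrected column NA.
#' @param convention `"sqrt_rate"` (default) or `"per_rate"`.
#' @return A tibble with one row per pulse: `stimulus`, `spike_index`,
#'   `signal_pct`, `noise_pct`, `snr`, `bleach_rate_pct_s`,
#'   `bleach_corrected_snr`, `snr_convention`, `n_trials`.
#' @export
snr_report <- function(trace, protocol, bleach_rate = NA_real_,
                       convention = c("sqrt_rate", "per_rate")) {
  convention <- match.arg(convention)
  rate <- trace_rate(trace)
  first_onset <- min(protocol$onset)
  noise <- noise_level(trace, as.integer(floor(first_onset * rate + 0.5)) + 1L)
  spike_no <- cumsum(protocol$kind == "spike") * (protocol$kind == "spike")
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    onset_frame <- as.integer(floor(protocol$onset[i] * rate + 0.5)) + 1L
    kind <- if (protocol$kind[i] == "long_depol") "long_depol"
      else if (spike_no[i] == 1L) "first_spike" else "later_spike"
    sig <- signal_amplitude(trace, onset_frame, kind,
                            duration_s = protocol$duration[i])
    tibble(stimulus = protocol$kind[i],
           spike_index = if (protocol$kind[i] == "spike") spike_no[i] else NA_integer_,
           signal_pct = sig, noise_pct = noise, snr = sig / noise)
  })
  out <- bind_rows(rows)
  corr <- if (is.na(bleach_rate) || bleach_rate <= 0) NA_real_
    else if (convention == "sqrt_rate") 1 / sqrt(bleach_rate)
    else 1 / bleach_rate
  mutate(out,
         bleach_rate_pct_s = bleach_rate,
         bleach_corrected_snr = .data$snr * corr,
         snr_convention = convention,
         n_trials = attr(trace, "n_trials") %||% 1L)
}

#' Shot-noise photon budget
#'
#' In the shot-noise limit, `SNR = (dF/F) * sqrt(n)` for `n` detected
#' photons. The forward form reports the SNR achieved with a photon count;
#' the inverse reports the photons required for a target SNR (e.g. a 1%
#' fluorescence change needs 10,000 photons for SNR 1).
#'
#' @param dff Fractional fluorescence change (> 0).
#' @param photons Photon count (forward query).
#' @param target_snr Target SNR (inverse query). Give exactly one of
#'   `photons` / `target_snr`.
#' @return SNR (forward) or required photon count (inverse).
#' @export
photon_budget <- function(dff, photons = NULL, target_snr = NULL) {
  if (is.null(photons) == is.null(target_snr))
    abort("give exactly one of `photons` or `target_snr`.")
  if (!is.null(photons)) {
    if (photons < 0) abort("`photons` must be >= 0.")
    return(dff * sqrt(photons))
  }
  if (dff <= 0) abort("`dff` must be > 0 for an inverse query (infinite budget at 0).")
  if (target_snr <= 0) abort("`target_snr` must be > 0.")
  (target_snr / dff)^2
}

#' Background-fluorescence degradation of dF/F and SNR
#'
#' Fluorescence from non-signaling structures dilutes the fractional signal
#' to `(1 - f_b) * dff0`. In a shot-noise-limited system the extra
#' background photons also raise the noise floor, degrading SNR by
#' `sqrt(1 - f_b)` (default); the linear `(1 - f_b)` convention is
#' selectable.
#'
#' @param f_b Background fraction in `[0, 1)`.
#' @param snr0 SNR without background.
#' @param dff0 dF/F without background (fraction).
#' @param snr_convention `"sqrt"` (default) or `"linear"`.
#' @return A tibble with `dff`, `snr` and the convention used.
#' @export
background_degradation <- function(f_b, snr0, dff0,
                                   snr_convention = c("sqrt", "linear")) {
  snr_convention <- match.arg(snr_convention)
  if (f_b < 0 || f_b >= 1) abort("`f_b` must be in [0, 1).")
  fac <- if (snr_convention == "sqrt") sqrt(1 - f_b) else (1 - f_b)
  tibble(dff = (1 - f_b) * dff0, snr = fac * snr0,
         snr_convention = snr_convention)
}
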