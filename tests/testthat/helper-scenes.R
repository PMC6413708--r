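# shared builders for small synthetic scenes

iou <- function(a, b) sum(a & b) / sum(a | b)
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

tiny_config <- function(..., seed = 1L) {
  defaults <- list(fov = c(48, 48), frame_rate = 100, n_frames = 60,
                   baseline_photons = 20000, bleach_rate = 0,
                   background_fraction = 0, gevi_tau = 0.02,
                   ap_amplitude = 0.002, depol_amplitude = 0.008,
                   read_noise_sd = 0, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

tiny_neuron <- function(center_px = c(24, 24), ps = 1.04, radius = 8,
                        dendrites = list(), defocus = 0.8) {
  neuron_geometry(center_px * ps, soma_radius = radius,
                  membrane_thickness = 2.5, dendrites = dendrites,
                  defocus_sigma = defocus)
}

single_pulse <- function(onset = 0.2, duration = 0.1, kind = "long_depol") {
  stim_protocol(onset, duration, kind)
}

# deterministic dF/F fluor_trace with a single AP transient, for frame-rate
# analyses: amplitude `amp` decaying with `tau`, optional iid gaussian noise
ap_trace <- function(rate = 500, n = 1500, onset_frame = 751, amp = 0.005,
                     tau = 0.012, noise_sd = 0, seed = 1) {
  tt <- (seq_len(n) - onset_frame) / rate
  v <- -amp * exp(-pmax(tt, 0) / tau) * (tt >= 0)
  if (noise_sd > 0)
    v <- v + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  fluor_trace(v, rate = rate, convention = "raw", unit = "fraction")
}
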