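raw_trace <- function(v, rate = 100)
  fluor_trace(v, rate = rate, convention = "raw", unit = "fraction")

test_that("all amplitude rules return zero on a flat trace", {
  tr <- raw_trace(rep(0, 100))
  expect_equal(signal_amplitude(tr, 41, "long_depol", duration_s = 0.1), 0)
  expect_equal(signal_amplitude(tr, 41, "first_spike"), 0)
  expect_equal(signal_amplitude(tr, 41, "later_spike"), 0)
})

test_that("a -0.59% step during a 100 ms stimulus measures 0.59%", {
  v <- rep(0, 100); v[41:50] <- -0.0059
  tr <- raw_trace(v)
  expect_equal(signal_amplitude(tr, 41, "long_depol", duration_s = 0.1),
               0.59, tolerance = 1e-9)
})

test_that("the first-spike rule recovers the attenuated AP peak", {
  # frame-integrated AP of true amplitude 0.0014/attenuation at 100 Hz
  tau <- 0.02; rate <- 100
  amp <- 0.0014 / ap_attenuation(tau, rate)
  tt0 <- (0:99) / rate  # frame starts; onset at frame 41 start
  v <- numeric(100)
  decay_avg <- function(t0) {
    tau * rate * (exp(-pmax(t0, 0) / tau) - exp(-pmax(t0 + 1 / rate, 0) / tau))
  }
  v[41:100] <- -amp * decay_avg(tt0[41:100] - tt0[41])
  expect_equal(signal_amplitude(raw_trace(v), 41, "first_spike"),
               0.14, tolerance = 1e-6)
})

test_that("later spikes use the conservative 20 ms maximum baseline", {
  v <- rep(0, 100)
  v[39:40] <- c(0.001, -0.002)   # residual of a previous transient
  v[41:45] <- -0.004
  got <- signal_amplitude(raw_trace(v), 41, "later_spike")
  expect_equal(got, 100 * (0.001 + 0.004), tolerance = 1e-9)
})

test_that("amplitude rules are invariant to constant offsets", {
  withr::with_seed(3, v <- rnorm(120, 0, 1e-3))
  tr0 <- raw_trace(v); tr1 <- raw_trace(v + 0.42)
  for (k in c("long_depol", "first_spike", "later_spike"))
    expect_equal(signal_amplitude(tr0, 61, k, duration_s = 0.1),
                 signal_amplitude(tr1, 61, k, duration_s = 0.1),
                 tolerance = 1e-9)
})

test_that("noise is the SD of exactly the 20 preceding samples", {
  expect_equal(noise_level(raw_trace(rep(0.3, 50)), 30), 0)
  expect_error(noise_level(raw_trace(rep(0, 50)), 20), "20")
  # alternating +/- c: sd = c * sqrt(20/19)
  v <- rep(c(7e-4, -7e-4), 25)
  expect_equal(noise_level(raw_trace(v), 41),
               100 * 7e-4 * sqrt(20 / 19), tolerance = 1e-9)
  # iid noise of SD 0.0007 reads 0.07% within chi-square tolerance at n=20
  got <- replicate(40, {
    v <- rnorm(60, 0, 7e-4)
    noise_level(raw_trace(v), 41)
  })
  expect_lt(abs(median(got) - 0.07), 0.35 * 0.07)
})

test_that("SNR reports combine the printed rules and conventions", {
  v <- rep(0, 120)
  withr::with_seed(8, v[1:100] <- rnorm(100, 0, 5.9e-4))
  v[101:110] <- -0.0059
  tr <- raw_trace(v)
  prot <- stim_protocol(1.0, 0.1, "long_depol")
  rep1 <- snr_report(tr, prot, bleach_rate = 1)
  expect_equal(rep1$snr, rep1$signal_pct / rep1$noise_pct, tolerance = 1e-9)
  # unit bleach rate: corrected equals raw under either convention
  expect_equal(rep1$bleach_corrected_snr, rep1$snr, tolerance = 1e-12)
  rep2 <- snr_report(tr, prot, bleach_rate = 4)
  expect_equal(rep2$bleach_corrected_snr, rep2$snr / 2, tolerance = 1e-12)
  rep3 <- snr_report(tr, prot, bleach_rate = 4, convention = "per_rate")
  expect_equal(rep3$bleach_corrected_snr, rep3$snr / 4, tolerance = 1e-12)
  expect_true(is.na(snr_report(tr, prot, bleach_rate = 0)$bleach_corrected_snr))
  # signal 0.59, noise 0.059 -> snr 10 (zero-median noise pattern so the
  # baseline median does not shift the measured amplitude)
  a <- 0.00059 * sqrt(19 / 10)
  v2 <- rep(0, 120); v2[1:100] <- rep(c(a, -a, 0, 0), 25)
  v2[101:110] <- -0.0059
  rep4 <- snr_report(raw_trace(v2), prot)
  expect_equal(rep4$snr, 10, tolerance = 0.05)
})

test_that("bleach-normalized SNR is invariant to illumination intensity", {
  run_one <- function(mult, seed) {
    cfg <- tiny_config(baseline_photons = 4000 * mult,
                       bleach_rate = 0.005 * mult, read_noise_sd = 0,
                       n_frames = 100, frame_rate = 100, seed = seed)
    prot <- stim_protocol(0.5, 0.1, "long_depol")
    sim <- simulate_movie(list(tiny_neuron()), cfg, prot)
    bl <- pixel_bleach_fit(sim$movie, nonstim_frames(prot, cfg))
    dff <- compute_dff(sim$movie, bl)
    tr <- roi_timecourse(dff, sim$truth$soma_masks[[1]])
    rate_roi <- median(bl$rate[sim$truth$soma_masks[[1]]], na.rm = TRUE)
    snr_report(tr, prot, bleach_rate = rate_roi)
  }
  lo <- dplyr::bind_rows(lapply(1:6, function(s) run_one(1, s)))
  hi <- dplyr::bind_rows(lapply(1:6, function(s) run_one(4, s + 50)))
  expect_equal(median(hi$snr) / median(lo$snr), 2, tolerance = 0.25)
  expect_equal(median(hi$bleach_corrected_snr) /
                 median(lo$bleach_corrected_snr), 1, tolerance = 0.1)
})

test_that("photon budget follows the shot-noise relation", {
  expect_equal(photon_budget(0.01, target_snr = 1), 10000)
  expect_equal(photon_budget(0.01, photons = 0), 0)
  expect_equal(photon_budget(0.01, photons = 1e6), 10)
  expect_error(photon_budget(0, target_snr = 1), "infinite")
  expect_error(photon_budget(0.01), "exactly one")
  # forward and inverse are exact mutual inverses
  withr::with_seed(2, {
    for (i in 1:20) {
      dff <- runif(1, 1e-4, 0.05); snr <- runif(1, 0.1, 50)
      expect_equal(photon_budget(dff, photons = photon_budget(dff, target_snr = snr)),
                   snr, tolerance = 1e-12)
    }
  })
})

test_that("background dilutes dF/F linearly and SNR by its square root", {
  unchanged <- background_degradation(0, snr0 = 5, dff0 = 0.01)
  expect_equal(unchanged$dff, 0.01); expect_equal(unchanged$snr, 5)
  expect_equal(background_degradation(0.75, 1, 0.01)$dff, 0.0025)
  expect_equal(background_degradation(0.75, 8, 0.01)$snr, 4)
  expect_equal(background_degradation(0.75, 8, 0.01,
                                      snr_convention = "linear")$snr, 2)
  expect_error(background_degradation(1, 1, 0.01), "f_b")
})

test_that("simulated background degrades measured SNR like sqrt(1 - f_b)", {
  # the degradation law uses the background fraction local to the measured
  # pixels; the scene's f_b is a whole-frame budget spread uniformly, so
  # the shot-noise oracle for the expected SNR ratio is built from the
  # ground-truth per-pixel photon split, and the sqrt convention must
  # describe the measurement where the linear one does not
  run_fb <- function(fb, seed) {
    cfg <- tiny_config(baseline_photons = 4000, background_fraction = fb,
                       read_noise_sd = 0, n_frames = 100, seed = seed)
    prot <- stim_protocol(0.5, 0.1, "long_depol")
    sim <- simulate_movie(list(tiny_neuron()), cfg, prot)
    bl <- pixel_bleach_fit(sim$movie, nonstim_frames(prot, cfg))
    roi <- sim$truth$soma_masks[[1]]
    tr <- roi_timecourse(compute_dff(sim$movie, bl), roi)
    s_px <- (sim$truth$brightness[[1]] * cfg$baseline_photons)[roi]
    f_px <- s_px + sim$truth$background_per_px
    list(snr = snr_report(tr, prot)$snr,
         sig = sum(s_px / f_px), noi = sqrt(sum(1 / f_px)),
         fb_local = 1 - sum(s_px) / sum(f_px))
  }
  # a whole-frame budget of 0.92 puts the fraction local to the soma near
  # 0.5 (the neuron occupies a small part of the field)
  lo <- lapply(1:8, function(s) run_fb(0, s))
  hi <- lapply(1:8, function(s) run_fb(0.92, s + 30))
  measured <- median(sapply(hi, `[[`, "snr")) / median(sapply(lo, `[[`, "snr"))
  oracle <- (hi[[1]]$sig / hi[[1]]$noi) / (lo[[1]]$sig / lo[[1]]$noi)
  expect_equal(measured, oracle, tolerance = 0.15)
  fb_local <- hi[[1]]$fb_local
  expect_lt(abs(measured - sqrt(1 - fb_local)),
            abs(measured - (1 - fb_local)))
  # and the oracle itself follows the square-root law in the local fraction
  expect_equal(oracle, sqrt(1 - fb_local), tolerance = 0.1)
})
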