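# Filtering, epoching, PSD, band integration, normalization, aggregation.

sinusoid_recording <- function(freq, rate = 256, dur = 10, amp = 1) {
  t <- (seq_len(dur * rate) - 1) / rate
  samples <- matrix(rep(amp * sin(2 * pi * freq * t), each = 15), nrow = 15)
  rownames(samples) <- eeg_montage()
  eeg_recording(samples, rate)
}

test_that("preprocessing notches 50 Hz, preserves 10 Hz, removes DC", {
  rate <- 256
  filt <- function(freq, dc = 0) {
    rec <- sinusoid_recording(freq, rate)
    if (dc != 0) rec$samples <- rec$samples + dc
    eeg_preprocess(rec)$samples["Cz", ]
  }
  raw50 <- sinusoid_recording(50, rate)$samples["Cz", ]
  atten_db <- 10 * log10(mean(filt(50)^2) / mean(raw50^2))
  expect_lt(atten_db, -20)
  expect_equal(sd(filt(10)), sd(sinusoid_recording(10, rate)$samples["Cz", ]),
               tolerance = 0.05)
  expect_lt(abs(mean(filt(10, dc = 100))), 1)
  # rate guard
  lowrate <- eeg_recording(matrix(0, 15, 100,
                                  dimnames = list(eeg_montage(), NULL)), 100)
  expect_error(eeg_preprocess(lowrate), class = "dyadsync_input_error")
})

test_that("epoching yields the arithmetic count and applies rejection rules", {
  cfg <- sim_config(seed = 2, baseline_s = 120, phase_s = 10,
                    cluster_spec = NULL)
  rec <- simulate_eeg_member(cfg)
  ep <- eeg_epochs(rec, phase_annotations(cfg))
  expect_equal(sum(ep$phase == "BL"), 60)
  expect_equal(sum(ep$phase == "IP"), 5)
  expect_true(all(ep$kept))  # clean synthetic input: zero rejections

  # one spiked epoch is rejected, others kept
  rec2 <- rec
  spike_at <- round(3.5 * cfg$eeg_rate)
  rec2$samples["Cz", spike_at] <- 500
  ep2 <- eeg_epochs(rec2, phase_annotations(cfg), amp_thresh_uV = 100)
  expect_identical(ep2$kept, ep2$epoch != 2 | ep2$phase != "BL")
  expect_equal(ep2$reason[ep2$phase == "BL" & ep2$epoch == 2], "amplitude")

  # flat channel: everything rejected -> error naming the phase
  flat <- eeg_recording(matrix(0, 15, 120 * 256,
                               dimnames = list(eeg_montage(), NULL)), 256)
  expect_error(
    eeg_epochs(flat, tibble::tibble(label = "BL", start_s = 0, end_s = 120)),
    "BL", class = "dyadsync_artifact_error")
})

test_that("PSD bins are 0.5 Hz apart and sinusoid power integrates to A^2/2", {
  for (rate in c(256, 1000)) {
    rec <- sinusoid_recording(10, rate, dur = 10)
    ep <- eeg_epochs(rec, tibble::tibble(label = "BL", start_s = 0, end_s = 10),
                     amp_thresh_uV = 1000)
    psd <- eeg_psd(ep)
    freqs <- sort(unique(psd$freq))
    expect_equal(unique(round(diff(freqs), 9)), 0.5)
    alpha <- band_power(psd) |>
      dplyr::filter(band == "alpha", channel == "Cz")
    expect_equal(alpha$power, 0.5, tolerance = 0.05)
  }
  # zero signal -> all-zero PSD (flat epochs are normally rejected; bypass)
  zero <- eeg_recording(matrix(0, 15, 512, dimnames = list(eeg_montage(), NULL)), 256)
  ep0 <- eeg_epochs(zero, tibble::tibble(label = "BL", start_s = 0, end_s = 2),
                    flat_range_uV = -1)
  expect_true(all(eeg_psd(ep0)$psd == 0))
})

test_that("band integration localizes power and respects flat spectra", {
  rec <- sinusoid_recording(2, 256, dur = 10)
  ep <- eeg_epochs(rec, tibble::tibble(label = "BL", start_s = 0, end_s = 10),
                   amp_thresh_uV = 1000)
  psd <- eeg_psd(ep)
  bp <- band_power(psd) |> dplyr::filter(channel == "Cz")
  tot <- sum(dplyr::filter(psd, channel == "Cz")$psd)
  expect_gt(bp$power[bp$band == "delta"] / tot, 0.95)
  # white noise: band power proportional to bandwidth
  set.seed(7)
  wn <- eeg_recording(matrix(rnorm(15 * 2560), 15,
                             dimnames = list(eeg_montage(), NULL)), 256)
  epw <- eeg_epochs(wn, tibble::tibble(label = "BL", start_s = 0, end_s = 10),
                    amp_thresh_uV = 100)
  bpw <- band_power(eeg_psd(epw)) |>
    dplyr::summarise(power = mean(power), .by = band)
  widths <- eeg_bands()$hi - eeg_bands()$lo + 0.5  # inclusive bins
  dens <- bpw$power / widths
  expect_equal(max(dens) / min(dens), 1, tolerance = 0.25)
  # bands outside the sampled spectrum are an error
  expect_error(band_power(dplyr::filter(psd, freq < 20),
                          tibble::tibble(band = "gamma", lo = 30.5, hi = 50)),
               class = "dyadsync_input_error")
})

test_that("baseline normalization follows (task - BL)/BL with guards", {
  expect_equal(normalize_to_baseline(3, 2), 0.5)
  expect_equal(normalize_to_baseline(2, 2), 0)
  expect_error(normalize_to_baseline(1, 0), class = "dyadsync_input_error")
  expect_error(normalize_to_baseline(1, -1), class = "dyadsync_input_error")
})

test_that("normalized band power is invariant to a common gain", {
  cfg <- quick_config(seed = 13)
  rec <- simulate_eeg_member(cfg)
  ph <- phase_annotations(cfg)
  # a generous artifact threshold keeps the retained-epoch sets identical,
  # which the invariance presumes
  bp1 <- compute_band_power(rec, ph, amp_thresh_uV = 1e6)
  rec_scaled <- rec
  rec_scaled$samples <- rec$samples * 3.7
  bp2 <- compute_band_power(rec_scaled, ph, amp_thresh_uV = 1e6)
  expect_equal(bp1$normalized, bp2$normalized, tolerance = 1e-10)
  expect_equal(bp2$psd_task, bp1$psd_task * 3.7^2, tolerance = 1e-8)
})

test_that("Parseval: integrated PSD matches time-domain variance", {
  cfg <- quick_config(seed = 4)
  rec <- eeg_preprocess(simulate_eeg_member(cfg))
  ep <- eeg_epochs(rec, phase_annotations(cfg))
  psd <- eeg_psd(ep)
  tot_psd <- sum(dplyr::filter(psd, channel == "Pz", phase == "BL")$psd)
  bl <- rec$samples["Pz", 1:(20 * cfg$eeg_rate)]
  expect_equal(tot_psd, var(bl), tolerance = 0.1)
  # band partition: five bands never exceed the total integrated power
  bands_tot <- sum(band_power(psd) |>
                     dplyr::filter(channel == "Pz", phase == "BL") |>
                     dplyr::pull(power))
  expect_lte(bands_tot, tot_psd + 1e-9)
})

test_that("ROI aggregation averages the right electrodes", {
  cfg <- quick_config(seed = 6)
  bp <- compute_band_power(simulate_eeg_member(cfg), phase_annotations(cfg))
  agg <- aggregate_band_power(bp)
  left_f <- dplyr::filter(agg, roi == "ROI-F", hemisphere == "left",
                          band == "alpha", phase == "IP")
  manual <- bp |>
    dplyr::filter(electrode %in% c("Fp1", "F3"), band == "alpha",
                  phase == "IP")
  expect_equal(left_f$normalized, mean(manual$normalized))
  expect_equal(unique(dplyr::filter(agg, hemisphere != "both")$n_electrodes), 2L)
  expect_equal(unique(dplyr::filter(agg, hemisphere == "both")$n_electrodes), 4L)
  # constant input: every aggregate equals that constant
  bp_const <- bp |> dplyr::mutate(normalized = 0.25)
  expect_true(all(aggregate_band_power(bp_const)$normalized == 0.25))
  # missing electrode is an informative error
  expect_error(aggregate_band_power(dplyr::filter(bp, electrode != "F3")),
               "F3", class = "dyadsync_input_error")
})
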