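# Synthetic dyad generator: determinism, montage, oscillator scaling, beat
# series, pulse rendering, electrodermal events, cohort structure.

test_that("EEG simulation is deterministic, labelled, and respects coupling limits", {
  cfg <- quick_config(seed = 11)
  r1 <- simulate_eeg_member(cfg, member = 1)
  r1b <- simulate_eeg_member(cfg, member = 1)
  expect_identical(r1$samples, r1b$samples)
  expect_identical(rownames(r1$samples), eeg_montage())
  expect_equal(ncol(r1$samples), round(50 * cfg$eeg_rate))

  # coupling 1, zero noise: members are bit-identical
  cfg1 <- quick_config(seed = 5, coupling = 1, noise_uV = 0)
  m1 <- simulate_eeg_member(cfg1, member = 1)
  m2 <- simulate_eeg_member(cfg1, member = 2)
  expect_identical(m1$samples, m2$samples)

  # different members differ when coupling < 1
  cfg0 <- quick_config(seed = 5, coupling = 0)
  expect_gt(max(abs(simulate_eeg_member(cfg0, 1)$samples -
                    simulate_eeg_member(cfg0, 2)$samples)), 1)
})

test_that("configuration validation rejects bad parameters", {
  expect_error(quick_config(band_amp_uV = c(sigma = 1)), class = "dyadsync_config_error")
  expect_error(quick_config(coupling = 1.5), class = "dyadsync_config_error")
  expect_error(quick_config(hrv_similarity = 2), class = "dyadsync_config_error")
  expect_error(quick_config(eeg_rate = -1), class = "dyadsync_config_error")
  expect_error(
    sim_config(n_dyads = 5, cluster_spec = default_cluster_spec(c(10, 3))),
    class = "dyadsync_config_error")
})

test_that("uncoupled members have uncorrelated band power across dyads", {
  # Monte-Carlo: at coupling 0, per-dyad alpha power of member 1 and member 2
  # over many dyads is uncorrelated
  cfg <- sim_config(seed = 21, baseline_s = 6, phase_s = 2,
                    cluster_spec = NULL, coupling = 0, noise_uV = 0,
                    band_amp_uV = c(alpha = 10), band_center_hz = c(alpha = 10))
  # oscillator streams are variance-normalized per session, so compare
  # power over a 2-s sub-window, where realizations genuinely fluctuate
  win <- seq_len(2 * cfg$eeg_rate)
  pow <- sapply(1:60, function(d) {
    sapply(1:2, function(m) {
      rec <- simulate_eeg_member(cfg, member = m, dyad = d)
      mean(rec$samples["Cz", win]^2)
    })
  })
  expect_lt(abs(cor(pow[1, ], pow[2, ])), 0.3)
})

test_that("a 1 uV 10 Hz oscillator recovers ~0.5 uV^2 of alpha power", {
  cfg <- sim_config(seed = 3, baseline_s = 120, phase_s = 2,
                    cluster_spec = NULL, noise_uV = 0, coupling = 0,
                    band_amp_uV = c(alpha = 1), band_center_hz = c(alpha = 10))
  rec <- simulate_eeg_member(cfg)
  ep <- eeg_epochs(rec, phase_annotations(cfg), amp_thresh_uV = 1000)
  bp <- band_power(eeg_psd(ep))
  alpha_bl <- dplyr::filter(bp, band == "alpha", phase == "BL")$power
  expect_equal(mean(alpha_bl), 0.5, tolerance = 0.1)
})

test_that("IBI series meet their contracts", {
  expect_true(all(simulate_ibi(800, 0, 30, seed = 1) == 800))
  # count oracle: 60-s span at 1000 ms
  counts <- sapply(1:20, function(s) length(simulate_ibi(1000, 40, 60, seed = s)))
  expect_true(all(counts >= 58 & counts <= 62))
  # RMSSD recovery in expectation (~300 beats)
  est <- sapply(1:50, function(s) {
    ibi <- simulate_ibi(800, 40, 240, seed = s)
    sqrt(mean(diff(ibi)^2))
  })
  expect_equal(mean(est), 40, tolerance = 0.15)
  # guards
  expect_error(simulate_ibi(100, 10, 10), class = "dyadsync_config_error")
  expect_error(simulate_ibi(800, -1, 10), class = "dyadsync_config_error")
  expect_error(simulate_ibi(800, 500, 10), class = "dyadsync_config_error")
})

test_that("BVP rendering produces one resolvable pulse per beat", {
  one <- render_bvp(800, 100)
  above <- one$value > 0.5
  # exactly one contiguous run above half amplitude
  expect_equal(sum(rle(above)$values), 1)
  expect_error(render_bvp(numeric(0)), class = "dyadsync_input_error")
  expect_error(render_bvp(rep(800, 5), bvp_rate = 10),
               class = "dyadsync_config_error")
})

test_that("SCL simulation covers duration, events and degenerate cases", {
  scl <- simulate_scl(120, 40, tonic_drift = 0, scr_rate_per_min = 0,
                      seed = 1, noise = 0)
  expect_equal(nrow(scl), 4800)
  expect_equal(diff(range(scl$value)), 0)
  expect_error(simulate_scl(60, scr_rate_per_min = -1),
               class = "dyadsync_config_error")
})

test_that("cohorts carry ground truth consistent with their cluster spec", {
  cs <- default_cluster_spec(c(3, 2))
  cfg <- sim_config(seed = 9, n_dyads = 5, baseline_s = 8, phase_s = 4,
                    cluster_spec = cs)
  coh <- simulate_cohort(cfg)
  expect_length(coh$sessions, 5)
  expect_equal(nrow(coh$ground_truth), 5)
  expect_equal(sort(table(coh$ground_truth$cluster)), sort(c(`1` = 3, `2` = 2)),
               ignore_attr = TRUE)
  expect_true(all(c("delta_IP", "delta_NCP", "delta_RP") %in%
                  names(coh$ground_truth)))
  # questionnaire: both members, BAS-RR present
  expect_equal(nrow(coh$questionnaire), 5 * 2 * 7)
  # one dyad per cluster is refused
  expect_error(simulate_hrv_features(default_cluster_spec(c(1, 1))),
               class = "dyadsync_config_error")
  # determinism of the whole cohort
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$ground_truth, coh2$ground_truth)
  expect_identical(coh$sessions[[3]]$members[[2]]$eeg$samples,
                   coh2$sessions[[3]]$members[[2]]$eeg$samples)
})

test_that("identical-mean clusters give chance-level recovery", {
  cs <- default_cluster_spec(c(6, 7))
  cs$IP <- 0; cs$NCP <- 0; cs$RP <- 0
  aris <- sapply(1:30, function(s) {
    f <- simulate_hrv_features(cs, seed = s)
    km <- kmeans_hw(standardize_features(f), 2, seed = s)
    adjusted_rand_index(km$labels, f$cluster)
  })
  expect_lt(abs(mean(aris)), 0.15)
})
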