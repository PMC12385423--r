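# Small configurations used across tests: short sessions keep the suite fast
# while preserving the analysis geometry (2-s epochs, all phases present).

quick_config <- function(seed = 1, ...) {
  sim_config(seed = seed, baseline_s = 20, phase_s = 10,
             cluster_spec = NULL, ...)
}

# per-member per-phase RMSSD estimated straight from simulated beat series,
# bypassing waveform rendering (used for ANOVA calibration suites)
simulated_hrv_table <- function(rep_seed, n_dyads = 13, rmssd = 40,
                                phase_s = 60) {
  rows <- purrr::map(seq_len(n_dyads), function(d) {
    vals <- sapply(1:2, function(m) {
      sapply(c("BL", "IP", "NCP", "RP"), function(ph) {
        ibi <- simulate_ibi(800, rmssd, phase_s,
                            seed = dyadsync:::substream_seed(rep_seed, d, m, ph))
        sqrt(mean(diff(ibi)^2))
      })
    })
    norm <- (vals[2:4, ] - rep(vals[1, ], each = 3)) / rep(vals[1, ], each = 3)
    tibble::tibble(dyad = d, phase = c("IP", "NCP", "RP"),
                   eudist = abs(norm[, 1] - norm[, 2]))
  })
  purrr::list_rbind(rows)
}

# mean EEG synchrony of one dyad at a given coupling (reduced-duration world)
dyad_mean_eudist <- function(coupling, seed, baseline_s = 30, phase_s = 20) {
  cfg <- sim_config(seed = seed, baseline_s = baseline_s, phase_s = phase_s,
                    cluster_spec = NULL, coupling = coupling)
  ses <- simulate_dyad(cfg, dyad = 1)
  bp <- lapply(1:2, function(m) {
    compute_band_power(ses$members[[m]]$eeg, ses$phases)
  })
  mean(eeg_synchrony(bp[[1]], bp[[2]])$eudist)
}
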