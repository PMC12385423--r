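# Synthetic dyad generator: band-limited oscillatory EEG with controllable
# inter-member coupling, AR(1) beat-interval series with controllable RMSSD,
# pulse-wave rendering, tonic + phasic electrodermal activity, and a cohort
# builder with a known two-cluster HRV-synchrony structure.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic dyad generator. Defaults encode
#' the recording setup the pipeline is built for: a 120-s resting baseline
#' followed by three ~60-s negotiation phases (IP, NCP, RP), electrodermal
#' activity sampled at 40 Hz and photoplethysmography at 100 Hz. EEG is
#' generated at a desk-scale 256 Hz by default (1000 Hz is supported); the
#' 0.5 Hz spectral resolution of the analysis comes from the 2-s epoch length
#' and is rate-independent.
#'
#' @param seed Master integer seed. All randomness flows from it through
#'   named substreams, so identical configurations reproduce bit-identical
#'   cohorts.
#' @param n_dyads Number of dyads in a cohort. Must equal the sum of
#'   `cluster_spec$n_dyads`.
#' @param eeg_rate,scl_rate,bvp_rate Sampling rates in Hz.
#' @param baseline_s,phase_s Durations (seconds) of the resting baseline and
#'   of each task phase.
#' @param band_amp_uV Named vector, sinusoid-equivalent oscillator amplitude
#'   per band (microvolt); band power contributed is `amp^2 / 2`.
#' @param band_center_hz Named vector, oscillator center frequency per band.
#' @param band_bw_hz Bandwidth (Hz) of the band-limited oscillator noise.
#' @param noise_uV Standard deviation of the pink (1/f) background noise.
#' @param coupling Fraction in `[0, 1]` of shared oscillatory source between
#'   the two members: a scalar, a named per-band vector, or a band x ROI
#'   matrix (rows named by band, columns `ROI-F`, `ROI-TC`, `ROI-PO`).
#' @param mean_ibi_ms Mean inter-beat interval (ms), in `[300, 2000]`.
#' @param rmssd_ms Target RMSSD (ms) of the beat series at baseline.
#' @param hrv_similarity Value in `[0, 1]`; when no `cluster_spec` drives a
#'   dyad, the target inter-member HRV divergence per phase is
#'   `(1 - hrv_similarity) * 0.8` on the baseline-normalized scale.
#' @param scl_level_uS,scl_drift_uS_min,scl_noise_uS Tonic skin conductance
#'   level (microsiemens), linear drift per minute, and slow tonic noise sd.
#' @param scr_rate_per_min Poisson rate of phasic skin conductance responses.
#' @param scr_amp_uS Median SCR amplitude (microsiemens).
#' @param cluster_spec Tibble describing the cohort's latent HRV-synchrony
#'   clusters; see [default_cluster_spec()]. Set to `NULL` to generate a
#'   homogeneous cohort driven by `hrv_similarity`.
#' @param eudist_base,eudist_scale Affine map from a cluster's latent
#'   (z-scaled) HRV-synchrony feature to the raw target divergence between
#'   members' baseline-normalized RMSSD, `delta = base + scale * z`.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_dyads = 4,
#'                   cluster_spec = default_cluster_spec(c(2, 2)))
sim_config <- function(seed = 1L,
                       n_dyads = 13,
                       eeg_rate = 256,
                       scl_rate = 40,
                       bvp_rate = 100,
                       baseline_s = 120,
                       phase_s = 60,
                       band_amp_uV = c(delta = 8, theta = 5, alpha = 10,
                                       beta = 3, gamma = 1.5),
                       band_center_hz = c(delta = 2, theta = 6, alpha = 10,
                                          beta = 20, gamma = 40),
                       band_bw_hz = 2,
                       noise_uV = 2,
                       coupling = 0.5,
                       mean_ibi_ms = 800,
                       rmssd_ms = 40,
                       hrv_similarity = 0.5,
                       scl_level_uS = 5,
                       scl_drift_uS_min = 0.05,
                       scl_noise_uS = 0.01,
                       scr_rate_per_min = 3,
                       scr_amp_uS = 0.3,
                       cluster_spec = default_cluster_spec(),
                       eudist_base = 0.5,
                       eudist_scale = 0.15) {
  cfg <- list(seed = as.integer(seed), n_dyads = n_dyads,
              eeg_rate = eeg_rate, scl_rate = scl_rate, bvp_rate = bvp_rate,
              baseline_s = baseline_s, phase_s = phase_s,
              band_amp_uV = band_amp_uV, band_center_hz = band_center_hz,
              band_bw_hz = band_bw_hz, noise_uV = noise_uV,
              coupling = coupling, mean_ibi_ms = mean_ibi_ms,
              rmssd_ms = rmssd_ms, hrv_similarity = hrv_similarity,
              scl_level_uS = scl_level_uS,
              scl_drift_uS_min = scl_drift_uS_min,
              scl_noise_uS = scl_noise_uS,
              scr_rate_per_min = scr_rate_per_min, scr_amp_uS = scr_amp_uS,
              cluster_spec = cluster_spec,
              eudist_base = eudist_base, eudist_scale = eudist_scale)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  err <- function(msg) abort(msg, class = "dyadsync_config_error")
  rates <- c(cfg$eeg_rate, cfg$scl_rate, cfg$bvp_rate)
  if (any(!is.finite(rates)) || any(rates <= 0)) err("all rates must be > 0")
  if (cfg$baseline_s <= 0 || cfg$phase_s <= 0) {
    err("baseline_s and phase_s must be > 0")
  }
  bad <- setdiff(names(cfg$band_amp_uV), band_levels())
  if (length(bad)) err(paste0("unknown band in band_amp_uV: ",
                              paste(bad, collapse = ", ")))
  bad <- setdiff(names(cfg$band_center_hz), band_levels())
  if (length(bad)) err(paste0("unknown band in band_center_hz: ",
                              paste(bad, collapse = ", ")))
  cp <- cfg$coupling
  if (any(cp < 0 | cp > 1)) err("coupling must lie in [0, 1]")
  if (is.matrix(cp)) {
    if (!all(rownames(cp) %in% band_levels())) {
      err("coupling matrix rows must be named by band")
    }
    if (!all(colnames(cp) %in% roi_levels())) {
      err("coupling matrix columns must be named by ROI")
    }
  } else if (!is.null(names(cp)) &&
             !all(names(cp) %in% band_levels())) {
    err("named coupling vector must use band names")
  }
  if (cfg$hrv_similarity < 0 || cfg$hrv_similarity > 1) {
    err("hrv_similarity must lie in [0, 1]")
  }
  if (cfg$mean_ibi_ms < 300 || cfg$mean_ibi_ms > 2000) {
    err("mean_ibi_ms must lie in [300, 2000]")
  }
  if (cfg$rmssd_ms < 0) err("rmssd_ms must be >= 0")
  if (cfg$scr_rate_per_min < 0) err("scr_rate_per_min must be >= 0")
  if (!is.null(cfg$cluster_spec)) {
    cs <- cfg$cluster_spec
    needed <- c("cluster", "n_dyads", "IP", "NCP", "RP", "sd",
                "bas_rr_mean", "bas_rr_sd")
    miss <- setdiff(needed, names(cs))
    if (length(miss)) err(paste0("cluster_spec lacks columns: ",
                                 paste(miss, collapse = ", ")))
    if (sum(cs$n_dyads) != cfg$n_dyads) {
      err("cluster_spec n_dyads must sum to n_dyads")
    }
    if (cfg$n_dyads < 2 * nrow(cs)) {
      err("need at least 2 dyads per requested cluster")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Default two-cluster HRV-synchrony cohort structure
#'
#' A 13-dyad cohort split into two latent clusters of phase-wise
#' HRV-synchrony profiles (on the standardized feature scale): a larger
#' low-divergence cluster (n = 10; IP -0.440, NCP -0.380, RP -0.301) with
#' higher reward responsiveness, and a smaller high-divergence cluster
#' (n = 3; IP 1.468, NCP 1.268, RP 1.002) with lower reward responsiveness.
#' Feature noise sd defaults to 0.3 per phase.
#'
#' @param n_dyads Length-2 integer vector of cluster sizes.
#' @param sd Within-cluster feature standard deviation.
#' @return Tibble with one row per cluster.
#' @export
default_cluster_spec <- function(n_dyads = c(10, 3), sd = 0.3) {
  tibble(
    cluster = seq_along(n_dyads),
    n_dyads = n_dyads,
    IP  = c(-0.440, 1.468)[seq_along(n_dyads)],
    NCP = c(-0.380, 1.268)[seq_along(n_dyads)],
    RP  = c(-0.301, 1.002)[seq_along(n_dyads)],
    sd = sd,
    # BIS/BAS subscales are item means on a 1-4 scale; the low-divergence
    # cluster carries the higher reward-responsiveness scores.
    bas_rr_mean = c(3.5, 2.9)[seq_along(n_dyads)],
    bas_rr_sd = 0.25
  )
}

#' Phase annotation table for a simulated session
#'
#' Half-open `[start_s, end_s)` intervals: baseline `BL` then the three task
#' phases `IP`, `NCP`, `RP`.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `label`, `start_s`, `end_s`.
#' @export
phase_annotations <- function(config) {
  starts <- config$baseline_s + config$phase_s * 0:2
  tibble(
    label = phase_factor(phase_levels()),
    start_s = c(0, starts),
    end_s = c(config$baseline_s, starts + config$phase_s)
  )
}

session_duration_s <- function(config) config$baseline_s + 3 * config$phase_s

# coupling value for one band x channel
coupling_for <- function(config, band, channel) {
  cp <- config$coupling
  if (is.matrix(cp)) {
    unname(cp[band, sim_roi_of_channel(channel)])
  } else if (!is.null(names(cp))) {
    unname(cp[[band]])
  } else {
    cp
  }
}

#' Construct an EEG recording object
#'
#' @param samples Numeric matrix, channels x time, in microvolts; row names
#'   are electrode labels.
#' @param rate Sampling rate in Hz.
#' @param member Member index (1 or 2).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, member = 1L) {
  if (is.null(rownames(samples))) {
    abort("samples must carry electrode labels as row names",
          class = "dyadsync_input_error")
  }
  miss <- setdiff(eeg_montage(), rownames(samples))
  if (length(miss)) {
    abort(paste0("missing montage channels: ", paste(miss, collapse = ", ")),
          class = "dyadsync_input_error")
  }
  structure(list(samples = samples[eeg_montage(), , drop = FALSE],
                 rate = rate, member = as.integer(member),
                 channels = eeg_montage()),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> member %d: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$member, nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  invisible(x)
}

#' Simulate one member's EEG
#'
#' Each channel is a sum over bands of
#' `amplitude * (coupling * shared + (1 - coupling) * private)` band-limited
#' oscillators plus pink (1/f) background noise, covering baseline plus the
#' three task phases. The shared oscillator stream is common to both members
#' of a dyad, so `coupling = 1` with zero noise makes the members identical,
#' while `coupling = 0` makes their oscillatory activity independent.
#' Oscillators have unit-sinusoid scaling: a band of amplitude A contributes
#' band power A^2/2 (microvolt squared) at coupling 0 or 1.
#'
#' @param config A [sim_config()].
#' @param member Member index (1 or 2).
#' @param dyad Dyad index; selects the shared-source substream.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, baseline_s = 4, phase_s = 2, cluster_spec = NULL)
#' rec <- simulate_eeg_member(cfg, member = 1)
simulate_eeg_member <- function(config, member = 1L, dyad = 1L) {
  n <- round(session_duration_s(config) * config$eeg_rate)
  bands <- intersect(band_levels(), names(config$band_amp_uV))
  channels <- eeg_montage()
  samples <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  for (ch in channels) {
    sig <- numeric(n)
    for (b in bands) {
      amp <- config$band_amp_uV[[b]]
      ctr <- config$band_center_hz[[b]]
      cp <- coupling_for(config, b, ch)
      shared <- with_substream(
        config$seed, "dyad", dyad, "eeg-shared", b, ch,
        code = narrowband_noise(n, config$eeg_rate, ctr, config$band_bw_hz))
      private <- with_substream(
        config$seed, "dyad", dyad, "member", member, "eeg-private", b, ch,
        code = narrowband_noise(n, config$eeg_rate, ctr, config$band_bw_hz))
      sig <- sig + (amp / sqrt(2)) * (cp * shared + (1 - cp) * private)
    }
    if (config$noise_uV > 0) {
      sig <- sig + config$noise_uV * with_substream(
        config$seed, "dyad", dyad, "member", member, "eeg-noise", ch,
        code = pink_noise(n, config$eeg_rate))
    }
    samples[ch, ] <- sig
  }
  eeg_recording(samples, config$eeg_rate, member)
}

#' Simulate an inter-beat-interval series
#'
#' First-order autoregressive Gaussian IBI stream (lag-1 coefficient `phi`)
#' scaled so the expected sample RMSSD equals `rmssd_ms`; the cumulative sum
#' of intervals covers at least `duration_s`.
#'
#' @param mean_ibi_ms Mean interval, ms, in `[300, 2000]`.
#' @param rmssd_ms Target RMSSD, ms; must be `>= 0` and at most
#'   `mean_ibi_ms / 2` (larger values are physiologically implausible).
#' @param duration_s Time span the beat series must cover.
#' @param seed Optional integer seed (the stream is drawn from the current
#'   RNG state when `NULL`).
#' @param phi AR(1) coefficient of successive intervals.
#' @return Numeric vector of intervals in ms.
#' @export
#' @examples
#' ibi <- simulate_ibi(1000, 40, 60, seed = 1)
simulate_ibi <- function(mean_ibi_ms, rmssd_ms, duration_s,
                         seed = NULL, phi = 0.4) {
  if (mean_ibi_ms < 300 || mean_ibi_ms > 2000) {
    abort("mean_ibi_ms must lie in [300, 2000]",
          class = "dyadsync_config_error")
  }
  if (rmssd_ms < 0) {
    abort("rmssd_ms must be >= 0", class = "dyadsync_config_error")
  }
  if (rmssd_ms > mean_ibi_ms / 2) {
    abort("rmssd_ms above mean_ibi_ms / 2 is physiologically implausible",
          class = "dyadsync_config_error")
  }
  gen <- function() {
    n <- ceiling(duration_s * 1000 / mean_ibi_ms * 1.5) + 20
    if (rmssd_ms == 0) {
      ibi <- rep(mean_ibi_ms, n)
    } else {
      # marginal sd sigma with Var(diff) = 2 sigma^2 (1 - phi) = rmssd^2
      sigma <- rmssd_ms / sqrt(2 * (1 - phi))
      innov_sd <- sigma * sqrt(1 - phi^2)
      e <- rnorm(n, 0, innov_sd)
      x <- as.numeric(stats::filter(e, phi, method = "recursive",
                                    init = rnorm(1, 0, sigma)))
      ibi <- pmax(mean_ibi_ms + x, 0.3 * mean_ibi_ms)
    }
    keep <- which(cumsum(ibi) >= duration_s * 1000)
    if (!length(keep)) ibi else ibi[seq_len(keep[1])]
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Render a blood-volume-pulse waveform from beat intervals
#'
#' Places one stereotyped pulse (a raised-cosine systolic peak) at each
#' cumulative beat time and samples the sum on a regular grid.
#'
#' @param ibi Numeric vector of inter-beat intervals in ms (non-empty).
#' @param bvp_rate Sampling rate in Hz; must be at least 20 Hz to resolve
#'   individual pulses.
#' @param pulse_width_s Full width of the raised-cosine pulse.
#' @param amplitude Peak amplitude (arbitrary units).
#' @return Tibble with columns `time_s` and `value`.
#' @export
#' @examples
#' bvp <- render_bvp(rep(800, 10), 100)
render_bvp <- function(ibi, bvp_rate = 100, pulse_width_s = 0.35,
                       amplitude = 1) {
  if (!length(ibi)) {
    abort("ibi must be non-empty", class = "dyadsync_input_error")
  }
  if (bvp_rate < 20) {
    abort("bvp_rate below 20 Hz cannot resolve individual pulses",
          class = "dyadsync_config_error")
  }
  check_finite(ibi, "ibi")
  beat_t <- cumsum(ibi) / 1000
  dur <- beat_t[length(beat_t)] + pulse_width_s
  t <- seq(0, dur, by = 1 / bvp_rate)
  value <- numeric(length(t))
  half <- pulse_width_s / 2
  for (bt in beat_t) {
    i0 <- max(1L, ceiling((bt - half) * bvp_rate) + 1L)
    i1 <- min(length(t), floor((bt + half) * bvp_rate) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    value[idx] <- value[idx] +
      amplitude * 0.5 * (1 + cos(pi * (t[idx] - bt) / half))
  }
  tibble(time_s = t, value = value)
}

#' Simulate a skin conductance level series
#'
#' Slow tonic component (level + linear drift + smoothed noise) with
#' superposed phasic skin conductance responses at Poisson event times; each
#' response has a fast rise and exponential decay and positive amplitude.
#'
#' @param duration_s Duration in seconds.
#' @param scl_rate Sampling rate in Hz.
#' @param tonic_drift Linear drift in microsiemens per minute.
#' @param scr_rate_per_min Poisson rate of phasic responses (`>= 0`).
#' @param seed Optional integer seed.
#' @param level Tonic level in microsiemens.
#' @param scr_amp Median response amplitude in microsiemens.
#' @param noise Tonic noise sd in microsiemens (0 for a deterministic tonic).
#' @param scr_times_s Optional vector of event onset times overriding the
#'   Poisson draw (used for round-trip tests).
#' @return Tibble with columns `time_s`, `value`; the ground-truth event
#'   onsets and amplitudes are attached as attributes `scr_times_s` and
#'   `scr_amps_uS`.
#' @export
#' @examples
#' scl <- simulate_scl(120, 40, scr_rate_per_min = 3, seed = 1)
simulate_scl <- function(duration_s, scl_rate = 40, tonic_drift = 0.05,
                         scr_rate_per_min = 3, seed = NULL, level = 5,
                         scr_amp = 0.3, noise = 0.01, scr_times_s = NULL) {
  if (scr_rate_per_min < 0) {
    abort("scr_rate_per_min must be >= 0", class = "dyadsync_config_error")
  }
  gen <- function() {
    n <- round(duration_s * scl_rate)
    t <- (seq_len(n) - 1) / scl_rate
    tonic <- level + tonic_drift * t / 60
    if (noise > 0) {
      w <- max(1L, round(10 * scl_rate))  # ~10-s smoothing of a random walk
      rw <- cumsum(rnorm(n))
      sm <- stats::filter(rw, rep(1 / w, w), sides = 2)
      sm[is.na(sm)] <- mean(sm, na.rm = TRUE)
      sm <- as.numeric(sm)
      s <- sd(sm)
      if (s > 0) tonic <- tonic + noise * (sm - mean(sm)) / s
    }
    if (is.null(scr_times_s)) {
      n_ev <- rpois(1, scr_rate_per_min * duration_s / 60)
      ev_t <- sort(runif(n_ev, 0, max(duration_s - 5, 0)))
    } else {
      ev_t <- sort(scr_times_s)
    }
    ev_a <- if (length(ev_t)) rlnorm(length(ev_t), log(scr_amp), 0.3) else numeric(0)
    value <- tonic
    tau_rise <- 0.75
    tau_decay <- 3
    for (i in seq_along(ev_t)) {
      rel <- t - ev_t[i]
      sel <- rel >= 0 & rel < 20
      shape <- exp(-rel[sel] / tau_decay) - exp(-rel[sel] / tau_rise)
      peak <- max(shape)
      if (peak > 0) value[sel] <- value[sel] + ev_a[i] * shape / peak
    }
    out <- tibble(time_s = t, value = value)
    attr(out, "scr_times_s") <- ev_t
    attr(out, "scr_amps_uS") <- ev_a
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Draw a cohort's latent HRV-synchrony features
#'
#' Generates, per dyad, the phase-wise HRV-synchrony feature triple
#' (IP, NCP, RP) on the standardized scale from the cluster structure in
#' `cluster_spec`, plus a per-dyad reward-responsiveness (BAS-RR) score.
#' These latent features are the ground truth that [simulate_dyad()] turns
#' into member-level RMSSD targets and that the cluster-recovery tests score
#' against.
#'
#' @param cluster_spec See [default_cluster_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `dyad`, `cluster`, `IP`, `NCP`, `RP`,
#'   `bas_rr`.
#' @export
#' @examples
#' simulate_hrv_features(default_cluster_spec(), seed = 1)
simulate_hrv_features <- function(cluster_spec = default_cluster_spec(),
                                  seed = 1L) {
  cs <- cluster_spec
  n_total <- sum(cs$n_dyads)
  if (n_total < 2 * nrow(cs)) {
    abort("need at least 2 dyads per requested cluster",
          class = "dyadsync_config_error")
  }
  withr::with_seed(as.integer(seed), {
    rows <- purrr::pmap(cs, function(cluster, n_dyads, IP, NCP, RP, sd,
                                     bas_rr_mean, bas_rr_sd) {
      tibble(
        cluster = cluster,
        IP  = rnorm(n_dyads, IP, sd),
        NCP = rnorm(n_dyads, NCP, sd),
        RP  = rnorm(n_dyads, RP, sd),
        bas_rr = rnorm(n_dyads, bas_rr_mean, bas_rr_sd)
      )
    })
    out <- purrr::list_rbind(rows)
    out$dyad <- seq_len(nrow(out))
    dplyr::relocate(out, "dyad")
  })
}

#' Simulate one dyadic hyperscanning session
#'
#' Generates both members' EEG, beat-interval series (rendered to BVP) and
#' skin conductance, with phase annotations. Per task phase, the two members'
#' RMSSD targets are split symmetrically about the baseline RMSSD so their
#' baseline-normalized HRV values diverge by `hrv_targets[phase]` in
#' expectation.
#'
#' @param config A [sim_config()].
#' @param dyad Dyad index.
#' @param hrv_targets Named numeric (`IP`, `NCP`, `RP`): target inter-member
#'   divergence of baseline-normalized RMSSD per phase. Defaults to
#'   `(1 - hrv_similarity) * 0.8` for all phases.
#' @return An object of class `dyad_session`: list with `dyad_id`, `phases`,
#'   `members` (each with `eeg`, `bvp`, `scl`, and ground-truth
#'   `rmssd_target` per phase), and the generating `config`.
#' @export
simulate_dyad <- function(config, dyad = 1L, hrv_targets = NULL) {
  if (is.null(hrv_targets)) {
    hrv_targets <- setNames(rep((1 - config$hrv_similarity) * 0.8, 3),
                            task_phases())
  }
  hrv_targets <- pmin(pmax(hrv_targets[task_phases()], 0), 1.5)
  phases <- phase_annotations(config)
  members <- lapply(1:2, function(m) {
    sign <- if (m == 1) 1 else -1
    rmssd_target <- c(
      BL = config$rmssd_ms,
      config$rmssd_ms * (1 + sign * hrv_targets / 2)
    )
    names(rmssd_target) <- phase_levels()
    ibi <- unlist(lapply(seq_len(nrow(phases)), function(i) {
      dur <- phases$end_s[i] - phases$start_s[i]
      simulate_ibi(
        config$mean_ibi_ms,
        min(rmssd_target[[as.character(phases$label[i])]],
            config$mean_ibi_ms / 2),
        dur,
        seed = substream_seed(config$seed, "dyad", dyad, "member", m,
                              "ibi", as.character(phases$label[i])))
    }), use.names = FALSE)
    bvp <- render_bvp(ibi, config$bvp_rate)
    scl <- simulate_scl(
      session_duration_s(config), config$scl_rate,
      tonic_drift = config$scl_drift_uS_min,
      scr_rate_per_min = config$scr_rate_per_min,
      seed = substream_seed(config$seed, "dyad", dyad, "member", m, "scl"),
      level = config$scl_level_uS, scr_amp = config$scr_amp_uS,
      noise = config$scl_noise_uS)
    list(eeg = simulate_eeg_member(config, member = m, dyad = dyad),
         bvp = bvp, scl = scl, ibi = ibi, rmssd_target = rmssd_target)
  })
  structure(list(dyad_id = as.integer(dyad), phases = phases,
                 members = members, config = config,
                 hrv_targets = hrv_targets),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session> dyad %d: 2 members, %.0f s (BL + IP/NCP/RP)\n",
              x$dyad_id, session_duration_s(x$config)))
  invisible(x)
}

#' Simulate a full cohort of dyads
#'
#' Draws the latent cluster structure with [simulate_hrv_features()], maps
#' each dyad's standardized feature triple to a raw per-phase RMSSD
#' divergence target via `eudist_base + eudist_scale * z` (floored at 0.05),
#' and generates every session. A questionnaire table provides per-member
#' scale scores: BAS reward responsiveness inherits the dyad's cluster
#' structure, the remaining scales are structureless.
#'
#' @param config A [sim_config()] with a non-`NULL` `cluster_spec`.
#' @return An object of class `dyad_cohort`: list with `sessions` (list of
#'   [simulate_dyad()] results), `ground_truth` (per-dyad latent features,
#'   divergence targets and cluster labels), `questionnaire` (long tibble
#'   `dyad`, `member`, `scale`, `score`) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (is.null(config$cluster_spec)) {
    abort("simulate_cohort requires a cluster_spec",
          class = "dyadsync_config_error")
  }
  feats <- simulate_hrv_features(
    config$cluster_spec, seed = substream_seed(config$seed, "features"))
  to_delta <- function(z) pmax(config$eudist_base + config$eudist_scale * z,
                               0.05)
  sessions <- lapply(feats$dyad, function(d) {
    z <- unlist(feats[feats$dyad == d, task_phases()])
    simulate_dyad(config, dyad = d, hrv_targets = to_delta(z))
  })
  ground_truth <- feats %>%
    mutate(delta_IP = to_delta(.data$IP),
           delta_NCP = to_delta(.data$NCP),
           delta_RP = to_delta(.data$RP))
  questionnaire <- withr::with_seed(
    substream_seed(config$seed, "questionnaire"),
    purrr::list_rbind(lapply(feats$dyad, function(d) {
      bas <- feats$bas_rr[feats$dyad == d]
      scales <- c(gdms_rational = rnorm(1, 3.5, 0.5),
                  ms_total = rnorm(1, 4, 0.8),
                  bis = rnorm(1, 2.8, 0.4),
                  bas_drive = rnorm(1, 2.7, 0.4),
                  bas_fun_seeking = rnorm(1, 3.0, 0.4),
                  bfi_agreeableness = rnorm(1, 3.6, 0.5))
      purrr::list_rbind(lapply(1:2, function(m) {
        tibble(dyad = d, member = m,
               scale = c("bas_reward_responsiveness", names(scales)),
               score = c(bas + rnorm(1, 0, 0.15),
                         scales + rnorm(length(scales), 0, 0.15)))
      }))
    })))
  structure(list(sessions = sessions, ground_truth = ground_truth,
                 questionnaire = questionnaire, config = config),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %d dyads, %d latent clusters (seed %d)\n",
              length(x$sessions),
              length(unique(x$ground_truth$cluster)), x$config$seed))
  invisible(x)
}
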