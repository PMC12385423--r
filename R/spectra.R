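# Raw EEG -> baseline-normalized band power per member x band x electrode,
# aggregated to ROI x hemisphere cells.

#' Band-pass and notch filter an EEG recording
#'
#' Zero-phase filtering with a 0.01--50 Hz band-pass plus a 50 Hz notch.
#' The filter is applied in the frequency domain with a magnitude response
#' equal to a 4th-order Butterworth band-pass times a second-order notch,
#' which makes it exactly zero-phase and leaves the recording length
#' unchanged. Power at the notch frequency is suppressed by far more than
#' 20 dB while in-band components (e.g. 10 Hz) are preserved to within a few
#' percent; the high-pass edge removes any DC offset.
#'
#' @param rec An [eeg_recording()]; its rate must be at least 128 Hz so the
#'   0--50 Hz analysis range is fully resolvable.
#' @param band Length-2 numeric, band-pass edges in Hz.
#' @param notch_hz Notch center frequency (`NULL` to disable).
#' @param notch_q Notch quality factor (center / -3 dB width).
#' @param order Butterworth order of each band-pass edge.
#' @return A filtered [eeg_recording()].
#' @export
eeg_preprocess <- function(rec, band = c(0.01, 50), notch_hz = 50,
                           notch_q = 35, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate < 128) {
    abort("sampling rate below 128 Hz cannot carry 50 Hz content reliably",
          class = "dyadsync_input_error")
  }
  n <- ncol(rec$samples)
  f <- rfft_freq(n, rec$rate)
  hp <- ifelse(f <= 0, 0, 1 / sqrt(1 + (band[1] / pmax(f, 1e-12))^(2 * order)))
  lp <- 1 / sqrt(1 + (f / band[2])^(2 * order))
  H <- hp * lp
  if (!is.null(notch_hz)) {
    num <- abs(f^2 - notch_hz^2)
    den <- sqrt((f^2 - notch_hz^2)^2 + (f * notch_hz / notch_q)^2)
    H <- H * ifelse(den == 0, 0, num / den)
  }
  filtered <- t(apply(rec$samples, 1, function(x) irfft(rfft(x) * H, n)))
  rownames(filtered) <- rownames(rec$samples)
  eeg_recording(filtered, rec$rate, rec$member)
}

#' Segment a recording into fixed-length epochs with artifact rejection
#'
#' Cuts each annotated phase into non-overlapping `epoch_s`-second epochs
#' (epochs that would straddle a phase boundary are dropped) and flags an
#' epoch as rejected when any channel exceeds `amp_thresh_uV` in absolute
#' amplitude or is flat (peak-to-peak range below `flat_range_uV`). This
#' deterministic rule stands in for visual artifact inspection.
#'
#' @param rec An [eeg_recording()].
#' @param phases Tibble of half-open phase annotations (`label`, `start_s`,
#'   `end_s`).
#' @param epoch_s Epoch length in seconds.
#' @param amp_thresh_uV Absolute amplitude rejection threshold.
#' @param flat_range_uV Flat-line rejection threshold.
#' @return Tibble with one row per epoch: `phase`, `epoch`, `start_s`,
#'   `kept`, `reason` (`NA`, `"amplitude"` or `"flat"`), and a list-column
#'   `signal` of channel x time matrices. Sampling rate and channel labels
#'   travel as attributes `rate` and `channels`.
#' @export
eeg_epochs <- function(rec, phases, epoch_s = 2, amp_thresh_uV = 100,
                       flat_range_uV = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- round(epoch_s * rec$rate)
  rows <- purrr::pmap(phases, function(label, start_s, end_s, ...) {
    n_ep <- floor((end_s - start_s) / epoch_s)
    if (n_ep < 1) {
      abort(paste0("phase ", label, " is shorter than one epoch"),
            class = "dyadsync_input_error")
    }
    purrr::map(seq_len(n_ep), function(k) {
      t0 <- start_s + (k - 1) * epoch_s
      i0 <- round(t0 * rec$rate) + 1
      sig <- rec$samples[, i0:(i0 + ns - 1), drop = FALSE]
      rng <- apply(sig, 1, function(v) diff(range(v)))
      reason <- if (any(abs(sig) > amp_thresh_uV)) "amplitude"
                else if (any(rng < flat_range_uV)) "flat"
                else NA_character_
      tibble(phase = as.character(label), epoch = k, start_s = t0,
             kept = is.na(reason), reason = reason, signal = list(sig))
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows)
  out$phase <- phase_factor(out$phase)
  dropped <- out %>% summarise(all_gone = all(!.data$kept), .by = "phase") %>%
    filter(.data$all_gone)
  if (nrow(dropped)) {
    abort(paste0("all epochs rejected in phase(s): ",
                 paste(dropped$phase, collapse = ", ")),
          class = "dyadsync_artifact_error")
  }
  attr(out, "rate") <- rec$rate
  attr(out, "channels") <- rec$channels
  attr(out, "epoch_s") <- epoch_s
  out
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Average power spectral density over retained epochs
#'
#' Per-epoch Hamming-windowed periodogram averaged over the retained epochs
#' of each phase. With 2-s epochs the spectral resolution is 0.5 Hz at any
#' sampling rate. Normalization is such that a unit-amplitude sinusoid
#' integrates (sums over bins) to 0.5 and, by Parseval, summed PSD matches
#' time-domain variance.
#'
#' @param epochs Result of [eeg_epochs()].
#' @return Tibble `phase`, `channel`, `freq`, `psd` (microvolt squared per
#'   bin).
#' @export
eeg_psd <- function(epochs) {
  kept <- dplyr::filter(epochs, .data$kept)
  if (!nrow(kept)) {
    abort("no retained epochs", class = "dyadsync_input_error")
  }
  rate <- attr(epochs, "rate")
  channels <- attr(epochs, "channels")
  n <- ncol(kept$signal[[1]])
  w <- hamming_window(n)
  wnorm <- n * sum(w^2)
  nf <- n %/% 2 + 1
  freq <- rfft_freq(n, rate)
  scale <- c(1, rep(2, nf - 2), if (n %% 2 == 0) 1 else 2)
  psd_one <- function(sig) {
    out <- matrix(0, nrow(sig), nf)
    for (i in seq_len(nrow(sig))) {
      X <- stats::fft(sig[i, ] * w)[seq_len(nf)]
      out[i, ] <- scale * Mod(X)^2 / wnorm
    }
    out
  }
  per_phase <- kept %>%
    dplyr::group_split(.data$phase)
  rows <- purrr::map(per_phase, function(g) {
    acc <- Reduce(`+`, lapply(g$signal, psd_one)) / nrow(g)
    tibble(phase = g$phase[1],
           channel = rep(channels, times = nf),
           freq = rep(freq, each = length(channels)),
           psd = as.numeric(acc))
  })
  purrr::list_rbind(rows)
}

#' Integrate PSD into band power
#'
#' Sums the PSD bins whose center frequency lies in `[lo, hi]` inclusive for
#' each band, per phase and channel.
#'
#' @param psd Tibble from [eeg_psd()].
#' @param bands Band definition tibble, see [eeg_bands()].
#' @return Tibble `phase`, `channel`, `band`, `power`.
#' @export
band_power <- function(psd, bands = eeg_bands()) {
  rows <- purrr::pmap(bands, function(band, lo, hi) {
    sel <- dplyr::filter(psd, .data$freq >= lo - 1e-9, .data$freq <= hi + 1e-9)
    if (!nrow(sel)) {
      abort(paste0("no spectral bins fall inside band ", band),
            class = "dyadsync_input_error")
    }
    sel %>%
      summarise(power = sum(.data$psd), .by = c("phase", "channel")) %>%
      mutate(band = band)
  })
  purrr::list_rbind(rows) %>%
    mutate(band = factor(.data$band, levels = band_levels())) %>%
    dplyr::relocate("phase", "channel", "band", "power")
}

#' Baseline-normalize task power
#'
#' `(task - baseline) / baseline`, dimensionless. The baseline must be
#' strictly positive: a non-positive baseline signals a degenerate baseline
#' recording and is an error.
#'
#' @param task,baseline Numeric vectors (recycled to common length).
#' @return Numeric vector of normalized values.
#' @export
#' @examples
#' normalize_to_baseline(3, 2) # 0.5
normalize_to_baseline <- function(task, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    abort("baseline power must be finite and > 0",
          class = "dyadsync_input_error")
  }
  (task - baseline) / baseline
}

#' Baseline-normalized band power for one member
#'
#' Full single-member spectral chain: filter, epoch with artifact rejection,
#' Hamming-windowed PSD averaged per phase, band integration and baseline
#' normalization. One row per task phase x band x electrode.
#'
#' @param rec An [eeg_recording()] (raw; filtering is applied here).
#' @param phases Phase annotation tibble (must contain a `BL` row).
#' @param bands Band definitions, see [eeg_bands()].
#' @param epoch_s,amp_thresh_uV Passed to [eeg_epochs()].
#' @param preprocess Set to `FALSE` if `rec` is already filtered.
#' @return Tibble `member`, `phase`, `band`, `electrode`, `psd_task`,
#'   `psd_bl`, `normalized`.
#' @export
compute_band_power <- function(rec, phases, bands = eeg_bands(),
                               epoch_s = 2, amp_thresh_uV = 100,
                               preprocess = TRUE) {
  if (!"BL" %in% as.character(phases$label)) {
    abort("phase annotations must include a BL baseline row",
          class = "dyadsync_input_error")
  }
  if (preprocess) rec <- eeg_preprocess(rec)
  eps <- eeg_epochs(rec, phases, epoch_s = epoch_s,
                    amp_thresh_uV = amp_thresh_uV)
  bp <- band_power(eeg_psd(eps), bands)
  bl <- bp %>%
    dplyr::filter(.data$phase == "BL") %>%
    dplyr::select("channel", "band", psd_bl = "power")
  bp %>%
    dplyr::filter(.data$phase != "BL") %>%
    dplyr::rename(psd_task = "power", electrode = "channel") %>%
    dplyr::left_join(bl, by = c(electrode = "channel", "band")) %>%
    mutate(member = rec$member,
           phase = phase_factor(.data$phase, task_phases()),
           normalized = normalize_to_baseline(.data$psd_task, .data$psd_bl)) %>%
    dplyr::relocate("member", "phase", "band", "electrode",
                    "psd_task", "psd_bl", "normalized")
}

#' Per-epoch band power for one member
#'
#' Like [compute_band_power()] but without averaging the periodograms over
#' epochs: one row per retained epoch x band x electrode, with each epoch's
#' power normalized to the phase-averaged baseline power of its electrode
#' and band. This is the input to the epoch-wise synchrony mode, where the
#' dyadic distance runs over the vector of an ROI's per-epoch mean powers.
#'
#' @inheritParams compute_band_power
#' @return Tibble `member`, `phase`, `epoch`, `band`, `electrode`,
#'   `psd_task`, `psd_bl`, `normalized`.
#' @export
epoch_band_power <- function(rec, phases, bands = eeg_bands(), epoch_s = 2,
                             amp_thresh_uV = 100, preprocess = TRUE) {
  if (!"BL" %in% as.character(phases$label)) {
    abort("phase annotations must include a BL baseline row",
          class = "dyadsync_input_error")
  }
  if (preprocess) rec <- eeg_preprocess(rec)
  eps <- eeg_epochs(rec, phases, epoch_s = epoch_s,
                    amp_thresh_uV = amp_thresh_uV)
  kept <- dplyr::filter(eps, .data$kept)
  rate <- attr(eps, "rate")
  channels <- attr(eps, "channels")
  per_epoch <- purrr::pmap(kept[, c("phase", "epoch", "signal")],
                           function(phase, epoch, signal) {
    n <- ncol(signal)
    w <- hamming_window(n)
    nf <- n %/% 2 + 1
    scale <- c(1, rep(2, nf - 2), if (n %% 2 == 0) 1 else 2)
    psd <- t(apply(signal, 1, function(x) {
      scale * Mod(stats::fft(x * w)[seq_len(nf)])^2 / (n * sum(w^2))
    }))
    tibble(phase = phase, epoch = epoch,
           channel = rep(channels, times = nf),
           freq = rep(rfft_freq(n, rate), each = length(channels)),
           psd = as.numeric(psd))
  })
  bp <- purrr::list_rbind(per_epoch) %>%
    dplyr::group_split(.data$epoch) %>%
    purrr::map(function(g) {
      band_power(g, bands) %>% mutate(epoch = g$epoch[1])
    }) %>%
    purrr::list_rbind()
  bl <- bp %>%
    dplyr::filter(.data$phase == "BL") %>%
    summarise(psd_bl = mean(.data$power), .by = c("channel", "band"))
  bp %>%
    dplyr::filter(.data$phase != "BL") %>%
    dplyr::rename(psd_task = "power", electrode = "channel") %>%
    dplyr::left_join(bl, by = c(electrode = "channel", "band")) %>%
    mutate(member = rec$member,
           phase = phase_factor(.data$phase, task_phases()),
           normalized = normalize_to_baseline(.data$psd_task, .data$psd_bl)) %>%
    dplyr::relocate("member", "phase", "epoch", "band", "electrode",
                    "psd_task", "psd_bl", "normalized")
}

#' Aggregate electrode-level band power to ROI x hemisphere cells
#'
#' Means of the baseline-normalized values (and of the raw powers) over the
#' electrodes of each ROI, each lateralized ROI (2 electrodes) and each
#' whole ROI (4 electrodes, `hemisphere = "both"`). Midline electrodes enter
#' no ROI.
#'
#' @param bp Electrode-level table from [compute_band_power()].
#' @param rois ROI/hemisphere map, see [roi_map()].
#' @return Tibble `member`, `phase`, `band`, `roi`, `hemisphere`,
#'   `n_electrodes`, `psd_task`, `psd_bl`, `normalized`.
#' @export
aggregate_band_power <- function(bp, rois = roi_map()) {
  cells <- tidyr::expand_grid(
    roi = names(rois$roi),
    hemisphere = c("left", "right", "both"))
  rows <- purrr::pmap(cells, function(roi, hemisphere) {
    electrodes <- rois$roi[[roi]]
    if (hemisphere != "both") {
      electrodes <- intersect(electrodes, rois$hemisphere[[hemisphere]])
    }
    miss <- setdiff(electrodes, unique(bp$electrode))
    if (length(miss)) {
      abort(paste0("missing electrode(s) for ", roi, "/", hemisphere, ": ",
                   paste(miss, collapse = ", ")),
            class = "dyadsync_input_error")
    }
    bp %>%
      dplyr::filter(.data$electrode %in% electrodes) %>%
      summarise(n_electrodes = dplyr::n(),
                psd_task = mean(.data$psd_task),
                psd_bl = mean(.data$psd_bl),
                normalized = mean(.data$normalized),
                .by = c("member", "phase", "band")) %>%
      mutate(roi = roi, hemisphere = hemisphere)
  })
  purrr::list_rbind(rows) %>%
    mutate(roi = factor(.data$roi, levels = roi_levels()),
           hemisphere = factor(.data$hemisphere,
                               levels = c("left", "right", "both"))) %>%
    dplyr::relocate("member", "phase", "band", "roi", "hemisphere")
}
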