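# Raw SCL and BVP -> per-phase autonomic scalars (SCL, SCR, HR, HRV) per
# member, with optional baseline normalization.

#' Decompose skin conductance into tonic and phasic components
#'
#' The phasic component is the SCL minus a centered moving average of width
#' `ma_window_s`; phasic excursions are runs of positive phasic signal whose
#' peak exceeds `min_amp_uS`, each counted as one skin conductance response
#' (SCR) with amplitude equal to the run's peak.
#'
#' @param scl Tibble with columns `time_s`, `value` (microsiemens), regularly
#'   sampled.
#' @param ma_window_s Moving-average window in seconds; must be shorter than
#'   the series.
#' @param min_amp_uS Minimum peak amplitude for an excursion to count.
#' @return List with `phasic` (tibble `time_s`, `value`) and `events`
#'   (tibble `time_s`, `amplitude`, one row per SCR).
#' @export
scr_from_scl <- function(scl, ma_window_s = 4, min_amp_uS = 0.01) {
  check_finite(scl$value, "scl")
  dt <- median(diff(scl$time_s))
  w <- max(1L, round(ma_window_s / dt))
  if (w >= nrow(scl)) {
    abort("moving-average window must be shorter than the series",
          class = "dyadsync_input_error")
  }
  # centered moving average with shrinking edges
  half <- w %/% 2
  n <- nrow(scl)
  cs <- cumsum(c(0, scl$value))
  i0 <- pmax(seq_len(n) - half, 1)
  i1 <- pmin(seq_len(n) + half, n)
  ma <- (cs[i1 + 1] - cs[i0]) / (i1 - i0 + 1)
  phasic <- scl$value - ma
  pos <- phasic > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ev <- purrr::map(which(runs$values), function(r) {
    idx <- starts[r]:ends[r]
    pk <- idx[which.max(phasic[idx])]
    if (phasic[pk] >= min_amp_uS) {
      tibble(time_s = scl$time_s[pk], amplitude = phasic[pk])
    } else {
      NULL
    }
  })
  events <- purrr::list_rbind(purrr::compact(ev))
  if (!nrow(events)) {
    events <- tibble(time_s = numeric(), amplitude = numeric())
  }
  list(phasic = tibble(time_s = scl$time_s, value = phasic),
       events = events)
}

#' Detect heart beats in a blood-volume-pulse waveform
#'
#' Local maxima above an adaptive threshold (median plus half the
#' median-to-maximum span) separated by at least `refractory_s`; when two
#' candidates fall inside the refractory window the taller one wins. Peak
#' times are refined by quadratic interpolation around the sample maximum to
#' sub-sample precision.
#'
#' @param bvp Tibble with `time_s`, `value` (length at least 2 s).
#' @param refractory_s Minimum inter-beat separation in seconds.
#' @return Numeric vector of beat times in seconds (at least 2, else error).
#' @export
detect_beats <- function(bvp, refractory_s = 0.3) {
  check_finite(bvp$value, "bvp")
  t <- bvp$time_s
  x <- bvp$value
  if (length(t) < 2 || (t[length(t)] - t[1]) < 2) {
    abort("bvp series must span at least 2 s", class = "dyadsync_input_error")
  }
  thr <- median(x) + 0.5 * (max(x) - median(x))
  if (max(x) <= median(x)) {
    abort("no pulsatile activity detected (flat signal)",
          class = "dyadsync_beat_error")
  }
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] >= thr]
  if (length(cand) < 2) {
    abort("fewer than 2 beats detected", class = "dyadsync_beat_error")
  }
  # enforce refractory period, keeping the taller of conflicting peaks
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || t[i] - t[keep[length(keep)]] >= refractory_s) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  dt <- median(diff(t))
  vapply(keep, function(i) {
    if (i <= 1 || i >= n) return(t[i])
    y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den == 0) return(t[i])
    delta <- 0.5 * (y0 - y2) / den
    t[i] + max(min(delta, 0.5), -0.5) * dt
  }, numeric(1))
}

#' Heart rate and heart rate variability from beat times
#'
#' Inter-beat intervals are successive beat-time differences in ms within
#' `[start_s, end_s)`; `hr_mean = 60000 / mean(IBI)` in bpm and
#' `hrv = RMSSD`, the root mean square of successive IBI differences
#' (`"sdnn"` is available as an alternative). Windows holding fewer than 3
#' beats yield missing values with a warning.
#'
#' @param beat_times Numeric beat times in seconds.
#' @param start_s,end_s Analysis window (half-open).
#' @param metric `"rmssd"` (default) or `"sdnn"`.
#' @return Tibble `n_beats`, `hr_mean`, `hrv`.
#' @export
#' @examples
#' hr_hrv_from_beats(cumsum(rep(1, 10))) # HR 60, HRV 0
hr_hrv_from_beats <- function(beat_times, start_s = -Inf, end_s = Inf,
                              metric = c("rmssd", "sdnn")) {
  metric <- match.arg(metric)
  bt <- sort(beat_times[beat_times >= start_s & beat_times < end_s])
  if (length(bt) < 3) {
    warn("window holds fewer than 3 beats; returning missing values")
    return(tibble(n_beats = length(bt), hr_mean = NA_real_, hrv = NA_real_))
  }
  ibi <- diff(bt) * 1000
  hrv <- if (metric == "rmssd") {
    sqrt(mean(diff(ibi)^2))
  } else {
    sd(ibi)
  }
  tibble(n_beats = length(bt), hr_mean = 60000 / mean(ibi), hrv = hrv)
}

#' Per-phase autonomic features for one member
#'
#' Derives, for every annotated phase (baseline included): mean SCL, SCR
#' count and mean SCR amplitude (from [scr_from_scl()]), and mean HR and HRV
#' (from beats detected in the BVP waveform).
#'
#' @param scl,bvp Tibbles with `time_s`, `value`.
#' @param phases Phase annotation tibble.
#' @param member Member index carried into the output.
#' @param hrv_metric Passed to [hr_hrv_from_beats()].
#' @param ma_window_s,min_amp_uS Passed to [scr_from_scl()].
#' @return Long tibble `member`, `phase`, `measure` in
#'   `{SCL, SCR, SCR_amp, HR, HRV}`, `value`.
#' @export
autonomic_features <- function(scl, bvp, phases, member = 1L,
                               hrv_metric = "rmssd",
                               ma_window_s = 4, min_amp_uS = 0.01) {
  scr <- scr_from_scl(scl, ma_window_s, min_amp_uS)
  beats <- detect_beats(bvp)
  rows <- purrr::pmap(phases, function(label, start_s, end_s, ...) {
    in_win <- scl$time_s >= start_s & scl$time_s < end_s
    ev <- scr$events %>%
      dplyr::filter(.data$time_s >= start_s, .data$time_s < end_s)
    hh <- hr_hrv_from_beats(beats, start_s, end_s, metric = hrv_metric)
    tibble(
      member = member, phase = as.character(label),
      measure = c("SCL", "SCR", "SCR_amp", "HR", "HRV"),
      value = c(mean(scl$value[in_win]), nrow(ev),
                if (nrow(ev)) mean(ev$amplitude) else NA_real_,
                hh$hr_mean, hh$hrv))
  })
  purrr::list_rbind(rows) %>%
    mutate(phase = phase_factor(.data$phase))
}

#' Baseline-normalize autonomic features
#'
#' Mirrors the EEG normalization: `(task - baseline) / baseline` per measure
#' per member. With `zero_baseline = "error"` (default) a zero or missing
#' baseline aborts; `"na"` instead emits a missing normalized value with a
#' warning (useful in pipelines where, e.g., a baseline window may contain
#' zero SCRs).
#'
#' @param features Long tibble from [autonomic_features()] including the
#'   `BL` phase.
#' @param zero_baseline `"error"` or `"na"`.
#' @return The task-phase rows of `features` with a `normalized` column.
#' @export
normalize_features <- function(features,
                               zero_baseline = c("error", "na")) {
  zero_baseline <- match.arg(zero_baseline)
  bl <- features %>%
    dplyr::filter(.data$phase == "BL") %>%
    dplyr::select("member", "measure", baseline = "value")
  out <- features %>%
    dplyr::filter(.data$phase != "BL") %>%
    dplyr::left_join(bl, by = c("member", "measure"))
  bad <- !is.finite(out$baseline) | out$baseline == 0
  if (any(bad)) {
    msg <- paste0("zero or missing baseline for ",
                  paste(unique(paste0("member ", out$member[bad], " ",
                                      out$measure[bad])), collapse = "; "))
    if (zero_baseline == "error") {
      abort(msg, class = "dyadsync_input_error")
    }
    warn(msg)
  }
  out %>%
    mutate(normalized = ifelse(bad, NA_real_,
                               (.data$value - .data$baseline) / .data$baseline),
           phase = phase_factor(as.character(.data$phase), task_phases())) %>%
    dplyr::select(-"baseline")
}
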