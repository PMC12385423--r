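# The dyadic Euclidean-distance (EuDist) synchrony index for EEG band power
# and autonomic features. Lower values indicate stronger alignment.

#' Euclidean distance between two feature vectors
#'
#' `sqrt(sum((v1 - v2)^2))`. The index is symmetric, non-negative and zero
#' exactly when the vectors coincide.
#'
#' @param v1,v2 Finite numeric vectors of equal, nonzero length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' eudist(c(0, 0), c(3, 4)) # 5
eudist <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    abort("v1 and v2 must have equal length", class = "dyadsync_input_error")
  }
  if (!length(v1)) {
    abort("vectors must be non-empty", class = "dyadsync_input_error")
  }
  check_finite(v1, "v1")
  check_finite(v2, "v2")
  sqrt(sum((v1 - v2)^2))
}

#' Inter-member EEG synchrony table
#'
#' For each phase x band x ROI x hemisphere cell, the Euclidean distance
#' between the two members' vectors of per-electrode baseline-normalized
#' band power (2 electrodes in a lateralized cell, 4 in a whole-ROI cell).
#'
#' @param bp1,bp2 Electrode-level band-power tables from
#'   [compute_band_power()] for members 1 and 2; their
#'   phase x band x electrode keys must match exactly.
#' @param rois ROI/hemisphere map, see [roi_map()].
#' @return Tibble `phase`, `band`, `roi`, `hemisphere`, `n_electrodes`,
#'   `eudist`.
#' @export
eeg_synchrony <- function(bp1, bp2, rois = roi_map()) {
  key <- function(bp) paste(bp$phase, bp$band, bp$electrode)
  miss <- c(setdiff(key(bp1), key(bp2)), setdiff(key(bp2), key(bp1)))
  if (length(miss)) {
    abort(paste0("band-power tables disagree on cells: ",
                 paste(unique(miss), collapse = "; ")),
          class = "dyadsync_input_error")
  }
  joined <- dplyr::inner_join(
    dplyr::select(bp1, "phase", "band", "electrode", n1 = "normalized"),
    dplyr::select(bp2, "phase", "band", "electrode", n2 = "normalized"),
    by = c("phase", "band", "electrode"))
  cells <- tidyr::expand_grid(roi = names(rois$roi),
                              hemisphere = c("left", "right", "both"))
  rows <- purrr::pmap(cells, function(roi, hemisphere) {
    electrodes <- rois$roi[[roi]]
    if (hemisphere != "both") {
      electrodes <- intersect(electrodes, rois$hemisphere[[hemisphere]])
    }
    joined %>%
      dplyr::filter(.data$electrode %in% electrodes) %>%
      summarise(n_electrodes = dplyr::n(),
                eudist = eudist(.data$n1, .data$n2),
                .by = c("phase", "band")) %>%
      mutate(roi = roi, hemisphere = hemisphere)
  })
  purrr::list_rbind(rows) %>%
    mutate(roi = factor(.data$roi, levels = roi_levels()),
           hemisphere = factor(.data$hemisphere,
                               levels = c("left", "right", "both"))) %>%
    dplyr::relocate("phase", "band", "roi", "hemisphere")
}

#' Epoch-wise inter-member EEG synchrony table
#'
#' Alternative summation dimension for the distance index: instead of the
#' per-electrode vector of a cell, the distance runs over the vector of
#' 2-s-epoch ROI-mean baseline-normalized powers within the phase. Only
#' epochs retained for both members enter the vector.
#'
#' @param ebp1,ebp2 Per-epoch band-power tables from [epoch_band_power()]
#'   for members 1 and 2.
#' @param rois ROI/hemisphere map, see [roi_map()].
#' @return Tibble `phase`, `band`, `roi`, `hemisphere`, `n_epochs`,
#'   `eudist`.
#' @export
eeg_synchrony_epochs <- function(ebp1, ebp2, rois = roi_map()) {
  cells <- tidyr::expand_grid(roi = names(rois$roi),
                              hemisphere = c("left", "right", "both"))
  roi_series <- function(ebp, roi, hemisphere) {
    electrodes <- rois$roi[[roi]]
    if (hemisphere != "both") {
      electrodes <- intersect(electrodes, rois$hemisphere[[hemisphere]])
    }
    ebp %>%
      dplyr::filter(.data$electrode %in% electrodes) %>%
      summarise(value = mean(.data$normalized),
                .by = c("phase", "band", "epoch"))
  }
  rows <- purrr::pmap(cells, function(roi, hemisphere) {
    dplyr::inner_join(roi_series(ebp1, roi, hemisphere),
                      roi_series(ebp2, roi, hemisphere),
                      by = c("phase", "band", "epoch"),
                      suffix = c("1", "2")) %>%
      summarise(n_epochs = dplyr::n(),
                eudist = eudist(.data$value1, .data$value2),
                .by = c("phase", "band")) %>%
      mutate(roi = roi, hemisphere = hemisphere)
  })
  purrr::list_rbind(rows) %>%
    mutate(roi = factor(.data$roi, levels = roi_levels()),
           hemisphere = factor(.data$hemisphere,
                               levels = c("left", "right", "both"))) %>%
    dplyr::relocate("phase", "band", "roi", "hemisphere")
}

#' Inter-member autonomic synchrony table
#'
#' Per phase and measure, the Euclidean distance between the two members'
#' scalar feature values, which in one dimension reduces to the absolute
#' difference. Uses the `normalized` column when present, the raw `value`
#' otherwise. Cells with a missing value in either member are dropped with a
#' warning.
#'
#' @param f1,f2 Feature tables from [autonomic_features()] /
#'   [normalize_features()] for members 1 and 2.
#' @return Tibble `phase`, `measure`, `eudist`.
#' @export
autonomic_synchrony <- function(f1, f2) {
  col <- if ("normalized" %in% names(f1) && "normalized" %in% names(f2)) {
    "normalized"
  } else {
    "value"
  }
  joined <- dplyr::inner_join(
    dplyr::select(f1, "phase", "measure", v1 = dplyr::all_of(col)),
    dplyr::select(f2, "phase", "measure", v2 = dplyr::all_of(col)),
    by = c("phase", "measure"))
  if (nrow(joined) < max(nrow(f1), nrow(f2))) {
    abort("members disagree on phase/measure cells",
          class = "dyadsync_input_error")
  }
  bad <- !is.finite(joined$v1) | !is.finite(joined$v2)
  if (any(bad)) {
    warn(paste0("dropping cells with missing values: ",
                paste(paste0(joined$phase[bad], "/", joined$measure[bad]),
                      collapse = ", ")))
  }
  joined %>%
    dplyr::filter(!bad) %>%
    mutate(eudist = abs(.data$v1 - .data$v2)) %>%
    dplyr::select("phase", "measure", "eudist")
}
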