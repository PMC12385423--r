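# 10/20 montage, frequency bands and regions of interest used throughout.

#' The 15-electrode 10/20 montage
#'
#' Channel labels, in canonical order, of the 15 scalp electrodes expected in
#' every EEG recording handled by the package.
#'
#' @return Character vector of 15 electrode labels.
#' @export
#' @examples
#' eeg_montage()
eeg_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz", "Cz", "C3", "C4",
    "T7", "T8", "Pz", "P3", "P4", "O1", "O2")
}

#' Standard EEG frequency bands
#'
#' Band edges in Hz: delta 0.5--3.5, theta 4--7.5, alpha 8--12.5, beta 13--30,
#' gamma 30.5--50. Bands are disjoint at the 0.5 Hz spectral resolution used
#' by [eeg_psd()]; a spectral bin contributes to a band when its center
#' frequency lies in `[lo, hi]` inclusive.
#'
#' @return A tibble with columns `band` (factor), `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = band_levels()),
    lo = c(0.5, 4, 8, 13, 30.5),
    hi = c(3.5, 7.5, 12.5, 30, 50)
  )
}

band_levels <- function() c("delta", "theta", "alpha", "beta", "gamma")

phase_levels <- function() c("BL", "IP", "NCP", "RP")

task_phases <- function() c("IP", "NCP", "RP")

#' Regions of interest and hemisphere groupings
#'
#' Electrode groupings used for regional aggregation: frontal
#' (ROI-F: Fp1, Fp2, F3, F4), temporo-central (ROI-TC: T7, T8, C3, C4) and
#' parieto-occipital (ROI-PO: P3, P4, O1, O2), plus left/right hemisphere
#' splits. Midline electrodes (Fz, Cz, Pz) are recorded but enter no ROI.
#'
#' @return A list with elements `roi` (named list of electrode sets) and
#'   `hemisphere` (named list with `left` and `right` electrode sets).
#' @export
#' @examples
#' roi_map()$roi$`ROI-F`
roi_map <- function() {
  list(
    roi = list(
      "ROI-F"  = c("Fp1", "Fp2", "F3", "F4"),
      "ROI-TC" = c("T7", "T8", "C3", "C4"),
      "ROI-PO" = c("P3", "P4", "O1", "O2")
    ),
    hemisphere = list(
      left  = c("Fp1", "F3", "T7", "C3", "P3", "O1"),
      right = c("Fp2", "F4", "T8", "C4", "P4", "O2")
    )
  )
}

roi_levels <- function() c("ROI-F", "ROI-TC", "ROI-PO")

# ROI used to look up per-region simulation parameters for midline channels.
sim_roi_of_channel <- function(channel) {
  rm <- roi_map()$roi
  for (r in names(rm)) if (channel %in% rm[[r]]) return(r)
  switch(channel, Fz = "ROI-F", Cz = "ROI-TC", Pz = "ROI-PO",
         abort(paste0("unknown channel label: ", channel),
               class = "dyadsync_config_error"))
}
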