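# Session-level and cohort-level orchestration: simulate -> spectra ->
# autonomic -> synchrony -> ANOVA -> cluster, plus delimited-text session
# I/O.

#' Analyze one dyadic session
#'
#' Runs the full per-dyad feature chain: baseline-normalized band power per
#' member (filter, epoch, PSD, band integration), EEG synchrony per
#' band x ROI x hemisphere x phase, per-phase autonomic features per member
#' with baseline normalization, and autonomic synchrony per measure x phase.
#'
#' @param session A `dyad_session` (from [simulate_dyad()] or
#'   [read_session()]).
#' @param bands Band definitions, see [eeg_bands()].
#' @param epoch_s,amp_thresh_uV Epoching parameters, see [eeg_epochs()].
#' @param hrv_metric `"rmssd"` or `"sdnn"`.
#' @param synchrony_mode `"electrode"` (default): the EEG distance runs over
#'   the per-electrode vector of each cell; `"epoch"`: it runs over the
#'   vector of 2-s-epoch ROI-mean powers, see [eeg_synchrony_epochs()].
#' @param zero_baseline Handling of zero autonomic baselines, see
#'   [normalize_features()]; the pipeline default is `"na"` so a single
#'   SCR-free baseline window cannot abort a cohort run.
#' @return List of tibbles (each carrying a `dyad` column): `band_power`,
#'   `eeg_synchrony`, `autonomic`, `autonomic_synchrony`.
#' @export
analyze_session <- function(session, bands = eeg_bands(), epoch_s = 2,
                            amp_thresh_uV = 100, hrv_metric = "rmssd",
                            synchrony_mode = c("electrode", "epoch"),
                            zero_baseline = "na") {
  synchrony_mode <- match.arg(synchrony_mode)
  phases <- session$phases
  bp <- lapply(1:2, function(m) {
    compute_band_power(session$members[[m]]$eeg, phases, bands = bands,
                       epoch_s = epoch_s, amp_thresh_uV = amp_thresh_uV)
  })
  eeg_sync <- if (synchrony_mode == "electrode") {
    eeg_synchrony(bp[[1]], bp[[2]])
  } else {
    ebp <- lapply(1:2, function(m) {
      epoch_band_power(session$members[[m]]$eeg, phases, bands = bands,
                       epoch_s = epoch_s, amp_thresh_uV = amp_thresh_uV)
    })
    eeg_synchrony_epochs(ebp[[1]], ebp[[2]])
  }
  feats <- lapply(1:2, function(m) {
    normalize_features(
      autonomic_features(session$members[[m]]$scl, session$members[[m]]$bvp,
                         phases, member = m, hrv_metric = hrv_metric),
      zero_baseline = zero_baseline)
  })
  add_dyad <- function(x) mutate(x, dyad = session$dyad_id, .before = 1)
  list(
    band_power = add_dyad(purrr::list_rbind(bp)),
    eeg_synchrony = add_dyad(eeg_sync),
    autonomic = add_dyad(purrr::list_rbind(feats)),
    autonomic_synchrony = add_dyad(autonomic_synchrony(feats[[1]],
                                                       feats[[2]]))
  )
}

#' Run the complete cohort pipeline
#'
#' Simulates a cohort from `config` (or takes a ready-made one), analyzes
#' every session, fits the per-band repeated-measures ANOVAs on EEG
#' synchrony (lateralization x ROI x phase) and the per-measure
#' phase ANOVAs on autonomic synchrony, clusters the per-dyad phase-wise
#' HRV synchrony profiles, and compares questionnaire scales between
#' clusters with one-way ANOVAs. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built `dyad_cohort`.
#' @param k Final k-means cluster count (`"auto"` for the gap choice).
#' @param gap_B,boot_B Validation resampling sizes.
#' @param out_dir Optional directory; when given, tidy CSV tables and a JSON
#'   report are written there.
#' @param ... Passed to [analyze_session()].
#' @return Object of class `synth_pipeline`: list with `tables` (the bound
#'   per-dyad tibbles), `eeg_anova` (per band), `autonomic_anova` (per
#'   measure), `clusters` (an `hrv_clusters` fit), `scale_anova`,
#'   `hrv_features`, `manifest`, and the `cohort`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL, k = 2,
                         gap_B = 100, boot_B = 200, out_dir = NULL, ...) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  config <- cohort$config
  analyses <- lapply(cohort$sessions, analyze_session, ...)
  tables <- purrr::map(
    setNames(nm = names(analyses[[1]])),
    function(nm) purrr::list_rbind(purrr::map(analyses, nm)))

  eeg_anova <- lapply(setNames(nm = band_levels()), function(b) {
    d <- tables$eeg_synchrony %>%
      dplyr::filter(.data$band == b, .data$hemisphere != "both") %>%
      mutate(lateralization = droplevels(.data$hemisphere))
    rm_anova(d, "eudist", c("lateralization", "roi", "phase"), "dyad")
  })

  auto_meas <- c("SCL", "SCR", "HR", "HRV")
  autonomic_anova <- lapply(setNames(nm = auto_meas), function(ms) {
    d <- tables$autonomic_synchrony %>%
      dplyr::filter(.data$measure == ms)
    complete <- d %>%
      dplyr::count(.data$dyad) %>%
      dplyr::filter(.data$n == length(task_phases()))
    d <- dplyr::semi_join(d, complete, by = "dyad")
    if (length(unique(d$dyad)) < 3) return(NULL)
    rm_anova(d, "eudist", "phase", "dyad")
  })

  hrv_features <- tables$autonomic_synchrony %>%
    dplyr::filter(.data$measure == "HRV") %>%
    tidyr::pivot_wider(id_cols = "dyad", names_from = "phase",
                       values_from = "eudist") %>%
    dplyr::filter(complete.cases(.))
  clusters <- cluster_hrv(hrv_features, k = k, gap_B = gap_B,
                          boot_B = boot_B,
                          seed = substream_seed(config$seed, "cluster"))

  dyad_scales <- cohort$questionnaire %>%
    summarise(score = mean(.data$score), .by = c("dyad", "scale")) %>%
    dplyr::inner_join(mutate(tidy(clusters), dyad = as.integer(.data$dyad)),
                      by = "dyad")
  scale_anova <- dyad_scales %>%
    dplyr::group_split(.data$scale) %>%
    purrr::map(function(g) {
      mutate(oneway_anova(g, "score", "cluster"), scale = g$scale[1],
             .before = 1)
    }) %>%
    purrr::list_rbind()

  manifest <- tibble(
    stage = c("cohort", "band_power", "eeg_synchrony", "autonomic",
              "autonomic_synchrony", "cluster"),
    rows = c(length(cohort$sessions), nrow(tables$band_power),
             nrow(tables$eeg_synchrony), nrow(tables$autonomic),
             nrow(tables$autonomic_synchrony), nrow(hrv_features)),
    checksum = c(NA, vapply(tables, numeric_checksum, numeric(1)),
                 numeric_checksum(hrv_features)),
    seed = config$seed)

  out <- structure(list(tables = tables, eeg_anova = eeg_anova,
                        autonomic_anova = autonomic_anova,
                        clusters = clusters, scale_anova = scale_anova,
                        hrv_features = hrv_features, manifest = manifest,
                        cohort = cohort, config = config),
                   class = "synth_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# order-independent checksum of a table's numeric content, rounded to 10
# significant digits so it is stable across platforms
numeric_checksum <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  v <- unlist(df[num], use.names = FALSE)
  v <- signif(v[is.finite(v)], 10)
  sum(v) + 1e-3 * length(v)
}

#' @export
print.synth_pipeline <- function(x, ...) {
  cat(sprintf("<synth_pipeline> %d dyads (seed %d)\n",
              length(x$cohort$sessions), x$config$seed))
  cat("EEG synchrony ANOVAs (ROI effect):\n")
  for (b in names(x$eeg_anova)) {
    tb <- tidy(x$eeg_anova[[b]])
    r <- tb[tb$effect == "roi", ]
    cat(sprintf("  %-6s F[%d,%d] = %6.3f, p = %.3f\n", b, r$df_num,
                r$df_den, r$F, r$p_reported))
  }
  if (!is.null(x$autonomic_anova$HRV)) {
    r <- tidy(x$autonomic_anova$HRV)
    cat(sprintf("HRV phase effect: F[%d,%d] = %.3f, p = %.3f\n",
                r$df_num, r$df_den, r$F, r$p_reported))
  }
  print(x$clusters)
  invisible(x)
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$tables$band_power, file.path(out_dir, "band_power.csv"))
  readr::write_csv(x$tables$eeg_synchrony,
                   file.path(out_dir, "eeg_synchrony.csv"))
  readr::write_csv(x$tables$autonomic, file.path(out_dir, "autonomic.csv"))
  readr::write_csv(x$tables$autonomic_synchrony,
                   file.path(out_dir, "autonomic_synchrony.csv"))
  readr::write_csv(tidy(x$clusters), file.path(out_dir, "cluster_labels.csv"))
  anova_tables <- purrr::list_rbind(purrr::imap(
    x$eeg_anova, function(a, b) mutate(tidy(a), band = b, .before = 1)))
  readr::write_csv(anova_tables, file.path(out_dir, "eeg_anova.csv"))
  report <- list(
    seed = x$config$seed,
    n_dyads = length(x$cohort$sessions),
    cluster = as.list(glance(x$clusters)),
    scale_anova = x$scale_anova,
    manifest = x$manifest)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Write a dyadic session as delimited text
#'
#' EEG per member as CSV (`time_s` plus the 15 montage channels in
#' microvolts), SCL and BVP per member as two-column CSV, and the phase
#' annotations as TSV with half-open `[start_s, end_s)` intervals.
#'
#' @param session A `dyad_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in 1:2) {
    mem <- session$members[[m]]
    eeg <- mem$eeg
    df <- as_tibble(t(eeg$samples))
    df <- dplyr::bind_cols(
      tibble(time_s = (seq_len(ncol(eeg$samples)) - 1) / eeg$rate), df)
    readr::write_csv(df, file.path(dir, sprintf("eeg_member%d.csv", m)))
    readr::write_csv(mem$scl, file.path(dir, sprintf("scl_member%d.csv", m)))
    readr::write_csv(mem$bvp, file.path(dir, sprintf("bvp_member%d.csv", m)))
  }
  readr::write_tsv(session$phases, file.path(dir, "phases.tsv"))
  invisible(dir)
}

#' Read a dyadic session from delimited text
#'
#' Counterpart of [write_session()]. Validates that all 15 montage channels
#' are present, that phase annotations are well-formed (positive-length,
#' non-overlapping half-open intervals; out-of-order rows are re-sorted with
#' a warning) and infers sampling rates from the time columns.
#'
#' @param dir Directory holding the session files.
#' @param dyad_id Dyad identifier for the returned session.
#' @return A `dyad_session`.
#' @export
read_session <- function(dir, dyad_id = 1L) {
  phases <- readr::read_tsv(file.path(dir, "phases.tsv"),
                            show_col_types = FALSE)
  if (any(phases$end_s <= phases$start_s)) {
    abort("phase annotations contain end_s <= start_s",
          class = "dyadsync_input_error")
  }
  if (is.unsorted(phases$start_s)) {
    warn("phase annotations out of order; re-sorting")
    phases <- dplyr::arrange(phases, .data$start_s)
  }
  if (any(head(phases$end_s, -1) > tail(phases$start_s, -1) + 1e-9)) {
    abort("phase annotations overlap", class = "dyadsync_input_error")
  }
  phases$label <- phase_factor(phases$label)
  members <- lapply(1:2, function(m) {
    eeg_df <- readr::read_csv(file.path(dir, sprintf("eeg_member%d.csv", m)),
                              show_col_types = FALSE)
    miss <- setdiff(eeg_montage(), names(eeg_df))
    if (length(miss)) {
      abort(paste0("eeg_member", m, ".csv lacks channels: ",
                   paste(miss, collapse = ", ")),
            class = "dyadsync_input_error")
    }
    rate <- 1 / median(diff(eeg_df$time_s))
    samples <- t(as.matrix(eeg_df[, eeg_montage()]))
    rec <- eeg_recording(samples, rate = round(rate), member = m)
    scl <- readr::read_csv(file.path(dir, sprintf("scl_member%d.csv", m)),
                           show_col_types = FALSE)
    bvp <- readr::read_csv(file.path(dir, sprintf("bvp_member%d.csv", m)),
                           show_col_types = FALSE)
    list(eeg = rec, scl = scl, bvp = bvp)
  })
  structure(list(dyad_id = as.integer(dyad_id), phases = phases,
                 members = members, config = NULL),
            class = "dyad_session")
}
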