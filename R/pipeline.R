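## End-to-end acquisition emulation: preprocess each synthetic spectrum,
## run doublet detection and MS3 precursor selection, score against ground
## truth, and assemble the per-spectrum records the metrics module consumes.

#' Detection/trigger parameter set
#'
#' Bundles the knobs of the doublet-detection and MS3-selection step. The
#' defaults are the optimized acquisition-emulation values: 5 ppm
#' tolerance, delta-mass shifts {0, +1H, +2H}, +/-1.5 m/z dedup window,
#' intensity-rank cutoff 20, at most 5 triggers, heavy-peak trigger, and
#' assumed fragment charges 1..(precursor charge - 1).
#'
#' @param tol_ppm Doublet mass tolerance (ppm).
#' @param shifts Integer H-shift offsets defining the delta variants.
#' @param window_mz Dedup half-window (Th); \code{NA} disables dedup.
#' @param max_rank Intensity-rank cutoff (NULL = none).
#' @param max_triggers MS3 budget per MS2.
#' @param trigger_on "heavy" or "light" doublet peak.
#' @param charges Assumed charges, or NULL for 1..(precursor charge - 1)
#'   per spectrum (falling back to 1 when the charge is unknown or 2).
#' @param precursor_window Precursor-removal half-window (Th) applied
#'   before detection; \code{NA} skips removal.
#' @return List of class \code{xl_detect_params}.
#' @export
detect_params <- function(tol_ppm = 5, shifts = c(0L, 1L, 2L),
                          window_mz = 1.5, max_rank = 20L,
                          max_triggers = 5L,
                          trigger_on = c("heavy", "light"),
                          charges = NULL, precursor_window = 2.0) {
  structure(list(tol_ppm = tol_ppm, shifts = as.integer(shifts),
                 window_mz = window_mz, max_rank = max_rank,
                 max_triggers = as.integer(max_triggers),
                 trigger_on = match.arg(trigger_on), charges = charges,
                 precursor_window = precursor_window),
            class = "xl_detect_params")
}

assumed_charges <- function(spectrum, params) {
  if (!is.null(params$charges)) return(params$charges)
  z <- spectrum$precursor_charge
  if (is.na(z) || z <= 2) 1L else seq_len(z - 1L)
}

#' Detect doublets and select MS3 precursors for one spectrum
#'
#' Removes the precursor region, ranks peaks, runs
#' \code{\link{find_doublets}} over the parameter set's delta variants, and
#' selects MS3 precursors (dedup + budget). With \code{window_mz = NA} the
#' dedup filter is skipped (the behaviour of the plain vendor-style
#' triggering).
#'
#' @param spec An \code{xl_spectrum}.
#' @param xl An \code{xl_crosslinker}.
#' @param params An \code{xl_detect_params}.
#' @return List with \code{matches} and \code{triggers}.
#' @export
detect_spectrum <- function(spec, xl, params = detect_params()) {
  if (!is.na(params$precursor_window))
    spec <- remove_precursor(spec, params$precursor_window)
  if (n_peaks(spec) == 0)
    return(list(matches = empty_doublet_matches(),
                triggers = select_ms3_precursors(empty_doublet_matches(),
                                                 NULL,
                                                 params$max_triggers)))
  rs <- rank_peaks(spec)
  deltas <- doublet_delta_set(xl, params$shifts)
  matches <- find_doublets(rs, deltas, tol_ppm = params$tol_ppm,
                           charges = assumed_charges(spec, params),
                           max_rank = params$max_rank)
  window <- if (is.na(params$window_mz)) 0 else params$window_mz
  triggers <- select_ms3_precursors(matches, rs,
                                    max_triggers = params$max_triggers,
                                    window_mz = window,
                                    trigger_on = params$trigger_on)
  list(matches = matches, triggers = triggers)
}

## best (lowest) intensity rank among a peptide's planted stub peaks,
## measured on the preprocessed spectrum
stub_best_rank <- function(spec, truth, pid, params) {
  if (!is.na(params$precursor_window))
    spec <- remove_precursor(spec, params$precursor_window)
  if (n_peaks(spec) == 0) return(NA_integer_)
  rs <- rank_peaks(spec)
  mzs <- if (pid == "alpha") truth$stub_mz_alpha else truth$stub_mz_beta
  if (length(mzs) == 0) return(NA_integer_)
  hit <- spec$mz %in% mzs
  if (!any(hit)) return(NA_integer_)
  min(rs$rank[hit])
}

#' Run the full trigger emulation over a dataset
#'
#' For every spectrum: preprocess, detect doublets, select MS3 precursors,
#' and score the triggers against ground truth. Doublet "found" flags and
#' best ranks report whether the generator planted the doublet (the
#' annotatable prevalence); "triggered" flags report the detection outcome.
#'
#' @param dataset An \code{xl_dataset} from \code{\link{generate_dataset}}.
#' @param params An \code{xl_detect_params}.
#' @return Records data.frame (one row per spectrum) with the columns the
#'   metrics module consumes.
#' @export
run_trigger_simulation <- function(dataset, params = detect_params()) {
  xl <- dataset$config$xl
  rows <- lapply(seq_along(dataset$spectra), function(i) {
    spec <- dataset$spectra[[i]]
    truth <- dataset$truths[[i]]
    det <- detect_spectrum(spec, xl, params)
    ev <- evaluate_triggers(det$triggers, truth, tol_ppm = params$tol_ppm)
    is_csm <- truth$class == "crosslinked"
    data.frame(
      scan_id = truth$scan_id, class = truth$class,
      stub_sum = truth$stub_sum, backbone_sum = truth$backbone_sum,
      doublet_alpha_found = length(truth$stub_mz_alpha) > 0,
      doublet_beta_found = if (is_csm) length(truth$stub_mz_beta) > 0 else NA,
      best_rank_alpha = stub_best_rank(spec, truth, "alpha", params),
      best_rank_beta = if (is_csm) stub_best_rank(spec, truth, "beta", params)
                       else NA_integer_,
      n_ms3_triggered = ev$n_triggers,
      alpha_triggered = ev$alpha_triggered,
      beta_triggered = if (is_csm) ev$beta_triggered else NA,
      n_false_triggers = ev$n_false_triggers
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary report over a records table
#'
#' Convenience wrapper assembling the dataset-level statistics into one
#' list (used by the \code{metrics} CLI command).
#'
#' @param records Records data.frame (see
#'   \code{\link{run_trigger_simulation}}).
#' @return Nested list of statistics.
#' @export
metrics_report <- function(records) {
  out <- list()
  csm <- records[records$class == "crosslinked", , drop = FALSE]
  if (nrow(csm) > 0) {
    out$orthogonality <- orthogonality_stats(csm)
    out$doublet_prevalence <- doublet_prevalence(csm)
    out$trigger_sensitivity <- trigger_sensitivity(csm)
    out$rank_cutoff_curve <- rank_cutoff_curve(csm)
    out$representative_scan <- representative_spectrum(
      csm[csm$stub_sum > 0 & csm$backbone_sum > 0, , drop = FALSE])
  }
  out$ms3_trigger_stats <- ms3_trigger_stats(records)
  out
}
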