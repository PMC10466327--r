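## Signature-doublet detection and MS3-trigger selection.
##
## A doublet is a pair of peaks in one MS2 spectrum whose neutral mass
## difference at some assumed charge matches one of the crosslinker's
## delta-mass variants within a ppm tolerance. Detected doublets are
## deduplicated within a +/-1.5 m/z trigger window (emulating the vendor
## exclusion-list behaviour) and converted into an ordered MS3 precursor
## list.

#' Find stub-pair doublets in a spectrum
#'
#' Returns every peak pair (i, j) with mz_j > mz_i and assumed charge z such
#' that |(mz_j - mz_i) * z - delta| <= tol_ppm * 1e-6 * (mz_j * z) for some
#' delta variant. The ppm reference mass is the heavy peak's charge-scaled
#' m/z, and each (i, j, z) is reported once with the closest-matching
#' variant (ties to the smaller variant).
#'
#' @param spectrum An \code{xl_ranked_spectrum} (see \code{\link{rank_peaks}}).
#' @param deltas An \code{xl_delta_set} or numeric vector of delta variants
#'   (Da).
#' @param tol_ppm Mass tolerance in ppm (default 5, the optimized value).
#' @param charges Assumed fragment charges to test (default 1).
#' @param max_rank If set, only pairs in which at least one peak has
#'   intensity rank <= max_rank are reported (acquisition emulation uses
#'   20).
#' @return A data.frame of class \code{xl_doublet_matches} with columns
#'   \code{light_idx}, \code{heavy_idx}, \code{charge}, \code{variant},
#'   \code{ppm_error}, \code{light_mz}, \code{heavy_mz},
#'   \code{summed_intensity}, \code{best_rank}.
#' @export
find_doublets <- function(spectrum, deltas, tol_ppm = 5, charges = 1L,
                          max_rank = NULL) {
  if (!inherits(spectrum, "xl_ranked_spectrum"))
    stop("find_doublets needs a ranked spectrum (see rank_peaks)",
         call. = FALSE)
  stopifnot(tol_ppm > 0, length(charges) >= 1)
  variants <- as_delta_variants(deltas)
  mz <- spectrum$mz
  if (is.unsorted(mz)) stop("spectrum peaks must be sorted by m/z",
                            call. = FALSE)
  n <- length(mz)
  empty <- empty_doublet_matches()
  if (n < 2) return(empty)
  t <- tol_ppm * 1e-6
  li <- hi <- zz <- integer(0)
  for (z in sort(unique(as.integer(charges)))) {
    for (d in variants) {
      centers <- mz + d / z
      ## candidate windows are slightly widened; the exact tolerance
      ## condition is re-applied below, so this only affects speed
      lo_idx <- findInterval(centers / (1 + t) - 1e-9, mz) + 1L
      hi_idx <- findInterval(centers / (1 - t) + 1e-9, mz)
      cnt <- pmax(hi_idx - lo_idx + 1L, 0L)
      if (!any(cnt > 0)) next
      i <- rep.int(seq_len(n), cnt)
      j <- unlist(lapply(seq_len(n)[cnt > 0], function(k)
        seq.int(lo_idx[k], hi_idx[k])), use.names = FALSE)
      li <- c(li, i); hi <- c(hi, j); zz <- c(zz, rep.int(z, length(i)))
    }
  }
  if (length(li) == 0) return(empty)
  ## unique (i, j, z), then pick the closest variant for each
  key <- paste(li, hi, zz)
  keep <- !duplicated(key)
  li <- li[keep]; hi <- hi[keep]; zz <- zz[keep]
  obs <- (mz[hi] - mz[li]) * zz
  err_mat <- outer(obs, variants, "-")
  best <- max.col(-abs(err_mat), ties.method = "first")
  variant <- variants[best]
  err <- obs - variant
  ok <- abs(err) <= t * mz[hi] * zz & hi > li  # exact tolerance condition
  out <- data.frame(
    light_idx = li[ok], heavy_idx = hi[ok], charge = zz[ok],
    variant = variant[ok],
    ppm_error = 1e6 * err[ok] / (mz[hi[ok]] * zz[ok]),
    light_mz = mz[li[ok]], heavy_mz = mz[hi[ok]],
    summed_intensity = spectrum$intensity[li[ok]] + spectrum$intensity[hi[ok]],
    best_rank = pmin(spectrum$rank[li[ok]], spectrum$rank[hi[ok]])
  )
  if (!is.null(max_rank)) out <- out[out$best_rank <= max_rank, , drop = FALSE]
  out <- out[order(out$light_idx, out$heavy_idx, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xl_doublet_matches", "data.frame")
  out
}

empty_doublet_matches <- function() {
  out <- data.frame(light_idx = integer(0), heavy_idx = integer(0),
                    charge = integer(0), variant = numeric(0),
                    ppm_error = numeric(0), light_mz = numeric(0),
                    heavy_mz = numeric(0), summed_intensity = numeric(0),
                    best_rank = integer(0))
  class(out) <- c("xl_doublet_matches", "data.frame")
  out
}

trigger_mz_of <- function(matches, trigger_on = c("heavy", "light")) {
  trigger_on <- match.arg(trigger_on)
  if (trigger_on == "heavy") matches$heavy_mz else matches$light_mz
}

#' Deduplicate doublet matches within a trigger m/z window
#'
#' Matches are processed in descending summed intensity (ties to the lower
#' trigger m/z, then lower light m/z); a match is kept only if its trigger
#' m/z lies farther than \code{window_mz} from every previously kept match's
#' trigger m/z. This prevents multiple MS3 triggers on the same doublet
#' cluster (hydrogen-shift satellites).
#'
#' @param matches An \code{xl_doublet_matches} data.frame.
#' @param spectrum Spectrum the matches refer to (kept for interface
#'   symmetry; trigger m/z is carried on the matches).
#' @param window_mz Half-window in Th (default 1.5).
#' @param trigger_on Which doublet peak is the MS3 precursor: "heavy"
#'   (default) or "light".
#' @return The surviving matches, in the greedy processing order.
#' @export
dedupe_window <- function(matches, spectrum = NULL, window_mz = 1.5,
                          trigger_on = c("heavy", "light")) {
  stopifnot(window_mz >= 0)
  trigger_on <- match.arg(trigger_on)
  if (nrow(matches) == 0) return(matches)
  tmz <- trigger_mz_of(matches, trigger_on)
  ord <- order(-matches$summed_intensity, tmz, matches$light_mz)
  kept_mz <- numeric(0)
  kept <- integer(0)
  for (k in ord) {
    if (length(kept_mz) == 0 || all(abs(tmz[k] - kept_mz) > window_mz)) {
      kept <- c(kept, k)
      kept_mz <- c(kept_mz, tmz[k])
    }
  }
  out <- matches[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select MS3 precursors from doublet matches
#'
#' Applies the \code{\link{dedupe_window}} filter, orders the surviving
#' matches by descending summed intensity and truncates to
#' \code{max_triggers}. The MS3 precursor is by default the heavier doublet
#' peak at the match's assumed charge.
#'
#' @param matches An \code{xl_doublet_matches} data.frame.
#' @param spectrum Spectrum the matches refer to.
#' @param max_triggers Maximum number of MS3 precursors (>= 1).
#' @param window_mz Dedup half-window in Th (default 1.5).
#' @param trigger_on "heavy" (default) or "light".
#' @return A data.frame of class \code{xl_trigger_list} with columns
#'   \code{precursor_mz}, \code{charge}, plus the source-match columns.
#' @export
select_ms3_precursors <- function(matches, spectrum = NULL, max_triggers = 5L,
                                  window_mz = 1.5,
                                  trigger_on = c("heavy", "light")) {
  stopifnot(max_triggers >= 1)
  trigger_on <- match.arg(trigger_on)
  surv <- dedupe_window(matches, spectrum, window_mz, trigger_on)
  if (nrow(surv) > 0) {
    ord <- order(-surv$summed_intensity, trigger_mz_of(surv, trigger_on))
    surv <- surv[ord, , drop = FALSE]
    surv <- utils::head(surv, max_triggers)
  }
  out <- cbind(data.frame(precursor_mz = trigger_mz_of(surv, trigger_on),
                          charge = surv$charge),
               surv[, setdiff(names(surv), "charge"), drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("xl_trigger_list", "data.frame")
  out
}

#' Score a trigger list against synthetic ground truth
#'
#' A trigger counts for a peptide if its precursor m/z matches any of that
#' peptide's true stub-peak m/z within \code{tol_ppm}; a trigger matching
#' neither peptide's stub peaks is a false trigger.
#'
#' @param triggers An \code{xl_trigger_list}.
#' @param truth A synthetic-truth object (see
#'   \code{\link{generate_csm_spectrum}}) carrying \code{stub_mz_alpha} /
#'   \code{stub_mz_beta}.
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @return List with \code{n_triggers}, \code{alpha_triggered},
#'   \code{beta_triggered}, \code{n_false_triggers}.
#' @export
evaluate_triggers <- function(triggers, truth, tol_ppm = 5) {
  hits <- function(mz, targets) {
    if (length(targets) == 0 || length(mz) == 0)
      return(rep(FALSE, length(mz)))
    vapply(mz, function(m)
      any(abs(m - targets) <= tol_ppm * 1e-6 * targets), logical(1))
  }
  mzs <- triggers$precursor_mz
  a <- hits(mzs, truth$stub_mz_alpha)
  b <- hits(mzs, truth$stub_mz_beta)
  list(n_triggers = length(mzs),
       alpha_triggered = any(a),
       beta_triggered = any(b),
       n_false_triggers = sum(!a & !b))
}
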