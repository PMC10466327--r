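## Centroided peak-list data model and the preprocessing steps applied
## before doublet detection and annotation: precursor removal, intensity
## ranking, median mass error and ppm recalibration. Operations are pure —
## they return new spectra.

#' Construct a centroided spectrum
#'
#' @param mz Numeric vector of peak m/z (Th), any order; stored sorted.
#' @param intensity Numeric vector of non-negative intensities, parallel to
#'   \code{mz}.
#' @param precursor_mz Precursor m/z (Th) or \code{NA}.
#' @param precursor_charge Positive integer precursor charge or \code{NA}.
#' @param scan_id Identifier string.
#' @param ms_level 2 or 3.
#' @param metadata Named list of free-form header strings.
#' @return An object of class \code{xl_spectrum}.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_, scan_id = "scan",
                     ms_level = 2L, metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("m/z values must be finite and positive", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (!is.na(precursor_charge)) {
    precursor_charge <- as.integer(precursor_charge)
    if (precursor_charge < 1) stop("precursor_charge must be positive",
                                   call. = FALSE)
  }
  ord <- order(mz)
  structure(
    list(mz = mz[ord], intensity = intensity[ord],
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = precursor_charge,
         scan_id = as.character(scan_id), ms_level = as.integer(ms_level),
         metadata = metadata),
    class = "xl_spectrum"
  )
}

#' @export
print.xl_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s  MS%d  %d peaks", x$scan_id, x$ms_level,
              length(x$mz)))
  if (!is.na(x$precursor_mz))
    cat(sprintf("  precursor %.4f %s", x$precursor_mz,
                if (is.na(x$precursor_charge)) ""
                else sprintf("%d+", x$precursor_charge)))
  cat(">\n")
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param spectrum An \code{xl_spectrum}.
#' @return Integer peak count.
#' @export
n_peaks <- function(spectrum) length(spectrum$mz)

## replace peaks keeping metadata; re-sorts
replace_peaks <- function(s, mz, intensity) {
  s$mz <- as.numeric(mz)
  s$intensity <- as.numeric(intensity)
  ord <- order(s$mz)
  s$mz <- s$mz[ord]
  s$intensity <- s$intensity[ord]
  if (inherits(s, "xl_ranked_spectrum")) {
    s$rank <- NULL
    class(s) <- "xl_spectrum"
  }
  s
}

## m/z values at which the precursor (and, if charge is known, its
## charge-reduced species) appear
precursor_species_mz <- function(s, charge_reduced = TRUE) {
  if (is.na(s$precursor_mz)) return(numeric(0))
  out <- s$precursor_mz
  z <- s$precursor_charge
  if (charge_reduced && !is.na(z) && z > 1) {
    M <- s$precursor_mz * z - z * PROTON_MASS
    zr <- seq_len(z - 1)
    out <- c(out, (M + zr * PROTON_MASS) / zr)
  }
  out
}

#' Remove precursor peaks from a spectrum
#'
#' Removes all peaks within \code{window_mz} of the precursor m/z and, when
#' the precursor charge is known and \code{charge_reduced} is TRUE, of each
#' charge-reduced precursor species m/z ((M + z'·proton)/z' for z' < z).
#'
#' @param spectrum An \code{xl_spectrum}.
#' @param window_mz Half-window in Th (default 2.0).
#' @param charge_reduced Also remove charge-reduced species (default TRUE).
#' @return A new \code{xl_spectrum}.
#' @export
remove_precursor <- function(spectrum, window_mz = 2.0, charge_reduced = TRUE) {
  stopifnot(window_mz > 0)
  targets <- precursor_species_mz(spectrum, charge_reduced)
  if (length(targets) == 0 || n_peaks(spectrum) == 0) return(spectrum)
  drop <- rep(FALSE, n_peaks(spectrum))
  for (t in targets) drop <- drop | abs(spectrum$mz - t) <= window_mz
  replace_peaks(spectrum, spectrum$mz[!drop], spectrum$intensity[!drop])
}

#' Rank peaks by intensity
#'
#' Rank 1 is the most intense peak; intensity ties are broken in favour of
#' the lower m/z. Ranks are a permutation of 1..n.
#'
#' @param spectrum A non-empty \code{xl_spectrum}.
#' @return An \code{xl_ranked_spectrum} (spectrum plus \code{rank} vector).
#' @export
rank_peaks <- function(spectrum) {
  if (n_peaks(spectrum) == 0) stop("cannot rank an empty spectrum",
                                   call. = FALSE)
  ord <- order(-spectrum$intensity, spectrum$mz)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  spectrum$rank <- rank
  class(spectrum) <- c("xl_ranked_spectrum", class(spectrum))
  spectrum
}

#' Median mass error in ppm
#'
#' @param matched Two-column matrix or data.frame of (observed m/z,
#'   theoretical m/z) pairs.
#' @return Median of 1e6 * (obs - theo) / theo.
#' @export
median_ppm_error <- function(matched) {
  matched <- as.matrix(matched)
  if (nrow(matched) == 0) stop("no matched peaks", call. = FALSE)
  stats::median(1e6 * (matched[, 1] - matched[, 2]) / matched[, 2])
}

#' Recalibrate a spectrum by a ppm offset
#'
#' Divides every fragment m/z and the precursor m/z by
#' (1 + ppm_offset * 1e-6), so that applying \code{median_ppm_error}'s
#' estimate brings the median error to zero.
#'
#' @param spectrum An \code{xl_spectrum}.
#' @param ppm_offset Signed ppm offset to remove.
#' @return A new \code{xl_spectrum}.
#' @export
recalibrate <- function(spectrum, ppm_offset) {
  stopifnot(is.finite(ppm_offset))
  f <- 1 / (1 + ppm_offset * 1e-6)
  s <- replace_peaks(spectrum, spectrum$mz * f, spectrum$intensity)
  if (!is.na(s$precursor_mz)) s$precursor_mz <- s$precursor_mz * f
  s
}
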