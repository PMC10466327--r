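## Theoretical fragment generation and greedy spectrum annotation.
##
## Backbone fragments use the conventional series offsets (b = prefix sum +
## proton; a = b - CO; c = b + NH3; y = suffix sum + water + proton;
## z-dot = y - NH3 + H; x = y + CO - H2). Stub fragments are the whole
## peptide plus one crosslinker stub. Annotation assigns candidate
## (peak, fragment) pairs greedily by absolute ppm error, one-to-one.

BACKBONE_SERIES <- c("a", "b", "c", "x", "y", "z")

#' Theoretical backbone fragments of a peptide
#'
#' @param peptide An \code{xl_peptide} or sequence string.
#' @param series Subset of \code{c("a","b","c","x","y","z")}.
#' @param charges Positive integer charges (default 1).
#' @param link_mod Mass (Da) added to every fragment that contains the
#'   peptide's link site (e.g. a stub mass for a stub-modified
#'   interpretation); default 0 annotates the bare backbone.
#' @param z_dot Use the z-dot (z+1H) radical convention for z ions
#'   (default TRUE).
#' @return data.frame with columns \code{series}, \code{index},
#'   \code{charge}, \code{shift} (always 0), \code{mz}.
#' @export
backbone_fragments <- function(peptide, series = c("a", "b", "y"),
                               charges = 1L, link_mod = 0, z_dot = TRUE) {
  pep <- as_peptide(peptide)
  series <- match.arg(series, BACKBONE_SERIES, several.ok = TRUE)
  stopifnot(all(charges >= 1))
  res <- residue_mass_vector(pep)
  n <- length(res)
  if (n < 2) return(fragment_frame())
  idx <- seq_len(n - 1L)
  prefix <- cumsum(res)[idx]                      # residues 1..i
  suffix <- rev(cumsum(rev(res)))[-1]             # residues (i+1)..n
  ls <- pep$link_site
  pre_has_link <- if (is.na(ls)) rep(FALSE, n - 1L) else idx >= ls
  suf_has_link <- if (is.na(ls)) rep(FALSE, n - 1L) else idx < ls
  out <- list()
  for (ser in series) {
    nterm <- ser %in% c("a", "b", "c")
    neutral <- if (nterm) {
      base <- prefix + ifelse(pre_has_link, link_mod, 0)
      switch(ser, b = base, a = base - CO_MASS, c = base + NH3_MASS)
    } else {
      base <- suffix + WATER_MASS + ifelse(suf_has_link, link_mod, 0)
      switch(ser,
             y = base,
             z = base - NH3_MASS + if (z_dot) H_ATOM_MASS else 0,
             x = base + CO_MASS - 2 * H_ATOM_MASS)
    }
    ## index counts cleavage position from the series' own terminus
    index <- if (nterm) idx else rev(idx)
    for (z in sort(unique(as.integer(charges)))) {
      out[[length(out) + 1L]] <- data.frame(
        series = ser, index = index, charge = z, shift = 0L,
        mz = (neutral + z * PROTON_MASS) / z
      )
    }
  }
  do.call(rbind, out)
}

fragment_frame <- function() {
  data.frame(series = character(0), index = integer(0), charge = integer(0),
             shift = integer(0), mz = numeric(0))
}

#' Theoretical stub fragments of a peptide
#'
#' Full cross product of stub labels x hydrogen shifts x charges for one
#' peptide.
#'
#' @param peptide An \code{xl_peptide} or sequence string.
#' @param xl An \code{xl_crosslinker}.
#' @param labels Stub labels (default: all of the crosslinker's).
#' @param shifts Integer H offsets (default: the crosslinker's configured
#'   shifts).
#' @param charges Positive integer charges (default 1).
#' @return data.frame with columns \code{series} ("stub"), \code{label},
#'   \code{charge}, \code{shift}, \code{mz}.
#' @export
stub_fragments <- function(peptide, xl, labels = names(xl$stubs),
                           shifts = xl$hydrogen_shifts, charges = 1L) {
  pep <- as_peptide(peptide)
  grid <- expand.grid(label = labels, shift = as.integer(shifts),
                      charge = sort(unique(as.integer(charges))),
                      stringsAsFactors = FALSE)
  grid$series <- "stub"
  grid$mz <- mapply(function(lab, sh, z)
    stub_fragment_mz(pep, xl, lab, sh, z),
    grid$label, grid$shift, grid$charge)
  grid[, c("series", "label", "charge", "shift", "mz")]
}

## build the candidate fragment table for a CSM (both peptides)
csm_fragment_table <- function(alpha, beta, xl, series, charges, shifts,
                               z_dot = TRUE) {
  mk <- function(pep, id) {
    bb <- backbone_fragments(pep, series = series, charges = charges,
                             z_dot = z_dot)
    bb$label <- NA_character_
    st <- stub_fragments(pep, xl, shifts = shifts, charges = charges)
    st$index <- NA_integer_
    cols <- c("series", "index", "label", "charge", "shift", "mz")
    out <- rbind(bb[, cols], st[, cols])
    out$peptide_id <- id
    out
  }
  frags <- rbind(mk(alpha, "alpha"),
                 if (!is.null(beta)) mk(beta, "beta"))
  frags[order(frags$mz), , drop = FALSE]
}

#' Annotate a spectrum against a crosslink-spectrum match
#'
#' Generates theoretical backbone and stub fragments for both peptides and
#' assigns them to peaks greedily: all candidate (peak, fragment) pairs
#' within \code{tol_ppm} are sorted by absolute ppm error (ties: lower peak
#' m/z, then fragment table order) and assigned one-to-one.
#'
#' @param spectrum An \code{xl_spectrum}.
#' @param alpha,beta \code{xl_peptide}s (beta may be NULL for a linear
#'   peptide).
#' @param xl An \code{xl_crosslinker}.
#' @param series Backbone series to annotate (default a, b, y).
#' @param charges Fragment charges (default 1).
#' @param shifts Hydrogen shifts for stub fragments (default: the
#'   crosslinker's).
#' @param tol_ppm Annotation tolerance in ppm (default 10).
#' @param z_dot z-ion convention (see \code{\link{backbone_fragments}}).
#' @return An \code{xl_annotated_spectrum}: the spectrum plus an
#'   \code{annotations} data.frame (one row per annotated peak) with columns
#'   \code{peak_idx}, \code{series}, \code{index}, \code{label},
#'   \code{peptide_id}, \code{charge}, \code{shift}, \code{theo_mz},
#'   \code{ppm_error}.
#' @export
annotate_spectrum <- function(spectrum, alpha, beta, xl,
                              series = c("a", "b", "y"), charges = 1L,
                              shifts = xl$hydrogen_shifts, tol_ppm = 10,
                              z_dot = TRUE) {
  stopifnot(tol_ppm > 0)
  frags <- csm_fragment_table(as_peptide(alpha),
                              if (is.null(beta)) NULL else as_peptide(beta),
                              xl, series, charges, shifts, z_dot)
  ann <- greedy_assign(spectrum$mz, frags, tol_ppm)
  spectrum$annotations <- ann
  class(spectrum) <- unique(c("xl_annotated_spectrum", class(spectrum)))
  spectrum
}

greedy_assign <- function(mz, frags, tol_ppm) {
  empty <- data.frame(peak_idx = integer(0), series = character(0),
                      index = integer(0), label = character(0),
                      peptide_id = character(0), charge = integer(0),
                      shift = integer(0), theo_mz = numeric(0),
                      ppm_error = numeric(0))
  if (length(mz) == 0 || nrow(frags) == 0) return(empty)
  t <- tol_ppm * 1e-6
  ## candidates: peaks within tol of each theoretical mz (ppm of theo mz)
  lo <- findInterval(frags$mz * (1 - t) - 1e-9, mz) + 1L
  hi <- findInterval(frags$mz * (1 + t) + 1e-9, mz)
  cnt <- pmax(hi - lo + 1L, 0L)
  if (!any(cnt > 0)) return(empty)
  fi <- rep.int(seq_len(nrow(frags)), cnt)
  pi <- unlist(lapply(which(cnt > 0), function(k) seq.int(lo[k], hi[k])),
               use.names = FALSE)
  ppm <- 1e6 * (mz[pi] - frags$mz[fi]) / frags$mz[fi]
  keep <- abs(ppm) <= tol_ppm
  fi <- fi[keep]; pi <- pi[keep]; ppm <- ppm[keep]
  if (length(fi) == 0) return(empty)
  ord <- order(abs(ppm), mz[pi], fi)
  used_peak <- logical(length(mz))
  used_frag <- logical(nrow(frags))
  sel <- integer(0)
  for (k in ord) {
    if (!used_peak[pi[k]] && !used_frag[fi[k]]) {
      used_peak[pi[k]] <- TRUE
      used_frag[fi[k]] <- TRUE
      sel <- c(sel, k)
    }
  }
  f <- frags[fi[sel], , drop = FALSE]
  out <- data.frame(peak_idx = pi[sel], series = f$series, index = f$index,
                    label = f$label, peptide_id = f$peptide_id,
                    charge = f$charge, shift = f$shift, theo_mz = f$mz,
                    ppm_error = ppm[sel])
  out <- out[order(out$peak_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summed stub and backbone intensities of an annotated spectrum
#'
#' @param annotated An \code{xl_annotated_spectrum}.
#' @param backbone_series Which series count as backbone (default a, b, y).
#' @return Named list \code{stub_sum}, \code{backbone_sum}; unannotated
#'   peaks count in neither.
#' @export
stub_backbone_sums <- function(annotated, backbone_series = c("a", "b", "y")) {
  ann <- annotated$annotations
  if (is.null(ann) || nrow(ann) == 0)
    return(list(stub_sum = 0, backbone_sum = 0))
  ints <- annotated$intensity[ann$peak_idx]
  list(stub_sum = sum(ints[ann$series == "stub"]),
       backbone_sum = sum(ints[ann$series %in% backbone_series]))
}

#' Precursor cleavage efficiency
#'
#' Defined as 1 minus the fraction of total spectrum intensity carried by
#' surviving precursor species (the precursor peak and, optionally, its
#' charge-reduced forms) within \code{window_mz}. A spectrum that is pure
#' precursor gives 0; one with no precursor signal gives 1.
#'
#' @param spectrum An \code{xl_spectrum} with known precursor m/z.
#' @param window_mz Half-window in Th for identifying precursor peaks
#'   (default 2.0).
#' @param charge_reduced Count charge-reduced precursor species as
#'   survivors (default TRUE).
#' @return Fraction in [0, 1].
#' @export
cleavage_efficiency <- function(spectrum, window_mz = 2.0,
                                charge_reduced = TRUE) {
  total <- sum(spectrum$intensity)
  if (total == 0) return(NA_real_)
  targets <- precursor_species_mz(spectrum, charge_reduced)
  if (length(targets) == 0) return(1)
  surv <- rep(FALSE, n_peaks(spectrum))
  for (tg in targets) surv <- surv | abs(spectrum$mz - tg) <= window_mz
  1 - sum(spectrum$intensity[surv]) / total
}
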