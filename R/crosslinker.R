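## Cleavable-crosslinker definitions: spacer and stub compositions, the
## doublet pair used for MS3 triggering, and the hydrogen-shift model.
## Definitions are plain JSON so corrected stub compositions can be dropped
## in without touching code; UCCL, DSSO and DSBU configs are bundled.

#' Construct a cleavable-crosslinker definition
#'
#' A cleavable crosslinker is described by the elemental composition of its
#' intact spacer (the piece joining the two reacted residues), an ordered set
#' of stub compositions (the remnants left on each peptide after gas-phase
#' cleavage), the stub pair whose characteristic mass difference forms the
#' signature doublet, and the hydrogen-shift offsets its cleavage chemistry
#' can produce (homolytic cleavage followed by H-atom transfer yields +/-1 Da
#' satellite variants).
#'
#' @param name Identifier string.
#' @param spacer Spacer composition (anything \code{\link{as_composition}}
#'   accepts, or a formula string).
#' @param stubs Named list of stub compositions in increasing-mass label
#'   order.
#' @param doublet_pair Character vector of two stub labels (light, heavy)
#'   used for doublet detection.
#' @param hydrogen_shifts Integer vector of H-atom offsets the stubs can
#'   carry (e.g. \code{-2:2}).
#' @param complementary_pairs List of label pairs that together reconstitute
#'   the spacer (one stub on each peptide). Checked exactly at construction.
#' @return An object of class \code{xl_crosslinker}.
#' @export
crosslinker <- function(name, spacer, stubs, doublet_pair,
                        hydrogen_shifts = 0L, complementary_pairs = list()) {
  stopifnot(is.character(name), length(name) == 1)
  spacer <- if (is.character(spacer)) parse_formula(spacer) else as_composition(spacer)
  stopifnot(is.list(stubs), length(stubs) >= 2, !is.null(names(stubs)))
  stubs <- lapply(stubs, function(s)
    if (is.character(s)) parse_formula(s) else as_composition(s))
  masses <- vapply(stubs, monoisotopic_mass, numeric(1))
  if (any(diff(masses) <= 0))
    stop("stub masses must be strictly increasing in the declared label order",
         call. = FALSE)
  stopifnot(length(doublet_pair) == 2, all(doublet_pair %in% names(stubs)))
  if (masses[doublet_pair[1]] >= masses[doublet_pair[2]])
    stop("doublet_pair must be ordered (light, heavy)", call. = FALSE)
  hydrogen_shifts <- sort(unique(as.integer(hydrogen_shifts)))
  for (pair in complementary_pairs) {
    stopifnot(length(pair) == 2, all(pair %in% names(stubs)))
    if (!isTRUE(stubs[[pair[1]]] + stubs[[pair[2]]] == spacer))
      stop("complementary stub pair ", pair[1], "+", pair[2],
           " does not sum to the spacer composition", call. = FALSE)
  }
  structure(
    list(name = name, spacer = spacer, stubs = stubs,
         doublet_pair = doublet_pair, hydrogen_shifts = hydrogen_shifts,
         complementary_pairs = complementary_pairs),
    class = "xl_crosslinker"
  )
}

#' @export
print.xl_crosslinker <- function(x, ...) {
  cat(sprintf("<crosslinker %s  spacer %.6f Da>\n", x$name,
              monoisotopic_mass(x$spacer)))
  sm <- stub_masses(x)
  for (lab in names(sm)) cat(sprintf("  stub %-5s %12.6f Da\n", lab, sm[[lab]]))
  cat(sprintf("  doublet pair %s-%s, hydrogen shifts {%s}\n",
              x$doublet_pair[1], x$doublet_pair[2],
              paste(x$hydrogen_shifts, collapse = ",")))
  invisible(x)
}

#' Read a crosslinker definition from JSON
#'
#' The JSON layout is
#' \code{\{"name": ..., "spacer": \{"C": 12, ...\}, "stubs": \{label:
#' composition, ...\}, "doublet_pair": [light, heavy], "hydrogen_shifts":
#' [ints], "complementary_pairs": [[l1, l2], ...]\}}.
#'
#' @param path Path to a JSON file, or one of the bundled names
#'   \code{"uccl"}, \code{"dsso"}, \code{"dsbu"}.
#' @return An \code{xl_crosslinker}.
#' @examples
#' load_crosslinker("uccl")
#' @export
load_crosslinker <- function(path) {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", "crosslinkers",
                           paste0(tolower(path), ".json"),
                           package = "xldoublet")
    if (nzchar(bundled)) path <- bundled
  }
  if (!file.exists(path))
    stop("crosslinker config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  crosslinker(
    name = cfg$name,
    spacer = cfg$spacer,
    stubs = cfg$stubs,
    doublet_pair = unlist(cfg$doublet_pair),
    hydrogen_shifts = unlist(cfg$hydrogen_shifts),
    complementary_pairs = lapply(cfg$complementary_pairs, unlist)
  )
}

#' Stub masses of a crosslinker
#'
#' @param xl An \code{xl_crosslinker}.
#' @return Named numeric vector of stub monoisotopic masses (Da), in the
#'   declared label order.
#' @examples
#' stub_masses(load_crosslinker("uccl"))
#' @export
stub_masses <- function(xl) {
  stopifnot(inherits(xl, "xl_crosslinker"))
  vapply(xl$stubs, monoisotopic_mass, numeric(1))
}

#' Doublet delta-mass set
#'
#' The signature doublet delta is the mass difference between the heavy and
#' light stub of the doublet pair; hydrogen-shift variants add integer
#' multiples of the H-atom mass.
#'
#' @param xl An \code{xl_crosslinker}.
#' @param shifts Integer H-atom offsets to apply to the base delta
#'   (default: the three most commonly observed, \code{c(0, 1, 2)}).
#' @return An object of class \code{xl_delta_set} with fields
#'   \code{base_delta}, \code{shifts} and sorted \code{variants} (Da).
#' @examples
#' doublet_delta_set(load_crosslinker("uccl"), shifts = c(0, 1, 2))
#' @export
doublet_delta_set <- function(xl, shifts = c(0L, 1L, 2L)) {
  stopifnot(inherits(xl, "xl_crosslinker"))
  if (length(shifts) == 0) stop("shifts must be non-empty", call. = FALSE)
  shifts <- sort(unique(as.integer(shifts)))
  sm <- stub_masses(xl)
  base <- unname(sm[xl$doublet_pair[2]] - sm[xl$doublet_pair[1]])
  variants <- sort(base + shifts * H_ATOM_MASS)
  structure(list(base_delta = base, shifts = shifts, variants = variants),
            class = "xl_delta_set")
}

#' @export
print.xl_delta_set <- function(x, ...) {
  cat(sprintf("<delta set  base %.6f Da  variants {%s}>\n", x$base_delta,
              paste(sprintf("%.6f", x$variants), collapse = ", ")))
  invisible(x)
}

as_delta_variants <- function(deltas) {
  if (inherits(deltas, "xl_delta_set")) deltas$variants
  else sort(unique(as.numeric(deltas)))
}

#' Theoretical m/z of a peptide stub fragment
#'
#' m/z of the whole peptide carrying one crosslinker stub, an optional
#' hydrogen shift, and \code{charge} protons.
#'
#' @param peptide An \code{xl_peptide} or sequence string.
#' @param xl An \code{xl_crosslinker}.
#' @param label Stub label.
#' @param shift Integer H-atom offset (default 0).
#' @param charge Positive integer charge.
#' @return m/z in Th.
#' @export
stub_fragment_mz <- function(peptide, xl, label, shift = 0L, charge = 1L) {
  stopifnot(inherits(xl, "xl_crosslinker"))
  if (!label %in% names(xl$stubs))
    stop("unknown stub label: ", label, call. = FALSE)
  if (length(charge) != 1 || charge < 1 || charge != round(charge))
    stop("charge must be a positive integer", call. = FALSE)
  m <- peptide_mass(peptide) + monoisotopic_mass(xl$stubs[[label]]) +
    shift * H_ATOM_MASS
  (m + charge * PROTON_MASS) / charge
}
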