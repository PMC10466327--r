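## Peptides and residue masses. Residue monoisotopic masses are derived from
## elemental compositions at load time so the residue table and the
## composition arithmetic cannot drift apart.

RESIDUE_FORMULAS <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Monoisotopic residue masses
#'
#' Residue (amino-acid minus water) monoisotopic masses for the 20 standard
#' amino acids, derived from their elemental compositions.
#'
#' @return Named numeric vector (Da).
#' @export
residue_masses <- function() {
  vapply(RESIDUE_FORMULAS, monoisotopic_mass, numeric(1))
}

.residue_mass_table <- NULL  # filled in .onLoad-free lazy accessor below

residue_mass_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- residue_masses()
    tab
  }
})

#' Construct a peptide
#'
#' @param sequence Uppercase residue string over the 20 standard amino acids.
#' @param link_site 1-based residue index of the crosslinked residue, or
#'   \code{NA} if none.
#' @param fixed_mods Named numeric vector of fixed modification mass deltas
#'   (Da) keyed by residue letter, e.g. \code{c(C = 57.02146)} for
#'   carbamidomethylation. Applied to every matching residue.
#' @return An object of class \code{xl_peptide}.
#' @examples
#' peptide("AKLHDYYK", link_site = 2)
#' @export
peptide <- function(sequence, link_site = NA_integer_, fixed_mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("peptide sequence must be non-empty", call. = FALSE)
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(RESIDUE_FORMULAS))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (!is.na(link_site)) {
    link_site <- as.integer(link_site)
    if (link_site < 1L || link_site > length(residues))
      stop("link_site outside sequence length", call. = FALSE)
  }
  if (!is.null(fixed_mods)) {
    stopifnot(is.numeric(fixed_mods), !is.null(names(fixed_mods)))
  }
  structure(
    list(sequence = sequence, residues = residues,
         link_site = link_site, fixed_mods = fixed_mods),
    class = "xl_peptide"
  )
}

as_peptide <- function(x, link_site = NA_integer_) {
  if (inherits(x, "xl_peptide")) x else peptide(x, link_site = link_site)
}

#' @export
print.xl_peptide <- function(x, ...) {
  cat(sprintf("<peptide %s  M = %.6f Da", x$sequence, peptide_mass(x)))
  if (!is.na(x$link_site)) cat(sprintf("  link site %d (%s)",
                                       x$link_site, x$residues[x$link_site]))
  cat(">\n")
  invisible(x)
}

## per-residue masses incl. fixed modifications
residue_mass_vector <- function(pep) {
  m <- residue_mass_table()[pep$residues]
  if (!is.null(pep$fixed_mods)) {
    hit <- match(pep$residues, names(pep$fixed_mods))
    add <- ifelse(is.na(hit), 0, pep$fixed_mods[hit])
    m <- m + add
  }
  unname(m)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, with fixed modifications applied.
#'
#' @param peptide An \code{xl_peptide} or sequence string.
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")  # 75.032028
#' @export
peptide_mass <- function(peptide) {
  pep <- as_peptide(peptide)
  sum(residue_mass_vector(pep)) + WATER_MASS
}
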