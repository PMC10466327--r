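## Elemental-composition arithmetic.
##
## Compositions are named non-negative integer vectors over element symbols.
## All stub, spacer and residue masses in the package derive from this single
## atomic-mass table, so complementarity checks are exact at integer level.

#' Monoisotopic atomic masses
#'
#' Named vector of monoisotopic atomic masses (Da) for the elements the
#' package knows about. Bundled so that all mass arithmetic is deterministic
#' and offline.
#'
#' @format Named numeric vector (Da).
#' @export
atomic_masses <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  Se = 79.9165218
)

#' Mass constants
#'
#' Monoisotopic masses (Da) of the proton, the hydrogen atom, water, ammonia
#' and carbon monoxide, used throughout fragment m/z arithmetic.
#'
#' @name mass-constants
#' @export
PROTON_MASS <- 1.00727646688

#' @rdname mass-constants
#' @export
H_ATOM_MASS <- 1.0078250319

#' @rdname mass-constants
#' @export
WATER_MASS <- 2 * 1.0078250319 + 15.9949146221

#' @rdname mass-constants
#' @export
NH3_MASS <- 14.0030740052 + 3 * 1.0078250319

#' @rdname mass-constants
#' @export
CO_MASS <- 12.0 + 15.9949146221

#' Construct an elemental composition
#'
#' @param ... Element counts, e.g. \code{composition(C = 3, H = 2, O = 1)}.
#'   Counts must be non-negative integers; zero counts are dropped.
#' @return An object of class \code{xl_composition}: a named integer vector.
#' @examples
#' composition(C = 3, H = 2, O = 1)          # the DSSO alkene stub
#' monoisotopic_mass(composition(H = 2, O = 1))
#' @export
composition <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)
  as_composition(counts)
}

#' Coerce a named count vector or list to a composition
#'
#' @param x Named numeric/integer vector or list of element counts.
#' @return An \code{xl_composition}.
#' @export
as_composition <- function(x) {
  if (inherits(x, "xl_composition")) return(x)
  x <- unlist(x)
  if (length(x) == 0) {
    out <- integer(0)
    class(out) <- "xl_composition"
    return(out)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("composition counts must be named by element symbol", call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers", call. = FALSE)
  unknown <- setdiff(names(x), names(atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  x <- x[x > 0]
  counts <- as.integer(x[order(names(x))])
  names(counts) <- sort(names(x))
  class(counts) <- "xl_composition"
  counts
}

#' Parse a molecular formula string
#'
#' Parses formulas such as \code{"C10H10OS2"} into a composition. Element
#' symbols follow the usual one-capital(-one-lowercase) convention; a missing
#' count means 1.
#'
#' @param formula Character scalar.
#' @return An \code{xl_composition}.
#' @examples
#' parse_formula("C8H8")   # the UCCL B-C doublet delta composition
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!nzchar(formula)) return(composition())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("cannot parse formula: ", formula, call. = FALSE)
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(cnts, syms, sum)
  as_composition(stats::setNames(as.integer(out), names(out)))
}

comp_align <- function(a, b) {
  elems <- sort(union(names(a), names(b)))
  av <- stats::setNames(integer(length(elems)), elems)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  list(a = av, b = bv, elems = elems)
}

#' @export
`+.xl_composition` <- function(e1, e2) {
  al <- comp_align(as_composition(e1), as_composition(e2))
  as_composition(al$a + al$b)
}

#' @export
`-.xl_composition` <- function(e1, e2) {
  al <- comp_align(as_composition(e1), as_composition(e2))
  d <- al$a - al$b
  if (any(d < 0))
    stop("composition subtraction would yield negative counts for: ",
         paste(al$elems[d < 0], collapse = ", "), call. = FALSE)
  as_composition(d)
}

#' @export
`==.xl_composition` <- function(e1, e2) {
  al <- comp_align(as_composition(e1), as_composition(e2))
  all(al$a == al$b)
}

#' @export
print.xl_composition <- function(x, ...) {
  if (length(x) == 0) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(x), ifelse(x > 1, x, "")), sep = "")
    cat(sprintf("  (%.6f Da)\n", monoisotopic_mass(x)))
  }
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' @param composition An \code{xl_composition}, named count vector, list, or
#'   formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  composition <- as_composition(composition)
  if (length(composition) == 0) return(0)
  sum(as.numeric(composition) * atomic_masses[names(composition)])
}
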