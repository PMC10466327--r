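## Mascot Generic Format reading and writing. The dialect recognises TITLE,
## PEPMASS (m/z with optional intensity), CHARGE ("3+"/"2-"), SCANS,
## RTINSECONDS and MSLEVEL; unknown "KEY=value" headers are preserved in the
## spectrum metadata so a read/write cycle is lossless. Gzip input is
## accepted (by .gz extension).

#' Read spectra from an MGF file
#'
#' @param path Path to an MGF file (optionally gzip-compressed, by
#'   extension).
#' @return List of \code{xl_spectrum}, one per BEGIN IONS block, peaks
#'   sorted by m/z.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  meta <- list(); mzs <- NULL; ints <- NULL
  start_line <- 0L
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block)
        stop("MGF parse error at line ", k, ": nested BEGIN IONS",
             call. = FALSE)
      in_block <- TRUE
      meta <- list(); mzs <- numeric(0); ints <- numeric(0)
      start_line <- k
    } else if (line == "END IONS") {
      if (!in_block)
        stop("MGF parse error at line ", k, ": END IONS without BEGIN IONS",
             call. = FALSE)
      spectra[[length(spectra) + 1L]] <- mgf_block_to_spectrum(meta, mzs, ints,
                                                              start_line)
      in_block <- FALSE
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      key <- toupper(substr(line, 1, eq - 1))
      meta[[key]] <- substr(line, eq + 1, nchar(line))
    } else if (in_block) {
      fields <- strsplit(line, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[1:2]))
      if (length(fields) < 2 || any(is.na(vals)))
        stop("MGF parse error at line ", k, ": malformed peak line '",
             line, "'", call. = FALSE)
      mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
    }
    ## lines outside blocks (global headers) are ignored
  }
  if (in_block)
    stop("MGF parse error: BEGIN IONS at line ", start_line,
         " never closed", call. = FALSE)
  spectra
}

mgf_block_to_spectrum <- function(meta, mzs, ints, start_line) {
  if (is.null(meta$PEPMASS))
    stop("MGF parse error: block starting at line ", start_line,
         " has no PEPMASS", call. = FALSE)
  pm <- suppressWarnings(as.numeric(strsplit(trimws(meta$PEPMASS),
                                             "[ \t]+")[[1]][1]))
  if (is.na(pm))
    stop("MGF parse error: unreadable PEPMASS in block at line ",
         start_line, call. = FALSE)
  charge <- NA_integer_
  if (!is.null(meta$CHARGE)) {
    m <- regmatches(meta$CHARGE, regexpr("[0-9]+", meta$CHARGE))
    if (length(m)) {
      charge <- as.integer(m)
      if (grepl("-", meta$CHARGE, fixed = TRUE)) charge <- -charge
    }
  }
  scan_id <- if (!is.null(meta$SCANS)) meta$SCANS
             else if (!is.null(meta$TITLE)) meta$TITLE else "scan"
  ms_level <- if (!is.null(meta$MSLEVEL))
    as.integer(meta$MSLEVEL) else 2L
  extra <- meta[setdiff(names(meta),
                        c("PEPMASS", "CHARGE", "SCANS", "MSLEVEL"))]
  spectrum(mzs, ints, precursor_mz = pm, precursor_charge = charge,
           scan_id = scan_id, ms_level = ms_level, metadata = extra)
}

#' Write spectra to an MGF file
#'
#' Deterministic formatting (m/z to 1e-6 Th, intensities with 10 significant
#' digits); metadata keys are emitted as uppercase headers. A write/read
#' round trip reproduces the spectra to better than 1e-6 relative tolerance.
#'
#' @param spectra List of \code{xl_spectrum} (or a single spectrum).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "xl_spectrum")) spectra <- list(spectra)
  con <- file(path, "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    meta <- s$metadata
    if (!is.null(meta$TITLE)) {
      writeLines(paste0("TITLE=", meta$TITLE), con)
      meta$TITLE <- NULL
    }
    writeLines(paste0("PEPMASS=", sprintf("%.6f", s$precursor_mz)), con)
    if (!is.na(s$precursor_charge))
      writeLines(sprintf("CHARGE=%d%s", abs(s$precursor_charge),
                         if (s$precursor_charge < 0) "-" else "+"), con)
    writeLines(paste0("SCANS=", s$scan_id), con)
    if (s$ms_level != 2L) writeLines(paste0("MSLEVEL=", s$ms_level), con)
    for (key in names(meta))
      writeLines(paste0(toupper(key), "=", meta[[key]]), con)
    if (n_peaks(s) > 0)
      writeLines(sprintf("%.6f %.10g", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
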