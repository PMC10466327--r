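## Ground-truth spectrum generator. Emulates the statistical structure the
## dataset-level analyses assume: crosslinked MS2 spectra carrying
## stub-pair doublets for both peptides (with hydrogen-shift satellites,
## per-peptide doublet dropout, and a configurable stub-to-backbone
## intensity partition), linear peptide spectra, and crosslinker-modified
## linear spectra, plus chemical noise, a surviving precursor peak, per-peak
## ppm jitter and an optional per-spectrum calibration offset.

#' Generator configuration
#'
#' Defaults describe a UCCL-like acquisition: stub/backbone intensity
#' log-ratio centred on ln(5.3) with sd 1, symmetric single-hydrogen-shift
#' satellites at probability 0.5 each, per-peptide doublet dropout 0.04
#' (both-doublet prevalence (1-q)^2 = 0.9216), 20 low-level chemical-noise
#' peaks, 2 ppm per-peak mass jitter, half of the ion current surviving as
#' unfragmented precursor, scan range 150-1800 Th, and CSM precursor
#' charges 3-5.
#'
#' @param crosslinker Crosslinker name or \code{xl_crosslinker} (default
#'   "uccl").
#' @param n_crosslinked,n_linear,n_xl_modified Spectra per class.
#' @param peptide_length Length-2 integer range (min >= 5).
#' @param log_ratio_mu,log_ratio_sigma Parameters of the natural-log-normal
#'   stub/backbone intensity partition.
#' @param hydrogen_shift_probs Named numeric vector: probability of planting
#'   a satellite stub peak at each H-atom shift (names are integer shifts).
#' @param satellite_intensity Satellite intensity multiplier relative to the
#'   unshifted stub peak's lognormal draw.
#' @param dropout_prob Per-peptide probability that its stub doublet is
#'   entirely missing.
#' @param n_noise_peaks Number of uniform-m/z chemical-noise peaks.
#' @param noise_intensity_frac Mean noise-peak intensity as a fraction of
#'   the fragment ion current.
#' @param peak_sdlog Lognormal sdlog of within-class peak intensities.
#' @param mz_jitter_ppm Per-peak i.i.d. mass-error sd (ppm).
#' @param calibration_offset_ppm Sd of a per-spectrum systematic mass offset
#'   (ppm); 0 disables. This is the error \code{\link{recalibrate}} removes.
#' @param scan_range Length-2 m/z range (Th).
#' @param precursor_charge_range,linear_charge_range Inclusive charge ranges
#'   for crosslinked and linear precursors.
#' @param precursor_fraction Fraction of total intensity left on the
#'   surviving precursor peak.
#' @param backbone_series Backbone series planted (default a, b, y).
#' @param total_intensity Total ion current per spectrum (arbitrary units).
#' @param exclusion_ppm Noise peaks are re-drawn if within this many ppm of
#'   any true peak, so ground truth stays unambiguous.
#' @param seed Integer seed fixing the full output stream of
#'   \code{\link{generate_dataset}}.
#' @return A list of class \code{xl_generator_config}.
#' @export
generator_config <- function(crosslinker = "uccl",
                             n_crosslinked = 100L, n_linear = 0L,
                             n_xl_modified = 0L,
                             peptide_length = c(6L, 18L),
                             log_ratio_mu = log(5.3), log_ratio_sigma = 1.0,
                             hydrogen_shift_probs = c("-1" = 0.5, "1" = 0.5),
                             satellite_intensity = 0.5,
                             dropout_prob = 0.04,
                             n_noise_peaks = 20L,
                             noise_intensity_frac = 0.002,
                             peak_sdlog = 1.0,
                             mz_jitter_ppm = 2,
                             calibration_offset_ppm = 0,
                             scan_range = c(150, 1800),
                             precursor_charge_range = c(3L, 5L),
                             linear_charge_range = c(2L, 3L),
                             precursor_fraction = 0.5,
                             backbone_series = c("a", "b", "y"),
                             total_intensity = 1e6,
                             exclusion_ppm = 20,
                             seed = 1L) {
  xl <- if (inherits(crosslinker, "xl_crosslinker")) crosslinker
        else load_crosslinker(crosslinker)
  stopifnot(length(peptide_length) == 2, peptide_length[1] >= 5,
            peptide_length[2] >= peptide_length[1])
  probs <- as.numeric(hydrogen_shift_probs)
  if (length(probs) && (any(probs < 0) || any(probs > 1)))
    stop("hydrogen shift probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(dropout_prob >= 0, dropout_prob <= 1,
            precursor_fraction >= 0, precursor_fraction < 1,
            scan_range[1] > 0, scan_range[2] > scan_range[1])
  structure(
    list(xl = xl, n_crosslinked = as.integer(n_crosslinked),
         n_linear = as.integer(n_linear),
         n_xl_modified = as.integer(n_xl_modified),
         peptide_length = as.integer(peptide_length),
         log_ratio_mu = log_ratio_mu, log_ratio_sigma = log_ratio_sigma,
         hydrogen_shift_probs = hydrogen_shift_probs,
         satellite_intensity = satellite_intensity,
         dropout_prob = dropout_prob,
         n_noise_peaks = as.integer(n_noise_peaks),
         noise_intensity_frac = noise_intensity_frac,
         peak_sdlog = peak_sdlog,
         mz_jitter_ppm = mz_jitter_ppm,
         calibration_offset_ppm = calibration_offset_ppm,
         scan_range = as.numeric(scan_range),
         precursor_charge_range = as.integer(precursor_charge_range),
         linear_charge_range = as.integer(linear_charge_range),
         precursor_fraction = precursor_fraction,
         backbone_series = backbone_series,
         total_intensity = total_intensity,
         exclusion_ppm = exclusion_ppm,
         seed = as.integer(seed)),
    class = "xl_generator_config"
  )
}

## draw uniformly from an inclusive integer range (avoids the scalar
## behaviour of sample())
sample_range <- function(lo, hi) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), 1L)]
}

#' Draw a random tryptic-like peptide
#'
#' Residues are uniform over the 20 standard amino acids; one position
#' before the C-terminus is forced to lysine and designated the link site
#' (NHS-ester chemistry links lysines).
#'
#' @param length_range Length-2 integer range (min >= 5).
#' @return An \code{xl_peptide} with \code{link_site} set.
#' @export
random_peptide <- function(length_range = c(6L, 18L)) {
  stopifnot(length_range[1] >= 5)
  len <- sample_range(length_range[1], length_range[2])
  residues <- sample(names(RESIDUE_FORMULAS), len, replace = TRUE)
  site <- sample.int(len - 1L, 1L)
  residues[site] <- "K"
  peptide(paste(residues, collapse = ""), link_site = site)
}

## plant the doublet-pair stub peaks (+ hydrogen-shift satellites) for one
## peptide; returns a provenance data.frame with relative weights
plant_stub_peaks <- function(pep, pid, xl, config) {
  rows <- list()
  probs <- config$hydrogen_shift_probs
  shift_vals <- as.integer(names(probs))
  for (lab in xl$doublet_pair) {
    w_main <- stats::rlnorm(1, 0, config$peak_sdlog)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "stub", peptide_id = pid, series = "stub", label = lab,
      index = NA_integer_, shift = 0L, charge = 1L,
      theo_mz = stub_fragment_mz(pep, xl, lab, 0L, 1L), weight = w_main)
    if (length(probs)) {
      present <- stats::runif(length(probs)) < probs
      for (k in which(present)) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "stub", peptide_id = pid, series = "stub", label = lab,
          index = NA_integer_, shift = shift_vals[k], charge = 1L,
          theo_mz = stub_fragment_mz(pep, xl, lab, shift_vals[k], 1L),
          weight = w_main * config$satellite_intensity *
            stats::rlnorm(1, 0, config$peak_sdlog))
      }
    }
  }
  do.call(rbind, rows)
}

plant_backbone_peaks <- function(pep, pid, config) {
  bb <- backbone_fragments(pep, series = config$backbone_series,
                           charges = 1L)
  if (nrow(bb) == 0) return(NULL)
  data.frame(kind = "backbone", peptide_id = pid, series = bb$series,
             label = NA_character_, index = bb$index, shift = 0L,
             charge = bb$charge, theo_mz = bb$mz,
             weight = stats::rlnorm(nrow(bb), 0, config$peak_sdlog))
}

## assemble peaks from a provenance table: scale class weights to the drawn
## intensity partition, add noise/precursor, apply jitter, sort
assemble_spectrum <- function(prov, precursor_theo_mz, charge, scan_id,
                              config, ratio) {
  frag_total <- config$total_intensity * (1 - config$precursor_fraction)
  stub_target <- frag_total * ratio / (1 + ratio)
  backbone_target <- frag_total / (1 + ratio)
  prov$intensity <- 0
  is_stub <- prov$kind == "stub"
  is_bb <- prov$kind == "backbone"
  if (any(is_stub))
    prov$intensity[is_stub] <-
      prov$weight[is_stub] / sum(prov$weight[is_stub]) * stub_target
  if (any(is_bb))
    prov$intensity[is_bb] <-
      prov$weight[is_bb] / sum(prov$weight[is_bb]) * backbone_target
  ## surviving precursor
  prov <- rbind(prov, data.frame(
    kind = "precursor", peptide_id = NA_character_, series = "precursor",
    label = NA_character_, index = NA_integer_, shift = 0L, charge = charge,
    theo_mz = precursor_theo_mz, weight = 1,
    intensity = config$total_intensity * config$precursor_fraction))
  ## chemical noise, kept clear of true peaks
  if (config$n_noise_peaks > 0) {
    noise_mz <- numeric(config$n_noise_peaks)
    for (k in seq_len(config$n_noise_peaks)) {
      repeat {
        m <- stats::runif(1, config$scan_range[1], config$scan_range[2])
        if (all(abs(m - prov$theo_mz) >
                config$exclusion_ppm * 1e-6 * prov$theo_mz)) break
      }
      noise_mz[k] <- m
    }
    prov <- rbind(prov, data.frame(
      kind = "noise", peptide_id = NA_character_, series = "noise",
      label = NA_character_, index = NA_integer_, shift = 0L,
      charge = NA_integer_, theo_mz = noise_mz, weight = 1,
      intensity = frag_total * config$noise_intensity_frac *
        stats::rlnorm(config$n_noise_peaks, 0, 1)))
  }
  calib <- if (config$calibration_offset_ppm > 0)
    stats::rnorm(1, 0, config$calibration_offset_ppm) else 0
  jitter <- if (config$mz_jitter_ppm > 0)
    stats::rnorm(nrow(prov), 0, config$mz_jitter_ppm) else rep(0, nrow(prov))
  prov$mz <- prov$theo_mz * (1 + jitter * 1e-6) * (1 + calib * 1e-6)
  ord <- order(prov$mz)
  prov <- prov[ord, , drop = FALSE]
  prov$peak_idx <- seq_len(nrow(prov))
  prov$weight <- NULL
  rownames(prov) <- NULL
  s <- spectrum(prov$mz, prov$intensity,
                precursor_mz = precursor_theo_mz * (1 + calib * 1e-6),
                precursor_charge = charge, scan_id = scan_id, ms_level = 2L)
  list(spectrum = s, peaks = prov, calibration_ppm = calib)
}

truth_of <- function(class, alpha, beta, asm, dropped_alpha, dropped_beta,
                     ratio, scan_id) {
  pk <- asm$peaks
  stub_mz <- function(pid) pk$mz[pk$kind == "stub" & !is.na(pk$peptide_id) &
                                   pk$peptide_id == pid]
  structure(
    list(class = class, scan_id = scan_id,
         alpha = alpha, beta = beta,
         dropped_alpha = dropped_alpha, dropped_beta = dropped_beta,
         stub_mz_alpha = stub_mz("alpha"), stub_mz_beta = stub_mz("beta"),
         stub_sum = sum(pk$intensity[pk$kind == "stub"]),
         backbone_sum = sum(pk$intensity[pk$kind == "backbone"]),
         target_ratio = ratio, calibration_ppm = asm$calibration_ppm,
         peaks = pk),
    class = "xl_truth"
  )
}

#' Generate a synthetic crosslinked-peptide MS2 spectrum
#'
#' Plants the doublet-pair stub peaks (with hydrogen-shift satellites) for
#' each peptide unless dropped, the a/b/y backbone peaks of both peptides,
#' a surviving precursor, and chemical noise; partitions fragment intensity
#' so that stub_sum / backbone_sum equals a draw from the configured
#' log-normal; applies per-peak ppm jitter. Uses the current RNG stream.
#'
#' @param alpha,beta \code{xl_peptide}s with link sites.
#' @param config An \code{xl_generator_config} (its crosslinker is used).
#' @param scan_id Identifier for the spectrum.
#' @return List with \code{spectrum} (an \code{xl_spectrum}) and
#'   \code{truth} (an \code{xl_truth} with per-peak provenance, observed
#'   stub m/z per peptide, realized class sums and dropout flags).
#' @export
generate_csm_spectrum <- function(alpha, beta, config, scan_id = "csm") {
  stopifnot(inherits(config, "xl_generator_config"))
  xl <- config$xl
  zr <- config$precursor_charge_range
  z <- sample_range(zr[1], zr[2])
  M <- peptide_mass(alpha) + peptide_mass(beta) +
    monoisotopic_mass(xl$spacer)
  pmz <- (M + z * PROTON_MASS) / z
  dropped_a <- stats::runif(1) < config$dropout_prob
  dropped_b <- stats::runif(1) < config$dropout_prob
  prov <- rbind(
    if (!dropped_a) plant_stub_peaks(alpha, "alpha", xl, config),
    if (!dropped_b) plant_stub_peaks(beta, "beta", xl, config),
    plant_backbone_peaks(alpha, "alpha", config),
    plant_backbone_peaks(beta, "beta", config)
  )
  ratio <- exp(stats::rnorm(1, config$log_ratio_mu, config$log_ratio_sigma))
  asm <- assemble_spectrum(prov, pmz, z, scan_id, config, ratio)
  list(spectrum = asm$spectrum,
       truth = truth_of("crosslinked", alpha, beta, asm,
                        dropped_a, dropped_b, ratio, scan_id))
}

#' Generate a synthetic linear-peptide MS2 spectrum
#'
#' Backbone plus noise and surviving precursor; when \code{modified}, the
#' peptide carries a hydrolysed crosslinker (spacer + water) and one stub
#' doublet is planted — the specificity challenge for MS3 triggering.
#'
#' @param pep An \code{xl_peptide}.
#' @param config An \code{xl_generator_config}.
#' @param modified Plant a mono-link stub doublet (default FALSE).
#' @param scan_id Identifier.
#' @return List with \code{spectrum} and \code{truth} (class "linear" or
#'   "xl_modified"; the single peptide is reported as alpha).
#' @export
generate_linear_spectrum <- function(pep, config, modified = FALSE,
                                     scan_id = "lin") {
  stopifnot(inherits(config, "xl_generator_config"))
  xl <- config$xl
  zr <- config$linear_charge_range
  z <- sample_range(zr[1], zr[2])
  M <- peptide_mass(pep) +
    if (modified) monoisotopic_mass(xl$spacer) + WATER_MASS else 0
  pmz <- (M + z * PROTON_MASS) / z
  dropped <- if (modified) stats::runif(1) < config$dropout_prob else TRUE
  prov <- rbind(
    if (!dropped) plant_stub_peaks(pep, "alpha", xl, config),
    plant_backbone_peaks(pep, "alpha", config)
  )
  ratio <- if (modified)
    exp(stats::rnorm(1, config$log_ratio_mu, config$log_ratio_sigma))
  else 0
  asm <- assemble_spectrum(prov, pmz, z, scan_id, config, ratio)
  list(spectrum = asm$spectrum,
       truth = truth_of(if (modified) "xl_modified" else "linear",
                        pep, NULL, asm, dropped, NA, ratio, scan_id))
}

#' Generate a full synthetic dataset
#'
#' Draws \code{n_crosslinked} CSM spectra, \code{n_linear} linear and
#' \code{n_xl_modified} crosslinker-modified linear spectra under the
#' config, reproducibly from \code{config$seed}. Optionally writes an MGF
#' peak list, a long-format per-peak truth table and a CSM table.
#'
#' @param config An \code{xl_generator_config}.
#' @param out_prefix If non-NULL, writes \code{<prefix>.mgf},
#'   \code{<prefix>.truth.tsv} and \code{<prefix>.csms.tsv}.
#' @return List of class \code{xl_dataset} with \code{spectra},
#'   \code{truths}, \code{csms} (data.frame) and \code{config}.
#' @export
generate_dataset <- function(config, out_prefix = NULL) {
  stopifnot(inherits(config, "xl_generator_config"))
  set.seed(config$seed)
  spectra <- list(); truths <- list(); csm_rows <- list()
  add <- function(gen, class, alpha, beta) {
    spectra[[length(spectra) + 1L]] <<- gen$spectrum
    truths[[length(truths) + 1L]] <<- gen$truth
    csm_rows[[length(csm_rows) + 1L]] <<- data.frame(
      scan_id = gen$spectrum$scan_id, class = class,
      peptide_alpha = alpha$sequence, link_site_alpha = alpha$link_site,
      peptide_beta = if (is.null(beta)) NA_character_ else beta$sequence,
      link_site_beta = if (is.null(beta)) NA_integer_ else beta$link_site,
      precursor_mz = gen$spectrum$precursor_mz,
      precursor_charge = gen$spectrum$precursor_charge)
  }
  for (i in seq_len(config$n_crosslinked)) {
    a <- random_peptide(config$peptide_length)
    b <- random_peptide(config$peptide_length)
    add(generate_csm_spectrum(a, b, config, sprintf("csm_%05d", i)),
        "crosslinked", a, b)
  }
  for (i in seq_len(config$n_linear)) {
    p <- random_peptide(config$peptide_length)
    add(generate_linear_spectrum(p, config, FALSE, sprintf("lin_%05d", i)),
        "linear", p, NULL)
  }
  for (i in seq_len(config$n_xl_modified)) {
    p <- random_peptide(config$peptide_length)
    add(generate_linear_spectrum(p, config, TRUE, sprintf("mod_%05d", i)),
        "xl_modified", p, NULL)
  }
  csms <- if (length(csm_rows)) do.call(rbind, csm_rows) else
    data.frame(scan_id = character(0), class = character(0),
               peptide_alpha = character(0), link_site_alpha = integer(0),
               peptide_beta = character(0), link_site_beta = integer(0),
               precursor_mz = numeric(0), precursor_charge = integer(0))
  ds <- structure(list(spectra = spectra, truths = truths, csms = csms,
                       config = config),
                  class = "xl_dataset")
  if (!is.null(out_prefix)) write_dataset(ds, out_prefix)
  ds
}

#' Write a synthetic dataset to disk
#'
#' @param dataset An \code{xl_dataset}.
#' @param out_prefix Path prefix for \code{.mgf}, \code{.truth.tsv},
#'   \code{.csms.tsv}.
#' @return \code{out_prefix}, invisibly.
#' @export
write_dataset <- function(dataset, out_prefix) {
  write_mgf(dataset$spectra, paste0(out_prefix, ".mgf"))
  truth_tab <- do.call(rbind, lapply(dataset$truths, function(tr) {
    pk <- tr$peaks
    pk$scan_id <- tr$scan_id
    pk$class <- tr$class
    pk[, c("scan_id", "class", "peak_idx", "mz", "intensity", "kind",
           "peptide_id", "series", "label", "index", "shift", "charge",
           "theo_mz")]
  }))
  if (is.null(truth_tab)) truth_tab <- data.frame()
  utils::write.table(truth_tab, paste0(out_prefix, ".truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$csms, paste0(out_prefix, ".csms.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_prefix)
}
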