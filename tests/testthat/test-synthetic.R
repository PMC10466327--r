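test_that("random_peptide: length, lysine link site, determinism", {
  set.seed(41)
  for (i in 1:50) {
    p <- random_peptide(c(5, 12))
    expect_gte(nchar(p$sequence), 5)
    expect_lte(nchar(p$sequence), 12)
    expect_false(is.na(p$link_site))
    expect_lt(p$link_site, nchar(p$sequence))  # not C-terminal
    expect_equal(p$residues[p$link_site], "K")
  }
  set.seed(99); p1 <- random_peptide()
  set.seed(99); p2 <- random_peptide()
  expect_identical(p1$sequence, p2$sequence)
  expect_error(random_peptide(c(3, 4)))
  # non-forced positions are uniform over the alphabet (chi-square at 4 sd)
  set.seed(42)
  res <- unlist(lapply(1:2000, function(i) {
    p <- random_peptide(c(6, 6))
    p$residues[-p$link_site]
  }))
  freq <- table(factor(res, levels = names(residue_masses())))
  expect_lt(max(abs(freq / length(res) - 1 / 20)),
            4 * sqrt((1 / 20) * (19 / 20) / length(res)))
})

test_that("ideal CSM spectra: recovery and exact intensity partition", {
  cfg <- generator_config(dropout_prob = 0, n_noise_peaks = 0,
                          mz_jitter_ppm = 0,
                          hydrogen_shift_probs = numeric(0), seed = 1)
  set.seed(1)
  uccl <- cfg$xl
  for (i in 1:10) {
    a <- random_peptide(); b <- random_peptide()
    g <- generate_csm_spectrum(a, b, cfg, scan_id = paste0("s", i))
    tr <- g$truth
    # both doublets present: two stub peaks per peptide
    expect_length(tr$stub_mz_alpha, 2)
    expect_length(tr$stub_mz_beta, 2)
    # detection at 5 ppm recovers both doublets
    det <- detect_spectrum(g$spectrum, uccl)
    ev <- evaluate_triggers(det$triggers, tr, tol_ppm = 5)
    expect_true(ev$alpha_triggered && ev$beta_triggered)
    # the C-stub (heavy) peaks are the triggered species
    cs <- c(max(tr$stub_mz_alpha), max(tr$stub_mz_beta))
    expect_true(all(vapply(cs, function(m)
      any(abs(det$triggers$precursor_mz - m) < 1e-6), logical(1))))
    # realized sums match the drawn partition exactly
    frag_total <- cfg$total_intensity * (1 - cfg$precursor_fraction)
    expect_equal(tr$stub_sum + tr$backbone_sum, frag_total,
                 tolerance = 1e-9)
    expect_equal(tr$stub_sum / tr$backbone_sum, tr$target_ratio,
                 tolerance = 1e-9)
    # annotation recovers every planted peak's provenance (noise-free);
    # the precursor peak is excluded via ground truth rather than the
    # +/-2 Th window, which can clip backbone peaks near charge-reduced
    # precursor species
    pk <- tr$peaks[tr$peaks$kind != "precursor", ]
    s2 <- spectrum(pk$mz, pk$intensity, scan_id = tr$scan_id)
    ann <- annotate_spectrum(s2, a, b, uccl, tol_ppm = 1,
                             shifts = 0)$annotations
    expect_equal(nrow(ann), nrow(pk))  # 100% recall, no spurious hits
    got <- ann[order(s2$mz[ann$peak_idx]), ]
    want <- pk[order(pk$mz), ]
    expect_equal(got$series == "stub", want$kind == "stub")
  }
})

test_that("dropout and hydrogen-shift satellites behave as configured", {
  cfg_q1 <- generator_config(dropout_prob = 1, n_noise_peaks = 0,
                             mz_jitter_ppm = 0, seed = 2)
  set.seed(2)
  g <- generate_csm_spectrum(random_peptide(), random_peptide(), cfg_q1)
  expect_length(g$truth$stub_mz_alpha, 0)
  expect_length(g$truth$stub_mz_beta, 0)
  expect_true(g$truth$dropped_alpha && g$truth$dropped_beta)
  # satellites: with prob 1 every stub peak gets each configured shift
  cfg_sat <- generator_config(dropout_prob = 0, n_noise_peaks = 0,
                              mz_jitter_ppm = 0,
                              hydrogen_shift_probs = c("-1" = 1, "1" = 1),
                              seed = 3)
  set.seed(3)
  g2 <- generate_csm_spectrum(random_peptide(), random_peptide(), cfg_sat)
  expect_length(g2$truth$stub_mz_alpha, 6)  # (B, C) x shifts {-1, 0, +1}
  pk <- g2$truth$peaks
  expect_setequal(unique(pk$shift[pk$kind == "stub"]), c(-1L, 0L, 1L))
})

test_that("linear and modified spectra: doublet content", {
  cfg <- generator_config(dropout_prob = 0, n_noise_peaks = 0,
                          mz_jitter_ppm = 0,
                          hydrogen_shift_probs = numeric(0), seed = 4)
  uccl <- cfg$xl
  set.seed(4)
  p <- random_peptide()
  lin <- generate_linear_spectrum(p, cfg, modified = FALSE)
  expect_equal(lin$truth$class, "linear")
  expect_length(lin$truth$stub_mz_alpha, 0)
  det <- detect_spectrum(lin$spectrum, uccl)
  expect_equal(evaluate_triggers(det$triggers, lin$truth)$alpha_triggered,
               FALSE)
  mod <- generate_linear_spectrum(p, cfg, modified = TRUE)
  expect_equal(mod$truth$class, "xl_modified")
  expect_length(mod$truth$stub_mz_alpha, 2)
  det2 <- detect_spectrum(mod$spectrum, uccl)
  expect_gte(nrow(det2$triggers), 1)
  expect_true(evaluate_triggers(det2$triggers, mod$truth)$alpha_triggered)
})

test_that("datasets are seed-reproducible and byte-identical on disk", {
  cfg <- generator_config(n_crosslinked = 4, n_linear = 2,
                          n_xl_modified = 2, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_equal(length(d1$spectra), 8)
  expect_equal(as.vector(table(d1$csms$class)[c("crosslinked", "linear",
                                                "xl_modified")]),
               c(4L, 2L, 2L))
  expect_identical(d1$spectra[[3]]$mz, d2$spectra[[3]]$mz)
  p1 <- file.path(withr::local_tempdir(), "a")
  p2 <- file.path(withr::local_tempdir(), "b")
  write_dataset(d1, p1)
  write_dataset(d2, p2)
  for (ext in c(".mgf", ".truth.tsv", ".csms.tsv"))
    expect_identical(readLines(paste0(p1, ext)), readLines(paste0(p2, ext)))
  # n = 0 -> empty outputs
  d0 <- generate_dataset(generator_config(n_crosslinked = 0, seed = 1))
  expect_length(d0$spectra, 0)
  expect_equal(nrow(d0$csms), 0)
})

test_that("noise keeps clear of true peaks; false matches scale with laxity", {
  cfg <- generator_config(n_crosslinked = 0, n_linear = 30,
                          n_noise_peaks = 60, mz_jitter_ppm = 0, seed = 5)
  ds <- generate_dataset(cfg)
  uccl <- cfg$xl
  for (tr in ds$truths[1:5]) {
    pk <- tr$peaks
    noise <- pk$mz[pk$kind == "noise"]
    true <- pk$theo_mz[pk$kind != "noise"]
    expect_gt(min(abs(outer(noise, true, "-")) /
                    rep(true, each = length(noise))), 20e-6 * 0.99)
  }
  # Monte-Carlo monotonicity: loose tolerance + more variants + no dedup
  # yields at least as many false triggers as the optimized parameters
  strict <- detect_params(tol_ppm = 5, shifts = 0:2, window_mz = 1.5)
  loose <- detect_params(tol_ppm = 50, shifts = -1:3, window_mz = NA)
  n_false <- function(params) sum(vapply(seq_along(ds$spectra), function(i) {
    det <- detect_spectrum(ds$spectra[[i]], uccl, params)
    evaluate_triggers(det$triggers, ds$truths[[i]],
                      params$tol_ppm)$n_false_triggers
  }, numeric(1)))
  expect_gt(n_false(loose), n_false(strict))
})
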