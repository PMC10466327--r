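uccl <- load_crosslinker("uccl")

test_that("backbone fragments: values, identities, complementarity", {
  bb <- backbone_fragments("GG", series = "b", charges = 1)
  expect_equal(bb$mz[bb$index == 1], 58.0287402, tolerance = 1e-6)
  # y_n-1 ... full-length y identity via the n-1 cleavage of a 2-mer
  pepseq <- "AKLHDYYK"
  yb <- backbone_fragments(pepseq, series = c("b", "y"), charges = 1)
  n <- nchar(pepseq)
  # b_i + y_(n-i) = M + 2 * proton at z = 1 each
  for (i in 1:(n - 1)) {
    b_i <- yb$mz[yb$series == "b" & yb$index == i]
    y_ni <- yb$mz[yb$series == "y" & yb$index == n - i]
    expect_equal(b_i + y_ni, peptide_mass(pepseq) + 2 * PROTON_MASS,
                 tolerance = 1e-9)
  }
  # series offsets: a = b - CO, c = b + NH3, x = y + CO - H2, zdot = y - NH3 + H
  all6 <- backbone_fragments(pepseq, series = c("a", "b", "c", "x", "y", "z"),
                             charges = 1)
  pick <- function(ser, i) all6$mz[all6$series == ser & all6$index == i]
  expect_equal(pick("a", 3), pick("b", 3) - CO_MASS, tolerance = 1e-9)
  expect_equal(pick("c", 3), pick("b", 3) + NH3_MASS, tolerance = 1e-9)
  expect_equal(pick("x", 3), pick("y", 3) + CO_MASS - 2 * H_ATOM_MASS,
               tolerance = 1e-9)
  expect_equal(pick("z", 3), pick("y", 3) - NH3_MASS + H_ATOM_MASS,
               tolerance = 1e-9)
  # property: complementarity for random peptides
  set.seed(21)
  for (i in 1:10) {
    seqr <- paste(sample(names(ORACLE_RESIDUES), sample(5:15, 1), TRUE),
                  collapse = "")
    fr <- backbone_fragments(seqr, series = c("b", "y"), charges = 1)
    nn <- nchar(seqr)
    expect_equal(fr$mz[fr$series == "b" & fr$index == 2] +
                   fr$mz[fr$series == "y" & fr$index == nn - 2],
                 peptide_mass(seqr) + 2 * PROTON_MASS, tolerance = 1e-9)
  }
  # link_mod lands only on fragments spanning the link site
  pep <- peptide("GAKLV", link_site = 3)
  plain <- backbone_fragments(pep, series = "b", charges = 1)
  mod <- backbone_fragments(pep, series = "b", charges = 1, link_mod = 100)
  expect_equal(mod$mz - plain$mz, c(0, 0, 100, 100))
})

test_that("stub_fragments is the labels x shifts x charges cross product", {
  fr <- stub_fragments("GAK", uccl, shifts = 0:2, charges = 1:2)
  expect_equal(nrow(fr), 4 * 3 * 2)
  dsso <- load_crosslinker("dsso")
  expect_equal(nrow(stub_fragments("GAK", dsso, shifts = 0, charges = 1:2)),
               3 * 1 * 2)
  sub <- fr[fr$label == "C" & fr$shift == 0 & fr$charge == 1, ]
  expect_equal(sub$mz, stub_fragment_mz("GAK", uccl, "C", 0, 1))
})

test_that("annotate_spectrum: greedy one-to-one assignment", {
  alpha <- peptide("GASKLV", link_site = 4)
  beta <- peptide("PEKTIDR", link_site = 3)
  # empty spectrum -> no annotations
  s0 <- spectrum(numeric(0), numeric(0))
  expect_equal(nrow(annotate_spectrum(s0, alpha, beta, uccl)$annotations), 0)
  # planted fragments recovered exactly under small jitter
  frags <- rbind(
    cbind(backbone_fragments(alpha, charges = 1), pid = "alpha"),
    cbind(backbone_fragments(beta, charges = 1), pid = "beta"))
  st <- stub_fragments(alpha, uccl, labels = "C", shifts = 0, charges = 1)
  mzs <- c(frags$mz, st$mz) * (1 + 2e-6)  # +2 ppm jitter, tol 10 ppm
  s <- spectrum(mzs, rep(100, length(mzs)), scan_id = "t")
  ann <- annotate_spectrum(s, alpha, beta, uccl, tol_ppm = 10)$annotations
  expect_equal(nrow(ann), length(mzs))
  expect_equal(sum(ann$series == "stub" & ann$label == "C" &
                     ann$peptide_id == "alpha" & ann$shift == 0), 1)
  # one-to-one: no peak or fragment used twice
  expect_false(any(duplicated(ann$peak_idx)))
  expect_false(any(duplicated(ann[, c("series", "index", "label",
                                      "peptide_id", "charge", "shift")])))
  # two peaks equidistant from one fragment -> lower m/z wins
  f1 <- backbone_fragments(alpha, series = "b", charges = 1)$mz[2]
  s2 <- spectrum(c(f1 - 1e-4, f1 + 1e-4), c(5, 5))
  ann2 <- annotate_spectrum(s2, alpha, NULL, uccl, tol_ppm = 10)$annotations
  expect_equal(ann2$peak_idx[ann2$series == "b" & ann2$index == 2], 1L)
  # stable under peak-order permutation and intensity scaling
  perm <- sample(length(mzs))
  s3 <- spectrum(mzs[perm], rep(7, length(mzs)))
  ann3 <- annotate_spectrum(s3, alpha, beta, uccl, tol_ppm = 10)$annotations
  expect_equal(nrow(ann3), nrow(ann))
  expect_equal(s3$mz[ann3$peak_idx], s$mz[ann$peak_idx])
})

test_that("stub_backbone_sums partitions annotated intensity", {
  alpha <- peptide("GASKLV", link_site = 4)
  expect_equal(
    stub_backbone_sums(annotate_spectrum(spectrum(5000, 1), alpha, NULL,
                                         uccl)),
    list(stub_sum = 0, backbone_sum = 0))
  # fixture: stub peaks 60 + 40, backbone peaks 10 + 10
  stub_mz <- c(stub_fragment_mz(alpha, uccl, "B"),
               stub_fragment_mz(alpha, uccl, "C"))
  bb <- backbone_fragments(alpha, series = "b", charges = 1)$mz[c(2, 4)]
  s <- spectrum(c(stub_mz, bb), c(60, 40, 10, 10))
  ann <- annotate_spectrum(s, alpha, NULL, uccl, tol_ppm = 5)
  sums <- stub_backbone_sums(ann)
  expect_equal(sums$stub_sum, 100)
  expect_equal(sums$backbone_sum, 20)
})

test_that("cleavage_efficiency fractions", {
  only_prec <- spectrum(500, 100, precursor_mz = 500)
  expect_equal(cleavage_efficiency(only_prec), 0)
  no_prec <- spectrum(c(100, 200), c(1, 1), precursor_mz = 900)
  expect_equal(cleavage_efficiency(no_prec), 1)
  mix <- spectrum(c(100, 200, 500), c(30, 40, 30), precursor_mz = 500)
  expect_equal(cleavage_efficiency(mix), 0.7)
  # charge-reduced survivor counted unless disabled
  pmz <- 400; M <- pmz * 3 - 3 * PROTON_MASS
  cr <- (M + 2 * PROTON_MASS) / 2
  s <- spectrum(c(200, cr), c(50, 50), precursor_mz = pmz,
                precursor_charge = 3)
  expect_equal(cleavage_efficiency(s), 0.5)
  expect_equal(cleavage_efficiency(s, charge_reduced = FALSE), 1)
})
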