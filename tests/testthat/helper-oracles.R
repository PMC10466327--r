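# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration rather than calling the code paths
# they check.

# exhaustive O(n^2 * |charges| * |variants|) doublet enumeration over the
# full pair matrix (vectorised per charge for speed, but every pair is
# examined — no windowed search)
oracle_find_doublets <- function(rspec, variants, tol_ppm, charges,
                                 max_rank = NULL) {
  mz <- rspec$mz
  n <- length(mz)
  pair <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  strict <- mz[j] > mz[i]
  i <- i[strict]; j <- j[strict]
  rows <- list()
  for (z in charges) {
    obs <- (mz[j] - mz[i]) * z
    errs <- outer(obs, variants, "-")
    within <- abs(errs) <= tol_ppm * 1e-6 * mz[j] * z  # recycles by column
    hit <- rowSums(within) > 0
    if (!any(hit)) next
    k <- apply(abs(errs[hit, , drop = FALSE]), 1, which.min)
    rows[[length(rows) + 1L]] <- data.frame(
      light_idx = i[hit], heavy_idx = j[hit], charge = z,
      variant = variants[k],
      best_rank = pmin(rspec$rank[i[hit]], rspec$rank[j[hit]]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(light_idx = integer(0), heavy_idx = integer(0),
               charge = integer(0), variant = numeric(0),
               best_rank = integer(0))
  if (!is.null(max_rank)) out <- out[out$best_rank <= max_rank, , drop = FALSE]
  out[order(out$light_idx, out$heavy_idx, out$charge), , drop = FALSE]
}

match_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sprintf("%d|%d|%d|%.6f", df$light_idx, df$heavy_idx, df$charge, df$variant)
}

# random centroided spectrum
random_spectrum <- function(n = 50, mz_range = c(150, 1800), scan_id = "r") {
  mz <- sort(runif(n, mz_range[1], mz_range[2]))
  spectrum(mz, rlnorm(n, 10, 1.5), precursor_mz = runif(1, 400, 1200),
           precursor_charge = sample(2:5, 1), scan_id = scan_id,
           metadata = list(TITLE = paste0("random ", scan_id)))
}

# greedy dedup oracle: straightforward re-statement with explicit sorting
oracle_dedupe <- function(matches, window_mz) {
  tmz <- matches$heavy_mz
  ord <- order(-matches$summed_intensity, tmz, matches$light_mz)
  kept <- c()
  for (k in ord) {
    if (all(abs(tmz[k] - tmz[kept]) > window_mz)) kept <- c(kept, k)
  }
  matches[kept, , drop = FALSE]
}

# sum of Euclidean distances
sum_dist <- function(y, pts) sum(sqrt((pts[, 1] - y[1])^2 +
                                      (pts[, 2] - y[2])^2))

# zooming grid search for the geometric median
oracle_grid_median <- function(pts, stages = 3, k = 61) {
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (all(lo == hi)) return(lo)
  best <- (lo + hi) / 2
  for (s in seq_len(stages)) {
    gx <- seq(lo[1], hi[1], length.out = k)
    gy <- seq(lo[2], hi[2], length.out = k)
    grid <- expand.grid(x = gx, y = gy)
    d <- rep(0, nrow(grid))
    for (i in seq_len(nrow(pts)))
      d <- d + sqrt((grid$x - pts[i, 1])^2 + (grid$y - pts[i, 2])^2)
    b <- which.min(d)
    best <- c(grid$x[b], grid$y[b])
    span <- c(gx[2] - gx[1], gy[2] - gy[1]) * 2
    lo <- best - span; hi <- best + span
  }
  best
}

# independent residue-mass table (literal values, not via the package)
ORACLE_RESIDUES <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527639,
  V = 99.0684140, T = 101.0476785, C = 103.0091845, L = 113.0840640,
  I = 113.0840640, N = 114.0429275, D = 115.0269430, Q = 128.0585775,
  K = 128.0949631, E = 129.0425931, M = 131.0404846, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793130)

oracle_peptide_mass <- function(seq)
  sum(ORACLE_RESIDUES[strsplit(seq, "")[[1]]]) + 18.0105647

# small UCCL-like CSM fixture built from first principles: two peptides'
# B/C doublet peaks plus optional hydrogen variants and extra peaks
make_doublet_fixture <- function(alpha = "GASKLV", beta = "PEKTIDR",
                                 variants_on = TRUE) {
  xl <- load_crosslinker("uccl")
  mzs <- c(); ints <- c()
  for (pep in c(alpha, beta)) {
    base <- oracle_peptide_mass(pep) + 1.00727646688
    mzs <- c(mzs, base + 73.9826354, base + 178.0452356)
    ints <- c(ints, 800, 1000)
    if (variants_on) {
      mzs <- c(mzs, base + 178.0452356 + 1.0078250319)
      ints <- c(ints, 300)
    }
  }
  spectrum(mzs, ints, precursor_mz = 700, precursor_charge = 4,
           scan_id = "fixture")
}
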