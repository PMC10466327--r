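## Dataset-level statistics: stub/backbone orthogonality, geometric-median
## representative spectra, doublet prevalence and rank-cutoff curves, and
## MS3-trigger sensitivity/specificity summaries.
##
## All operations take a "records" data.frame with one row per spectrum
## match and (a subset of) the columns: scan_id, class ("crosslinked",
## "linear", "xl_modified"), stub_sum, backbone_sum, doublet_alpha_found,
## doublet_beta_found, best_rank_alpha, best_rank_beta, n_ms3_triggered,
## alpha_triggered, beta_triggered.

#' Stub/backbone orthogonality statistics
#'
#' Ratios are stub_sum / backbone_sum; records with backbone_sum == 0 are
#' excluded from the median ratio (no finite ratio) but still count toward
#' the fraction with stub > backbone.
#'
#' @param records Records data.frame with \code{stub_sum} and
#'   \code{backbone_sum}.
#' @param boot Number of bootstrap resamples for the median's SE/CI
#'   (default 0 = none). Uses the current RNG stream.
#' @param conf Confidence level for the bootstrap percentile CI.
#' @return List with \code{median_ratio},
#'   \code{fraction_stub_gt_backbone}, \code{n}, and, when \code{boot > 0},
#'   \code{boot_se} and \code{ci} (length-2).
#' @export
orthogonality_stats <- function(records, boot = 0L, conf = 0.95) {
  stopifnot(nrow(records) > 0)
  ok <- records$backbone_sum > 0
  ratios <- records$stub_sum[ok] / records$backbone_sum[ok]
  out <- list(
    median_ratio = stats::median(ratios),
    fraction_stub_gt_backbone =
      mean(records$stub_sum > records$backbone_sum),
    n = nrow(records)
  )
  if (boot > 0 && length(ratios) > 0) {
    meds <- vapply(seq_len(boot), function(i)
      stats::median(sample(ratios, replace = TRUE)), numeric(1))
    out$boot_se <- stats::sd(meds)
    out$ci <- unname(stats::quantile(meds, c((1 - conf) / 2,
                                             1 - (1 - conf) / 2)))
  }
  out
}

#' Geometric median of 2-D points (Weiszfeld)
#'
#' Minimises the sum of Euclidean distances to the points using Weiszfeld
#' iteration with the Vardi-Zhang adjustment when an iterate coincides with
#' a data point.
#'
#' @param points Two-column matrix or data.frame (x, y).
#' @param tol Convergence threshold on the iterate step (default 1e-9).
#' @param max_iter Iteration cap (default 10000).
#' @return Numeric length-2 vector (x, y). On non-convergence an error of
#'   class \code{xl_weiszfeld_error} is raised carrying the last iterate in
#'   its \code{iterate} field.
#' @export
geometric_median <- function(points, tol = 1e-9, max_iter = 10000L) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 1, all(is.finite(pts)))
  if (nrow(pts) == 1) return(as.numeric(pts[1, ]))
  y <- colMeans(pts)
  for (iter in seq_len(max_iter)) {
    d <- sqrt((pts[, 1] - y[1])^2 + (pts[, 2] - y[2])^2)
    at_point <- d < .Machine$double.eps * 100 * (1 + max(abs(y)))
    eta <- sum(at_point)
    if (eta == nrow(pts)) return(as.numeric(y))  # all points coincide
    w <- 1 / d[!at_point]
    tt <- colSums(pts[!at_point, , drop = FALSE] * w) / sum(w)
    if (eta > 0) {
      ## Vardi-Zhang: pull toward T only as far as the subgradient allows
      r <- sqrt(sum((colSums((pts[!at_point, , drop = FALSE] -
                                rep(y, each = sum(!at_point))) * w))^2))
      if (r <= eta) return(as.numeric(y))  # y is the optimum
      lambda <- eta / r
      y_new <- (1 - lambda) * tt + lambda * y
    } else {
      y_new <- tt
    }
    if (sqrt(sum((y_new - y)^2)) < tol) return(as.numeric(y_new))
    y <- y_new
  }
  cond <- structure(
    class = c("xl_weiszfeld_error", "error", "condition"),
    list(message = sprintf("Weiszfeld did not converge in %d iterations",
                           max_iter),
         call = sys.call(), iterate = as.numeric(y))
  )
  stop(cond)
}

#' Representative spectrum of an intensity distribution
#'
#' Projects each record to (log backbone_sum, log stub_sum), computes the
#' geometric median of the cloud and returns the scan_id of the nearest
#' record (Euclidean; ties to the lower scan_id).
#'
#' @param records Records with \code{scan_id}, \code{stub_sum},
#'   \code{backbone_sum}; rows with non-finite log-intensities are dropped.
#' @param log_base Base for the log-intensity plane (default 10); use
#'   \code{NA} for linear space.
#' @param tol,max_iter Passed to \code{\link{geometric_median}}.
#' @return The representative \code{scan_id}.
#' @export
representative_spectrum <- function(records, log_base = 10, tol = 1e-9,
                                    max_iter = 10000L) {
  x <- records$backbone_sum
  y <- records$stub_sum
  if (!is.na(log_base)) {
    x <- log(x, base = log_base)
    y <- log(y, base = log_base)
  }
  ok <- is.finite(x) & is.finite(y)
  stopifnot(any(ok))
  x <- x[ok]; y <- y[ok]
  ids <- as.character(records$scan_id[ok])
  gm <- geometric_median(cbind(x, y), tol = tol, max_iter = max_iter)
  d <- sqrt((x - gm[1])^2 + (y - gm[2])^2)
  cand <- which(d == min(d))
  ids[cand[order(ids[cand])[1]]]
}

#' Doublet prevalence
#'
#' Proportion of crosslinked records containing at least one, and both,
#' peptide doublets.
#'
#' @param records Records with \code{doublet_alpha_found} /
#'   \code{doublet_beta_found} (crosslinked class; other classes are
#'   filtered out if a \code{class} column is present).
#' @return List \code{p_at_least_one}, \code{p_both}, \code{n}.
#' @export
doublet_prevalence <- function(records) {
  if ("class" %in% names(records))
    records <- records[records$class == "crosslinked", , drop = FALSE]
  stopifnot(nrow(records) > 0)
  a <- records$doublet_alpha_found
  b <- records$doublet_beta_found
  list(p_at_least_one = mean(a | b), p_both = mean(a & b),
       n = nrow(records))
}

#' Doublet intensity-rank cutoff curve
#'
#' For each cutoff r: the proportion of records whose more-intense doublet
#' (the better of the two per-peptide best ranks) passes rank <= r, and the
#' proportion where both peptides' doublets do. A missing doublet
#' (\code{NA} rank) never passes.
#'
#' @param records Records with \code{best_rank_alpha}, \code{best_rank_beta}.
#' @param cutoffs Integer rank cutoffs (default 1, 5, 10, 20).
#' @return data.frame with columns \code{cutoff}, \code{p_more_intense},
#'   \code{p_both}.
#' @export
rank_cutoff_curve <- function(records, cutoffs = c(1L, 5L, 10L, 20L)) {
  if ("class" %in% names(records))
    records <- records[records$class == "crosslinked", , drop = FALSE]
  stopifnot(nrow(records) > 0)
  ra <- records$best_rank_alpha
  rb <- records$best_rank_beta
  best <- pmin(ra, rb, na.rm = TRUE)          # NA only if both NA
  best[is.na(ra) & is.na(rb)] <- NA
  worst <- pmax(ra, rb)                        # NA if either missing
  data.frame(
    cutoff = cutoffs,
    p_more_intense = vapply(cutoffs, function(r)
      mean(!is.na(best) & best <= r), numeric(1)),
    p_both = vapply(cutoffs, function(r)
      mean(!is.na(worst) & worst <= r), numeric(1))
  )
}

#' MS3 triggers per MS2, by spectrum class
#'
#' Mean number of triggered MS3 scans per MS2 with a normal-approximation
#' 0.95 confidence interval (mean +/- 1.96 sd / sqrt(n)).
#'
#' @param records Records with \code{class} and \code{n_ms3_triggered}.
#' @param conf Confidence level (default 0.95).
#' @return data.frame with columns \code{class}, \code{n}, \code{mean},
#'   \code{ci_lower}, \code{ci_upper}.
#' @export
ms3_trigger_stats <- function(records, conf = 0.95) {
  stopifnot(nrow(records) > 0)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  classes <- unique(records$class)
  do.call(rbind, lapply(classes, function(cl) {
    x <- records$n_ms3_triggered[records$class == cl]
    m <- mean(x)
    se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    data.frame(class = cl, n = length(x), mean = m,
               ci_lower = m - zq * se, ci_upper = m + zq * se)
  }))
}

#' MS3-trigger sensitivity
#'
#' Proportion of crosslinked records with at least one, and both, peptide
#' doublets correctly triggered for MS3. Always bounded above by the
#' corresponding doublet prevalence (an undetected doublet cannot trigger).
#'
#' @param records Records with \code{alpha_triggered},
#'   \code{beta_triggered}.
#' @return List \code{p_one_triggered}, \code{p_both_triggered}, \code{n}.
#' @export
trigger_sensitivity <- function(records) {
  if ("class" %in% names(records))
    records <- records[records$class == "crosslinked", , drop = FALSE]
  stopifnot(nrow(records) > 0)
  a <- records$alpha_triggered
  b <- records$beta_triggered
  list(p_one_triggered = mean(a | b), p_both_triggered = mean(a & b),
       n = nrow(records))
}
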