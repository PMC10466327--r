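test_that("orthogonality_stats: medians, fractions, zero handling", {
  rec <- data.frame(stub_sum = c(2, 2, 2), backbone_sum = c(2, 2, 2))
  out <- orthogonality_stats(rec)
  expect_equal(out$median_ratio, 1.0)
  expect_equal(out$fraction_stub_gt_backbone, 0.0)
  rec2 <- data.frame(stub_sum = c(1, 5, 25), backbone_sum = c(1, 1, 1))
  expect_equal(orthogonality_stats(rec2)$median_ratio, 5.0)
  # backbone_sum == 0 excluded from median, kept in the fraction
  rec3 <- data.frame(stub_sum = c(1, 5, 25, 9), backbone_sum = c(1, 1, 1, 0))
  out3 <- orthogonality_stats(rec3)
  expect_equal(out3$median_ratio, 5.0)
  expect_equal(out3$fraction_stub_gt_backbone, 0.75)
})

test_that("geometric_median: exact cases and grid oracle", {
  expect_equal(geometric_median(cbind(3, 4)), c(3, 4))
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(geometric_median(sq), c(0.5, 0.5), tolerance = 1e-6)
  # coincident points: all identical
  expect_equal(geometric_median(rbind(c(2, 2), c(2, 2), c(2, 2))), c(2, 2))
  # iterate landing on a data point (majority point is the optimum)
  maj <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 0), c(0, 5))
  expect_equal(geometric_median(maj), c(0, 0), tolerance = 1e-6)
  # objective never exceeds the best input point; matches grid oracle
  set.seed(31)
  for (i in 1:8) {
    np <- sample(5:80, 1)
    pts <- cbind(rnorm(np, sd = 3), rnorm(np, sd = 3))
    gm <- geometric_median(pts)
    best_pt <- min(apply(pts, 1, sum_dist, pts = pts))
    expect_lte(sum_dist(gm, pts), best_pt + 1e-6)
    grid <- oracle_grid_median(pts)
    expect_lte(sum_dist(gm, pts), sum_dist(grid, pts) + 1e-6)
  }
  # non-convergence carries the last iterate
  err <- tryCatch(geometric_median(sq, tol = 0, max_iter = 3),
                  xl_weiszfeld_error = function(e) e)
  expect_s3_class(err, "xl_weiszfeld_error")
  expect_length(err$iterate, 2)
})

test_that("representative_spectrum picks the nearest record", {
  one <- data.frame(scan_id = "a", stub_sum = 10, backbone_sum = 10)
  expect_equal(representative_spectrum(one), "a")
  # median coincides with a data point
  rec <- data.frame(scan_id = c("a", "b", "c", "d", "e"),
                    stub_sum = 10^c(1, 2, 1.5, 1.5, 1.5),
                    backbone_sum = 10^c(1.5, 1.5, 1, 2, 1.5))
  expect_equal(representative_spectrum(rec), "e")
  # random sets: equals brute-force nearest point to the geometric median
  set.seed(32)
  for (i in 1:6) {
    n <- sample(5:50, 1)
    rec <- data.frame(scan_id = sprintf("s%03d", 1:n),
                      stub_sum = 10^runif(n, 1, 5),
                      backbone_sum = 10^runif(n, 1, 5))
    pts <- cbind(log10(rec$backbone_sum), log10(rec$stub_sum))
    gm <- geometric_median(pts)
    d <- sqrt((pts[, 1] - gm[1])^2 + (pts[, 2] - gm[2])^2)
    expect_equal(representative_spectrum(rec), rec$scan_id[which.min(d)])
  }
})

test_that("doublet_prevalence proportions", {
  rec <- data.frame(doublet_alpha_found = c(TRUE, TRUE, FALSE, TRUE),
                    doublet_beta_found = c(FALSE, TRUE, FALSE, TRUE))
  out <- doublet_prevalence(rec)
  expect_equal(out$p_at_least_one, 0.75)
  expect_equal(out$p_both, 0.5)
  all_found <- data.frame(doublet_alpha_found = rep(TRUE, 3),
                          doublet_beta_found = rep(TRUE, 3))
  expect_equal(doublet_prevalence(all_found)$p_both, 1.0)
  # closed form: independent dropout q per doublet
  set.seed(33)
  q <- 0.2; n <- 4000
  rec2 <- data.frame(doublet_alpha_found = runif(n) > q,
                     doublet_beta_found = runif(n) > q)
  p <- doublet_prevalence(rec2)$p_both
  ci <- qnorm(0.975) * sqrt((1 - q)^2 * (1 - (1 - q)^2) / n)
  expect_lt(abs(p - (1 - q)^2), 3 * ci)
})

test_that("rank_cutoff_curve: counting and monotonicity", {
  rec <- data.frame(best_rank_alpha = 3L, best_rank_beta = 7L)
  out <- rank_cutoff_curve(rec, cutoffs = c(5L, 10L))
  expect_equal(out$p_more_intense, c(1.0, 1.0))
  expect_equal(out$p_both, c(0.0, 1.0))
  all1 <- data.frame(best_rank_alpha = rep(1L, 4),
                     best_rank_beta = rep(1L, 4))
  expect_true(all(rank_cutoff_curve(all1)$p_both == 1.0))
  # counting oracle + monotonicity on random fixtures; NA = missing doublet
  set.seed(34)
  for (i in 1:10) {
    n <- 50
    ra <- sample(c(1:40, NA), n, TRUE)
    rb <- sample(c(1:40, NA), n, TRUE)
    rec <- data.frame(best_rank_alpha = ra, best_rank_beta = rb)
    cuts <- c(1L, 5L, 10L, 20L)
    out <- rank_cutoff_curve(rec, cuts)
    best <- pmin(ra, rb, na.rm = TRUE)
    best[is.na(ra) & is.na(rb)] <- NA
    for (k in seq_along(cuts)) {
      r <- cuts[k]
      expect_equal(out$p_more_intense[k], mean(!is.na(best) & best <= r))
      expect_equal(out$p_both[k],
                   mean(!is.na(ra) & !is.na(rb) & ra <= r & rb <= r))
    }
    expect_true(all(diff(out$p_more_intense) >= 0))
    expect_true(all(diff(out$p_both) >= 0))
    expect_true(all(out$p_both <= out$p_more_intense))
  }
})

test_that("ms3_trigger_stats: mean and normal CI per class", {
  rec <- data.frame(class = rep("crosslinked", 3),
                    n_ms3_triggered = c(2L, 2L, 2L))
  out <- ms3_trigger_stats(rec)
  expect_equal(out$mean, 2.0)
  expect_equal(out$ci_lower, out$ci_upper)
  rec2 <- data.frame(class = rep("linear", 4), n_ms3_triggered = 0:3)
  out2 <- ms3_trigger_stats(rec2)
  expect_equal(out2$mean, 1.5)
  se <- sd(0:3) / 2
  expect_equal(out2$ci_upper - out2$mean, qnorm(0.975) * se,
               tolerance = 1e-9)
  # Poisson simulation: true lambda inside the CI most of the time
  set.seed(35)
  lam <- 1.7
  rec3 <- data.frame(class = "x", n_ms3_triggered = rpois(2000, lam))
  out3 <- ms3_trigger_stats(rec3)
  expect_lt(abs(out3$mean - lam), 4 * sd(rec3$n_ms3_triggered) / sqrt(2000))
})

test_that("trigger_sensitivity and its prevalence bound", {
  rec <- data.frame(
    class = "crosslinked",
    doublet_alpha_found = c(TRUE, TRUE, TRUE, FALSE),
    doublet_beta_found = c(TRUE, TRUE, FALSE, FALSE),
    alpha_triggered = c(TRUE, TRUE, TRUE, FALSE),
    beta_triggered = c(TRUE, FALSE, FALSE, FALSE))
  out <- trigger_sensitivity(rec)
  expect_equal(out$p_one_triggered, 0.75)
  expect_equal(out$p_both_triggered, 0.25)
  prev <- doublet_prevalence(rec)
  expect_lte(out$p_both_triggered, prev$p_both)
  expect_lte(out$p_one_triggered, prev$p_at_least_one)
  # zero MS3 budget
  none <- transform(rec, alpha_triggered = FALSE, beta_triggered = FALSE)
  expect_equal(trigger_sensitivity(none)$p_one_triggered, 0)
})
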