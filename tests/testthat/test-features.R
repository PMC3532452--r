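pe <- library_profile("PE", 300, 30)
mp <- library_profile("MP", 3000, 300)
th <- thresholds()

test_that("CE statistic matches direct arithmetic and handles empty windows", {
  expect_equal(ce_statistic(rep(300, 10), pe), 0)
  expect_equal(ce_statistic(rep(330, 9), pe), 3)
  expect_true(is.na(ce_statistic(numeric(0), pe)))
  set.seed(4)
  x <- rnorm(25, 310, 20)
  expect_equal(ce_statistic(x, pe), (mean(x) - 300) / (30 / sqrt(25)))
})

test_that("coverage detectors flag threshold crossings and nothing else", {
  st <- structure(list(mean_read_cov = 40, mean_proper_cov = 40,
                       genome_size = 1e5, insert_mean = 300, insert_sd = 30,
                       n_fragments = 0L, lib_role = "PE"),
                  class = "global_stats")
  flat <- fake_tracks(rep(40L, 3000L))
  expect_equal(nrow(detect_coverage_features(flat, st, th)), 0L)

  dipped <- rep(40L, 3000L)
  dipped[1001:1500] <- 5L
  regs <- detect_coverage_features(fake_tracks(dipped), st, th)
  low <- regs[regs$type == "LOW_COV_PE", ]
  expect_equal(nrow(low), 1L)
  expect_equal(c(low$start, low$end), c(1000L, 1500L))
  # proper_cov mirrors read_cov here, so the normalised twin fires too
  expect_true("LOW_NORM_COV_PE" %in% regs$type)

  expect_error(detect_coverage_features(fake_tracks(rep(0L, 10L)),
                                        structure(list(mean_read_cov = 0,
                                                       mean_proper_cov = 0,
                                                       lib_role = "PE"),
                                                  class = "global_stats"), th),
               "empty alignment")
  expect_error(detect_coverage_features(fake_tracks(rep(1L, 10L),
                                                    lib_role = "MP"), st, th),
               "PE library")
})

test_that("coverage runs equal per-position thresholding plus merging", {
  set.seed(31)
  st <- structure(list(mean_read_cov = 30, mean_proper_cov = 30,
                       lib_role = "PE"), class = "global_stats")
  for (rep in 1:5) {
    cov <- sample(c(0L, 5L, 30L, 120L), 4000L, replace = TRUE,
                  prob = c(0.05, 0.1, 0.85, 0.05))
    regs <- detect_coverage_features(fake_tracks(cov), st, th)
    low <- regs[regs$type == "LOW_COV_PE", ]
    flagged <- cov < th$cov_low_frac * 30
    want <- oracle_merge(which(diff(c(FALSE, flagged)) == 1L) - 1L,
                         which(diff(c(flagged, FALSE)) == -1L),
                         th$merge_gap, th$min_region)
    expect_equal(unname(cbind(low$start, low$end)), unname(want))
  }
})

test_that("CE detector flags windows outside the thresholds at tile resolution", {
  tr <- fake_tracks(rep(30L, 5000L))
  n_win <- length(tr$win_n)
  # every window exactly at the insert mean: no regions
  tr$win_n <- rep(25L, n_win)
  tr$win_sum <- 300 * tr$win_n
  expect_equal(nrow(detect_ce_features(tr, pe, th)), 0L)

  # one stretched window; min_region at the tile width keeps it
  th_tile <- thresholds(min_region = 200L)
  hot <- 5L
  tr$win_sum[hot] <- (300 + 3.5 * 30 / sqrt(25)) * 25
  regs <- detect_ce_features(tr, pe, th_tile, size_bias_correction = FALSE)
  expect_equal(regs$type, "STRECH_PE")
  expect_equal(c(regs$start, regs$end),
               c(tr$win_mid[hot] - 100L, tr$win_mid[hot] + 100L))

  # windows with no data are skipped, never treated as compressed
  tr$win_n[] <- 0L
  tr$win_sum[] <- 0
  expect_equal(nrow(detect_ce_features(tr, pe, th)), 0L)

  # MP tracks carry the MP suffix
  tr$lib_role <- "MP"
  tr$win_n <- rep(25L, n_win)
  tr$win_sum <- (3000 - 5 * 300 / sqrt(25)) * tr$win_n
  regs <- detect_ce_features(tr, mp, th_tile, size_bias_correction = FALSE)
  expect_true(all(regs$type == "COMPR_MP"))
})

test_that("pair-anomaly detector uses the window-mean anomaly ratio", {
  cov <- rep(100L, 4000L)
  clean <- fake_tracks(cov)
  expect_equal(nrow(detect_pair_anomaly_features(clean, pe, th)), 0L)

  # half the reads across a 1.2 kb stretch are outies: 0.5 > 0.4
  outie <- integer(4000L)
  outie[1001:2200] <- 50L
  tr <- fake_tracks(cov, outie_cnt = outie)
  regs <- detect_pair_anomaly_features(tr, pe, th)
  expect_equal(unique(regs$type), "HIGH_OUTIE_PE")
  expect_gt(nrow(regs), 0L)
  # the call covers the core of the anomalous stretch
  expect_lte(regs$start[1], 1400L)
  expect_gte(max(regs$end), 1800L)

  # uncovered positions are skipped rather than counted as anomalous
  tr <- fake_tracks(integer(4000L), singleton_cnt = integer(4000L))
  expect_equal(nrow(detect_pair_anomaly_features(tr, pe, th)), 0L)
})

test_that("merging respects gap and minimum-length rules", {
  r2 <- feature_df(c(100L, 250L), c(200L, 400L))
  m <- merge_regions(r2, merge_gap = 100L, min_region = 0L)
  expect_equal(c(m$start, m$end), c(100L, 400L))

  r2 <- feature_df(c(100L, 400L), c(200L, 500L))
  m <- merge_regions(r2, merge_gap = 100L, min_region = 0L)
  expect_equal(nrow(m), 2L)

  mixed <- feature_df(c(0L, 50L), c(10L, 60L))
  mixed$type <- c("LOW_COV_PE", "HIGH_COV_PE")
  expect_error(merge_regions(mixed), "single type")
})

test_that("merging equals the quadratic union-then-filter oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(1:15, 1L)
    s <- sort(sample.int(5000L, n)) - 1L
    e <- s + sample.int(400L, n)
    gap <- sample.int(300L, 1L)
    mn <- sample.int(300L, 1L)
    got <- merge_regions(feature_df(s, e), gap, mn)
    want <- oracle_merge(s, e, gap, mn)
    expect_equal(unname(cbind(got$start, got$end)), unname(want))
  }
})

test_that("loosening a threshold never increases flagged bases", {
  set.seed(23)
  tr <- fake_tracks(rpois(6000L, 30),
                    outie_cnt = as.integer(rbinom(6000L, 30, 0.3)))
  tr$win_n <- rep(25L, length(tr$win_n))
  tr$win_sum <- (300 + rnorm(length(tr$win_n), 0, 60 / sqrt(25))) * 25
  st <- structure(list(mean_read_cov = 30, mean_proper_cov = 30,
                       lib_role = "PE"), class = "global_stats")

  base_th <- thresholds(min_region = 0L)
  for (loose in list(thresholds(cov_low_frac = 0.2, min_region = 0L),
                     thresholds(cov_high_frac = 5, min_region = 0L))) {
    expect_lte(flagged_bases(detect_coverage_features(tr, st, loose)),
               flagged_bases(detect_coverage_features(tr, st, base_th)))
  }
  expect_lte(flagged_bases(detect_ce_features(tr, pe, thresholds(ce_high = 4,
                                                                 min_region = 0L))),
             flagged_bases(detect_ce_features(tr, pe, base_th)))
  expect_lte(flagged_bases(detect_pair_anomaly_features(tr, pe,
                                                        thresholds(anomaly_frac = 0.6,
                                                                   min_region = 0L))),
             flagged_bases(detect_pair_anomaly_features(tr, pe, base_th)))
})

test_that("per-type regions are disjoint and sorted after annotation", {
  set.seed(41)
  tr <- fake_tracks(rpois(6000L, 30),
                    outie_cnt = as.integer(rbinom(6000L, 30, 0.35)))
  tr$win_n <- rep(25L, length(tr$win_n))
  tr$win_sum <- (305 + rnorm(length(tr$win_n), 0, 80 / sqrt(25))) * 25
  st <- structure(list(mean_read_cov = 30, mean_proper_cov = 30,
                       genome_size = 1e5, insert_mean = 300, insert_sd = 30,
                       n_fragments = 100L, lib_role = "PE"),
                  class = "global_stats")
  feats <- annotate_contig(tr, st)
  expect_false(any(grepl("_MP$", feats$type)))
  for (tp in unique(feats$type)) {
    f <- feats[feats$type == tp, ]
    f <- f[order(f$start), ]
    if (nrow(f) > 1L) expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  }
})
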