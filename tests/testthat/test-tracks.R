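pe <- library_profile("PE", 300, 30)

test_that("single-read and single-pair tracks match their definitions", {
  one <- rv("c", 0L, 100L, paired = FALSE, mate_mapped = FALSE,
            mate_contig = NA, mate_strand = NA, leftmost = FALSE)
  tr <- build_tracks(one, pe, "c", 200L)
  expect_equal(tr$read_cov, rep(c(1L, 0L), each = 100L))
  expect_equal(sum(tr$proper_cov), 0L)

  pair <- make_pair("c", 0L, 300L, 100L)
  tr <- build_tracks(pair, pe, "c", 400L)
  expect_equal(tr$span_cov, rep(c(1L, 0L), c(300L, 100L)))
  expect_equal(tr$proper_cov,
               as.integer(seq_len(400L) %in% c(1:100, 201:300)))
  expect_equal(tr$proper_fragments, 300)
})

test_that("randomised tracks equal the brute-force per-base oracle", {
  set.seed(21)
  for (rep in 1:5) {
    len <- sample(800:2000, 1L)
    reads <- random_reads(sample(20:50, 1L), len, pe)
    tr <- build_tracks(reads, pe, "c", len, window = 500L, step = 100L)
    want <- oracle_tracks(reads, pe, len, window = 500L, step = 100L)
    expect_equal(tr$read_cov, want$read_cov)
    expect_equal(tr$proper_cov, want$proper_cov)
    expect_equal(tr$span_cov, want$span_cov)
    expect_equal(tr$singleton_cnt, want$singleton_cnt)
    expect_equal(tr$outie_cnt, want$outie_cnt)
    expect_equal(tr$spanning_cnt, want$spanning_cnt)
    expect_equal(tr$win_n, want$win_n)
    expect_equal(tr$win_sum, want$win_sum)
  }
})

test_that("coverage conservation and containment invariants hold", {
  reads <- random_reads(80L, 3000L, pe, seed = 5)
  tr <- build_tracks(reads, pe, "c", 3000L)
  expect_equal(sum(tr$read_cov), sum(reads$width))
  expect_true(all(tr$proper_cov <= tr$read_cov))
  expect_true(all(tr$span_cov >= tr$proper_cov | tr$proper_cov == 0L))
})

test_that("degenerate inputs are handled per contract", {
  empty <- build_tracks(rv("c")[0, ], pe, "c", 500L)
  expect_equal(sum(empty$read_cov), 0L)
  expect_equal(empty$n_reads, 0L)
  expect_error(build_tracks(rv("c", pos = 450L, width = 100L), pe, "c", 500L),
               "beyond contig")
})

test_that("global stats pool coverage and refine the insert estimate", {
  # 40x uniform: 40 unpaired reads tiling a 100 bp contig end to end
  reads <- do.call(rbind, replicate(40, rv("c", 0L, 100L, paired = FALSE,
                                           mate_mapped = FALSE,
                                           mate_contig = NA, mate_strand = NA,
                                           leftmost = FALSE),
                                    simplify = FALSE))
  tr <- build_tracks(reads, pe, "c", 100L)
  st <- estimate_global_stats(tr, pe, genome_size = 1000L)
  expect_equal(st$mean_read_cov, 40)
  expect_equal(st$genome_size, 1000)

  # identical fragments: refined mean exact, sd floored at 1 bp
  pairs <- do.call(rbind, lapply(0:9 * 40L, function(s) make_pair("c", s, 300L)))
  tr <- build_tracks(pairs, pe, "c", 1000L)
  st <- estimate_global_stats(tr, pe, 1000L)
  expect_equal(st$insert_mean, 300)
  expect_equal(st$insert_sd, 1)

  # Gaussian fragments: refined mean within 3 standard errors
  mp <- library_profile("MP", 3000, 300)
  set.seed(9)
  frags <- round(rnorm(1000, 3000, 300))
  fake <- build_tracks(rv("c")[0, ], mp, "c", 100L)
  fake$proper_fragments <- frags
  fake$n_reads <- 2000L
  st <- estimate_global_stats(fake, mp, 1e6)
  expect_lt(abs(st$insert_mean - 3000), 3 * 300 / sqrt(1000))

  expect_error(estimate_global_stats(build_tracks(rv("c")[0, ], pe, "c", 10L),
                                     pe, 1000L),
               "empty alignment")
})
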