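pe <- library_profile("PE", 300, 30)
mp <- library_profile("MP", 3000, 300)

test_that("reference generation is seeded, GC-bounded and plants repeats", {
  a <- generate_reference(1000L, 0.5, seed = 7)
  expect_identical(a, generate_reference(1000L, 0.5, seed = 7))
  expect_equal(nchar(a), 1000L)

  gc_only <- generate_reference(500L, 1, seed = 3)
  expect_true(grepl("^[GC]+$", gc_only))

  rep_spec <- list(n_repeats = 1L, repeat_len = 500L, n_copies = 3L)
  g <- generate_reference(20000L, 0.5, repeats = rep_spec, seed = 11)
  # every 100-mer of the repeat unit occurs in all three copies, so some
  # 100-mer must appear at least 3 times; random 100-mers are unique
  kmers <- substring(g, 1:(nchar(g) - 99L), 100:nchar(g))
  expect_gte(max(table(kmers)), 3L)

  expect_error(generate_reference(1000L,
                                  repeats = list(n_repeats = 2L,
                                                 repeat_len = 400L,
                                                 n_copies = 2L), seed = 1),
               "repeat mass")
})

test_that("an empty event list reproduces the reference with identity liftover", {
  ref <- generate_reference(2000L, seed = 5)
  sim <- apply_misassembly_events(ref, list())
  expect_equal(unname(sim$contigs), ref)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(sim$blocks), 1L)
  expect_equal(sim$blocks$strand, 1L)
})

test_that("events reshape the assembly as defined", {
  ref <- generate_reference(10000L, seed = 6)

  inv <- apply_misassembly_events(ref, list(
    misassembly_event("INVERSION", start = 2000L, end = 3000L)))
  seg <- substr(unname(inv$contigs), 2001L, 3000L)
  expect_equal(seg, frcurve:::revcomp(substr(ref, 2001L, 3000L)))
  expect_equal(inv$truth$type, "INVERSION")
  expect_equal(c(inv$truth$start, inv$truth$end), c(2000L, 3000L))

  ref2 <- plant_duplicate(ref, 5000L, 5500L)
  com <- apply_misassembly_events(ref2, list(
    misassembly_event("COMPRESSION", start = 5000L, end = 5500L)))
  expect_equal(unname(nchar(com$contigs)), 10000L - 500L)

  frag <- apply_misassembly_events(ref, list(
    misassembly_event("FRAGMENTATION", pos = 4000L)))
  expect_equal(unname(frag$contig_lengths), c(4000L, 6000L))
  expect_equal(frag$truth$type, rep("FRAGMENTATION", 2L))

  exp_ <- apply_misassembly_events(ref, list(
    misassembly_event("EXPANSION", start = 1000L, end = 1400L)))
  expect_equal(unname(nchar(exp_$contigs)), 10400L)

  rel <- apply_misassembly_events(ref, list(
    misassembly_event("RELOCATION", start = 6000L, end = 7000L,
                      target = 2000L)))
  asm <- unname(rel$contigs)
  expect_equal(nchar(asm), 10000L)
  expect_equal(substr(asm, 2001L, 3000L), substr(ref, 6001L, 7000L))
  expect_equal(sum(rel$truth$type == "RELOCATION"), 3L)

  expect_error(apply_misassembly_events(ref, list(
    misassembly_event("INVERSION", start = 100L, end = 500L),
    misassembly_event("DELETION", start = 400L, end = 600L))), "overlap")
})

test_that("simulated pairs respect count, orientation and sequence contracts", {
  ref <- generate_reference(100000L, seed = 13)
  pp <- simulate_pairs(ref, pe, coverage = 40, read_len = 100L, seed = 2)
  expect_equal(nrow(pp), floor(40 * 100000 / (2 * 100)))
  # error-free reads are exact reference substrings (stored reference-forward)
  i <- sample.int(nrow(pp), 50L)
  expect_equal(pp$left_seq[i],
               substring(ref, pp$left_start[i] + 1L, pp$left_end[i]))
  # fragment sample mean within 3 standard errors
  expect_lt(abs(mean(pp$fragment) - 300), 3 * 30 / sqrt(nrow(pp)))

  mpp <- simulate_pairs(ref, mp, coverage = 5, read_len = 100L, seed = 3)
  expect_true(all(mpp$left_strand == "-" & mpp$right_strand == "+"))
  expect_error(simulate_pairs(generate_reference(1000L, seed = 1), mp, 10, 100L),
               "insert_mean")
})

test_that("identity liftover yields proper pairs", {
  ref <- generate_reference(20000L, seed = 8)
  sim <- apply_misassembly_events(ref, list())
  pp <- simulate_pairs(ref, pe, coverage = 10, read_len = 100L, seed = 4)
  aln <- liftover_alignments(pp, sim)
  expect_true(all(aln$mapped))
  cls <- classify_pairs(aln, pe)
  # no mis-orientation, spanning or singleton evidence; the only non-proper
  # pairs are the distribution's own >3-sigma fragment tails (~0.3%)
  expect_true(all(cls %in% c("PROPER", "OUTIE")))
  expect_gt(mean(cls == "PROPER"), 0.99)
  expect_equal(sort(unique(aln$cigar)), "100M")

  # with fragments pinned at the mean, every pair is proper
  pinned <- pp
  shift <- 300L - pinned$fragment
  pinned$fragment <- 300L
  pinned$right_start <- pinned$right_start + shift
  pinned$right_end <- pinned$right_end + shift
  ok <- pinned$right_end <= 20000L
  cls2 <- classify_pairs(liftover_alignments(pinned[ok, ], sim), pe)
  expect_true(all(cls2 == "PROPER"))
})

test_that("liftover encodes event geometry in the pair signals", {
  ref <- plant_duplicate(generate_reference(20000L, seed = 9), 10000L, 10500L)
  sim <- apply_misassembly_events(ref, list(
    misassembly_event("COMPRESSION", start = 10000L, end = 10500L)))

  # a pair cleanly flanking the collapsed copy maps 500 bp closer together
  pp <- simulate_pairs(ref, mp, coverage = 3, read_len = 100L, seed = 5)
  aln <- liftover_alignments(pp, sim)
  sel <- pp$left_end <= 9950L & pp$right_start >= 10550L
  ids <- sprintf("pair_%08d", pp$pair[sel])
  sub <- aln[aln$qname %in% ids & aln$mate == 1L, ]
  expect_gt(nrow(sub), 10L)
  expect_true(all(sub$mapped))
  expect_equal(sub$fragment,
               pp$fragment[sel][match(sub$qname, ids)] - 500L)

  # one mate inside an inversion becomes mis-oriented
  sim_inv <- apply_misassembly_events(generate_reference(20000L, seed = 10),
                                      list(misassembly_event("INVERSION",
                                                             start = 8000L,
                                                             end = 12000L)))
  ref_inv <- generate_reference(20000L, seed = 10)
  ppi <- simulate_pairs(ref_inv, pe, coverage = 10, read_len = 100L, seed = 6)
  ai <- liftover_alignments(ppi, sim_inv)
  inside <- function(s, e) s >= 8000L & e <= 12000L
  outside <- function(s, e) e <= 8000L | s >= 12000L
  one_in <- (inside(ppi$left_start, ppi$left_end) &
               outside(ppi$right_start, ppi$right_end)) |
    (outside(ppi$left_start, ppi$left_end) &
       inside(ppi$right_start, ppi$right_end))
  crossing <- sprintf("pair_%08d", ppi$pair[one_in])
  sub <- ai[ai$qname %in% crossing & ai$mapped & ai$mate_mapped, ]
  expect_gt(nrow(sub), 5L)
  expect_true(all(classify_pairs(sub, pe) == "OUTIE"))

  # reads from deleted sequence are unmapped; their mates become singletons
  sim_del <- apply_misassembly_events(ref_inv, list(
    misassembly_event("DELETION", start = 5000L, end = 6000L)))
  ad <- liftover_alignments(ppi, sim_del)
  from_del <- ppi$left_start >= 5000L & ppi$left_end <= 6000L
  ids <- sprintf("pair_%08d", ppi$pair[from_del])
  expect_true(all(!ad$mapped[ad$qname %in% ids & ad$mate == 1L]))
  mates <- ad[ad$qname %in% ids & ad$mate == 2L & ad$mapped, ]
  expect_true(all(classify_pairs(mates, pe) == "SINGLETON"))
})

test_that("reads straddling a breakpoint are clipped or dropped by tolerance", {
  ref <- generate_reference(4000L, seed = 14)
  sim <- apply_misassembly_events(ref, list(
    misassembly_event("FRAGMENTATION", pos = 2000L)))
  # read overhanging the cut by 10 bases is soft-clipped, by 50 it is unmapped
  pairs <- data.frame(pair = 1:2, fragment = 400L,
                      left_start = c(1910L, 1950L),
                      left_end = c(2010L, 2050L),
                      left_strand = "+",
                      right_start = c(2210L, 2250L),
                      right_end = c(2310L, 2350L), right_strand = "-",
                      left_seq = "N", right_seq = "N",
                      stringsAsFactors = FALSE)
  aln <- liftover_alignments(pairs, sim, breakpoint_tolerance = 20L)
  a1 <- aln[aln$qname == "pair_00000001" & aln$mate == 1L, ]
  expect_true(a1$mapped)
  expect_equal(a1$cigar, "90M10S")
  a2 <- aln[aln$qname == "pair_00000002" & aln$mate == 1L, ]
  expect_false(a2$mapped)
})
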