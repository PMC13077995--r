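test_that("find_segments maps exact substrings on both strands", {
  g <- fixture_genome()
  s <- genome_seq(g, 100, 400)
  seg <- find_segments(s, g)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$query_start, 0L)
  expect_equal(seg$query_end, 300L)
  expect_equal(seg$ref_start, 100L)
  expect_equal(seg$ref_end, 400L)
  expect_equal(seg$strand, "+")
  expect_equal(seg$score, 300L)

  segm <- find_segments(revcomp(s), g)
  expect_equal(segm$strand, "-")
  expect_equal(segm$ref_start, 100L)
  expect_equal(segm$ref_end, 400L)

  # short reads are not scanned
  short <- find_segments(substr(s, 1, 50), g)
  expect_equal(nrow(short), 0L)
  expect_match(attr(short, "note"), "shorter")
})

test_that("a bridged deletion splits into two segments matching the oracle", {
  g <- fixture_genome()
  rd <- paste0(genome_seq(g, 100, 300), genome_seq(g, 350, 550))
  seg <- find_segments(rd, g)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$ref_start, c(100L, 350L))
  expect_equal(seg$ref_end, c(300L, 550L))
  orc <- oracle_segments(rd, g)
  expect_true(segments_agree(seg, orc, tol = 3L))
})

test_that("chain_and_call types junctions and events", {
  g <- fixture_genome()
  # single locus is not a hybrid
  s <- genome_seq(g, 100, 700)
  expect_null(chain_and_call(find_segments(s, g), read_seq = s, genome = g))

  # pos_pos deletion
  rd <- paste0(genome_seq(g, 100, 300), genome_seq(g, 330, 500))
  call <- chain_and_call(find_segments(rd, g), read_seq = rd, genome = g,
                         read_id = "del30")
  expect_equal(call$junction_type, "pos_pos")
  expect_equal(call$event, "deletion")
  expect_equal(call$delta, 30L)
  expect_true(call$in_paper_range)
  expect_equal(call$j1_ref, 300L)
  expect_equal(call$j2_ref, 330L)

  # foldback: opposite strands, overlapping reference
  fb <- paste0(genome_seq(g, 1000, 1400), revcomp(genome_seq(g, 1250, 1400)))
  cf <- chain_and_call(find_segments(fb, g), read_seq = fb, genome = g,
                       read_id = "fb")
  expect_equal(cf$junction_type, "foldback")
  expect_equal(cf$event, "none")
})

test_that("classify_event computes signed offsets in transcript orientation", {
  ev <- classify_event("+", 100L, 300L, 330L, 500L)
  expect_equal(ev$event, "deletion")
  expect_equal(ev$delta, 30L)

  ev2 <- classify_event("+", 100L, 300L, 260L, 500L)
  expect_equal(ev2$event, "duplication")
  expect_equal(ev2$delta, -40L)

  # negative-strand junction: computed on the reverse-complement frame
  ev3 <- classify_event("-", 1255L, 1700L, 900L, 1300L)
  expect_equal(ev3$event, "duplication")
  expect_equal(ev3$delta, -45L)

  expect_error(classify_event(c("+", "-"), 1L, 2L, 3L, 4L), "foldback")
})

test_that("simulated hybrids are recovered with junctions within 5 nt", {
  g <- fixture_genome()
  spec <- data.frame(
    type = c("pos_pos", "pos_pos", "neg_neg", "neg_neg"),
    event = c("deletion", "duplication", "deletion", "duplication"),
    n = 5L, delta_min = 20L, delta_max = 60L
  )
  h <- simulate_hybrids(g, spec, seed = 2L, error_rate = 0.02)
  calls <- detect_hybrids(h$reads, g)
  first <- calls[calls$junction_index == 1L, ]
  m <- match(h$truth$read_id, first$read_id)
  expect_gte(mean(!is.na(m)), 0.95)
  ok <- !is.na(m)
  expect_true(all(first$event[m[ok]] == h$truth$event[ok]))
  expect_true(all(abs(abs(first$delta[m[ok]]) - h$truth$delta[ok]) <= 5))
  # junction coordinates within 5 nt (unordered pair comparison); an error
  # landing on the junction flank can shift a split a few nt, so allow the
  # occasional outlier at this small n
  jok <- vapply(which(ok), function(i) {
    got <- sort(c(first$j1_ref[m[i]], first$j2_ref[m[i]]))
    want <- sort(c(h$truth$j1[i], h$truth$j2[i]))
    all(abs(got - want) <= 5)
  }, logical(1))
  expect_gte(mean(jok), 0.90)
})

test_that("foldbacks are labelled foldback, never deletion/duplication", {
  g <- fixture_genome()
  h <- simulate_hybrids(g, data.frame(type = "foldback", n = 10L,
                                      delta_min = NA, delta_max = NA),
                        seed = 3L, error_rate = 0.02)
  calls <- detect_hybrids(h$reads, g)
  first <- calls[calls$junction_index == 1L, ]
  m <- match(h$truth$read_id, first$read_id)
  expect_gte(mean(!is.na(m)), 0.9)
  expect_true(all(first$junction_type[m[!is.na(m)]] == "foldback"))
  expect_true(all(first$event[m[!is.na(m)]] == "none"))
})

test_that("non-hybrid reads produce no calls on error-free sequence", {
  g <- fixture_genome()
  sim <- simulate_reads(g, 60, seed = 13L, error_rate = 0,
                        sequences = TRUE)
  calls <- detect_hybrids(sim$reads, g)
  expect_equal(nrow(calls), 0L)
})

test_that("hybrid_summary reports ratios per group", {
  g <- fixture_genome()
  all_reads <- tibble::tibble(
    read_id = sprintf("r%04d", 1:1000), timepoint = "6h"
  )
  calls <- tibble::tibble(
    read_id = c("r0001", "r0002"), junction_index = 1L,
    junction_type = c("pos_pos", "neg_neg"),
    event = c("deletion", "duplication"), delta = c(30L, -40L),
    in_paper_range = TRUE, j1_ref = 1L, j2_ref = 2L,
    q_end1 = 1L, q_start2 = 1L, strand1 = "+", strand2 = "+",
    ref_start1 = 1L, ref_end1 = 2L, ref_start2 = 3L, ref_end2 = 4L,
    n_segments = 2L, timepoint = "6h", sample = "t", query_length = 500L,
    strand = "+"
  )
  hsum <- hybrid_summary(calls, all_reads)
  expect_equal(hsum$ratio, 0.002)
  expect_equal(hsum$n_deletion, 1L)
  expect_equal(hsum$n_duplication, 1L)

  empty <- hybrid_summary(calls[0, ], all_reads)
  expect_equal(empty$ratio, 0)
})
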