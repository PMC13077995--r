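test_that("make_genome plants ORF signals and is seed-deterministic", {
  g <- fixture_genome()
  expect_equal(g$length, 3569L)
  expect_equal(nrow(g$orfs), 4L)
  for (k in seq_len(4)) {
    s <- g$orfs$start[k]; e <- g$orfs$end[k]
    expect_equal(genome_seq(g, s, s + 3L), "ATG")
    expect_true(genome_seq(g, e - 3L, e) %in% c("TAA", "TAG", "TGA"))
    # AG-rich hexamer 8-12 nt upstream of the start
    upstream <- genome_seq(g, s - 18L, s - 8L)
    expect_true(grepl("AGGAGG", upstream))
  }
  g2 <- make_genome(seed = 1L)
  expect_identical(g2$sequence, g$sequence)
  g3 <- make_genome(seed = 2L)
  expect_false(identical(g3$sequence, g$sequence))

  toy <- make_genome(length = 1000L,
                     orf_layout = data.frame(name = "orf1", start = 100L,
                                             end = 400L),
                     seed = 3L)
  expect_equal(toy$length, 1000L)
  expect_equal(genome_seq(toy, 100L, 103L), "ATG")
})

test_that("class generators respect their coordinate contracts", {
  g <- fixture_genome()
  fl <- simulate_reads(g, 50, mixture = c(full_length = 1), seed = 5L,
                       sequences = FALSE)
  expect_true(all(fl$reads$ref_end - fl$reads$ref_start >= 0.93 * g$length))

  coat <- orf_interval_test(g, "coat")
  cs <- simulate_reads(g, 20, mixture = c(coat_subgenomic = 1), seed = 6L,
                       sequences = FALSE)
  expect_true(all(cs$reads$ref_start <= coat[1]))
  expect_true(all(cs$reads$ref_end >= coat[2]))
  expect_true(all(cs$reads$ref_end - cs$reads$ref_start < 800))

  tp <- simulate_reads(g, 30, mixture = c(three_prime_anchored = 1),
                       seed = 7L, sequences = FALSE)
  expect_true(all(tp$reads$ref_end >= g$length - 10))
  expect_true(all(tp$reads$ref_start > 25))

  # determinism: identical truth tables for the same seed
  a <- simulate_reads(g, 200, seed = 8L, sequences = TRUE)
  b <- simulate_reads(g, 200, seed = 8L, sequences = TRUE)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads$seq, b$reads$seq)

  # mixture must sum to 1
  expect_error(simulate_reads(g, 10, mixture = c(full_length = 0.5)),
               "sum to 1")
})

test_that("error-free simulated reads are exact genome substrings", {
  g <- fixture_genome()
  sim <- simulate_reads(g, 80, seed = 9L, error_rate = 0, sequences = TRUE)
  for (i in seq_len(nrow(sim$reads))) {
    r <- sim$reads[i, ]
    expected <- genome_seq(g, r$ref_start, r$ref_end)
    if (r$strand == "-") expected <- revcomp(expected)
    expect_identical(r$seq, expected)
  }
})

test_that("class counts follow the configured multinomial mixture", {
  g <- fixture_genome()
  mix <- default_mixture_test()
  for (seed in 1:5) {
    sim <- simulate_reads(g, 20000, mixture = mix, seed = seed,
                          sequences = FALSE)
    obs <- table(factor(sim$truth$true_class, levels = names(mix)))
    p <- suppressWarnings(chisq.test(obs, p = mix)$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("hybrid constructions follow the junction arithmetic", {
  g <- fixture_genome()
  spec <- data.frame(type = "pos_pos", event = "deletion", n = 1L,
                     delta_min = 30L, delta_max = 30L, j1 = 3410L)
  h <- simulate_hybrids(g, spec, seed = 4L)
  tr <- h$truth
  expect_equal(tr$j1, 3410L)
  expect_equal(tr$j2, 3440L)
  # read is genome[a:j1) + genome[j2:b)
  expect_identical(
    h$reads$seq,
    paste0(genome_seq(g, tr$a, tr$j1), genome_seq(g, tr$j2, tr$b)))

  fb <- simulate_hybrids(g, data.frame(type = "foldback", n = 1L,
                                       delta_min = NA, delta_max = NA),
                         seed = 5L)
  expect_equal(fb$truth$type, "foldback")
  expect_identical(
    fb$reads$seq,
    paste0(genome_seq(g, fb$truth$a, fb$truth$b),
           revcomp(genome_seq(g, fb$truth$b - fb$truth$arm, fb$truth$b))))

  expect_error(
    simulate_hybrids(g, data.frame(type = "pos_pos", event = "deletion",
                                   n = 1L, delta_min = 0L, delta_max = 0L)),
    "not a hybrid")
})

test_that("modification calls reproduce the configured stoichiometry", {
  g <- fixture_genome()
  cpos <- which(strsplit(g$sequence, "")[[1]] == "C")
  site <- cpos[200] - 1L # 0-based
  reads <- tibble::tibble(
    read_id = sprintf("r%04d", 1:1000), strand = "+",
    ref_start = pmax(0L, site - 200L), ref_end = site + 200L,
    timepoint = "0h"
  )
  # stoichiometry 1: every record called modified
  mc1 <- simulate_modifications(
    g, data.frame(ref_pos = site, mod_type = "m5C", stoichiometry = 1),
    reads, seed = 2L)
  expect_true(all(mc1$probability >= 0.85))

  # IVT sample with no artifact sites: nothing above the threshold
  mci <- simulate_modifications(
    g, data.frame(ref_pos = site, mod_type = "m5C", stoichiometry = 0.9),
    reads, ivt = TRUE, seed = 3L)
  expect_true(all(mci$probability < 0.30))
  expect_equal(unique(mci$sample), "ivt")

  # stoichiometry 0.8 at depth 1000: independent Bernoulli recount of the
  # emitted table matches the configured rate within binomial noise
  mc8 <- simulate_modifications(
    g, data.frame(ref_pos = site, mod_type = "m5C", stoichiometry = 0.8),
    reads, seed = 4L)
  expect_equal(nrow(mc8), 1000L)
  recount <- sum(mc8$probability >= 0.85) / nrow(mc8)
  expect_lt(abs(recount - 0.8), 4 * sqrt(0.8 * 0.2 / 1000))

  # base-incompatible site is an error
  apos <- which(strsplit(g$sequence, "")[[1]] == "A")[50] - 1L
  expect_error(
    simulate_modifications(
      g, data.frame(ref_pos = apos, mod_type = "m5C", stoichiometry = 0.5),
      reads, seed = 5L),
    "incompatible")
})
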