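uniform_reads <- function(n, L = 3569L, span = 300L, seed = 1L,
                          strand = "+") {
  set.seed(seed)
  st <- sample.int(L - span, n, replace = TRUE) - 1L
  tibble::tibble(
    read_id = sprintf("u%05d", seq_len(n)), strand = strand,
    ref_start = st, ref_end = st + span, query_length = span,
    mean_phred = 14, timepoint = "3h", sample = "test", is_primary = TRUE
  )
}

test_that("window statistics count starts, ends and depth correctly", {
  g <- fixture_genome()
  # 10 reads all starting at window boundary 1000: depth across [1000,1005)
  # is 10, all starts in that window
  r <- tibble::tibble(
    read_id = sprintf("r%d", 1:10), strand = "+",
    ref_start = 1000L, ref_end = 1500L, query_length = 500L,
    mean_phred = 14, timepoint = "0h", sample = "t", is_primary = TRUE
  )
  ws <- window_site_stats(r, g, min_depth = 5)
  w <- ws[ws$window_start == 1000 & ws$strand == "+", ]
  expect_equal(w$depth, 10)
  expect_equal(w$start_count, 10L)
  expect_equal(w$start_ratio, 1.0)
  # the matching end window
  we <- ws[ws$window_start == 1495 & ws$strand == "+", ]
  expect_equal(we$end_count, 10L)

  # start/end counts over all windows equal the read count
  expect_equal(sum(ws$start_count), 10L)
  expect_equal(sum(ws$end_count), 10L)

  # negative-strand biological orientation: start is the genome-max end
  rn <- r; rn$strand <- "-"
  wsn <- window_site_stats(rn, g, min_depth = 5)
  wn <- wsn[wsn$window_start == 1495 & wsn$strand == "-", ]
  expect_equal(wn$start_count, 10L) # biological 5' at ref_end - 1 = 1499
  wn0 <- wsn[wsn$window_start == 1000 & wsn$strand == "-", ]
  expect_equal(wn0$end_count, 10L)

  # empty input: everything flagged missing
  ws0 <- window_site_stats(r[0, ], g)
  expect_true(all(!ws0$ok_depth))
  expect_true(all(is.na(ws0$start_ratio)))
})

test_that("hotspot calls respect threshold, ranges and depth gating", {
  g <- fixture_genome()
  set.seed(41)
  n <- 10000L
  planted <- rbinom(1, n, 0.15)
  st <- c(sample(1500:1504, planted, replace = TRUE),
          sample.int(3569L - 301L, n - planted, replace = TRUE) - 1L)
  r <- uniform_reads(0)[0, ]
  r <- tibble::tibble(
    read_id = sprintf("p%05d", seq_len(n)), strand = "+",
    ref_start = as.integer(st), ref_end = as.integer(pmin(st + 300L, 3569L)),
    query_length = 300L, mean_phred = 14, timepoint = "3h", sample = "t",
    is_primary = TRUE
  )
  ws <- window_site_stats(r, g)
  hs <- call_hotspots(ws)
  hit <- hs[hs$site == "start" & hs$window_start == 1500, ]
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$fold, 5)
  # output sorted by fold descending
  expect_true(all(diff(hs$fold) <= 0))

  # a window outside the start reporting range is never a start call
  st2 <- c(rep(40L, 1500L), st)
  r2 <- tibble::tibble(
    read_id = sprintf("q%05d", seq_along(st2)), strand = "+",
    ref_start = as.integer(st2), ref_end = as.integer(pmin(st2 + 300L, 3569L)),
    query_length = 300L, mean_phred = 14, timepoint = "3h", sample = "t",
    is_primary = TRUE
  )
  hs2 <- call_hotspots(window_site_stats(r2, g))
  expect_false(any(hs2$site == "start" & hs2$window_start == 40))

  # infinite threshold: no calls
  expect_equal(nrow(call_hotspots(ws, fold_threshold = Inf)), 0L)
})

test_that("uniform start placement yields zero hotspot calls", {
  g <- fixture_genome()
  for (seed in 1:2) {
    r <- uniform_reads(10000L, seed = seed)
    hs <- call_hotspots(window_site_stats(r, g))
    expect_equal(nrow(hs), 0L)
  }
})

test_that("fold changes are stable under down-sampling", {
  g <- fixture_genome()
  set.seed(51)
  n <- 20000L
  st <- c(sample(1500:1504, 3000L, replace = TRUE),
          sample.int(3569L - 301L, n - 3000L, replace = TRUE) - 1L)
  r <- tibble::tibble(
    read_id = sprintf("d%05d", seq_len(n)), strand = "+",
    ref_start = as.integer(st), ref_end = as.integer(pmin(st + 300L, 3569L)),
    query_length = 300L, mean_phred = 14, timepoint = "3h", sample = "t",
    is_primary = TRUE
  )
  full <- window_site_stats(r, g)
  half <- window_site_stats(r[sample.int(n, n / 2), ], g)
  f1 <- full$start_fold[full$window_start == 1500 & full$strand == "+"]
  f2 <- half$start_fold[half$window_start == 1500 & half$strand == "+"]
  expect_lt(abs(f2 - f1) / f1, 0.10)
})

test_that("codon annotation flags nearby starts and stops", {
  g <- fixture_genome()
  mat <- orf_interval_test(g, "mat")
  hs <- tibble::tibble(
    window_start = c(mat[1] - 3L, mat[1]), pos = c(mat[1] - 2L, mat[1] + 1L),
    strand = "+", site = "start", count = 1L, depth = 100,
    ratio = 0.01, fold = 6
  )
  ann <- annotate_codons(g, hs, flank = 10L)
  expect_true(all(ann$start_codon_nearby))
  expect_true(grepl(sprintf("%d\\(\\+\\)", mat[1] + 1L), ann$start_codons[1]))

  # flank 0: only codons overlapping the window itself
  far <- tibble::tibble(window_start = mat[1] - 40L, pos = mat[1] - 39L,
                        strand = "+", site = "start", count = 1L,
                        depth = 100, ratio = 0.01, fold = 6)
  ann0 <- annotate_codons(g, far, flank = 0L)
  has_atg <- grepl("ATG", genome_seq(g, mat[1] - 40L, mat[1] - 33L))
  expect_equal(ann0$start_codon_nearby, has_atg)
})

test_that("AG-richness test matches the exact binomial tail", {
  # balanced genome (purine fraction exactly 0.5) with a pure-purine flank
  # upstream of position 2000 and a compensating pyrimidine stretch
  base <- strrep("AGCT", 1000)
  seq <- base
  substr(seq, 1981, 2000) <- strrep("AG", 10)
  substr(seq, 3001, 3020) <- strrep("CT", 10)
  g <- genome_model("balanced", seq,
                    data.frame(name = "o", start = 0L, end = 300L))
  counts <- table(strsplit(g$sequence, "")[[1]])
  expect_equal(as.numeric(counts["A"] + counts["G"]), 2000)

  hw <- tibble::tibble(window_start = 2000L, strand = "+")
  res <- ag_richness_test(g, hw, flank = 20L)
  expect_equal(res$purine_fraction, 1.0)
  expect_equal(res$p_value, 0.5^20, tolerance = 1e-12)

  # background-level flank is not significant
  hw2 <- tibble::tibble(window_start = 1000L, strand = "+")
  res2 <- ag_richness_test(g, hw2, flank = 20L)
  expect_gte(res2$p_value, 0.5)

  # all-purine genome: background 1, p = 1 everywhere
  gp <- genome_model("purine", strrep("AG", 600),
                     data.frame(name = "o", start = 0L, end = 120L))
  resp <- ag_richness_test(gp, tibble::tibble(window_start = 600L,
                                              strand = "+"), flank = 20L)
  expect_equal(resp$p_value, 1.0)
})
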