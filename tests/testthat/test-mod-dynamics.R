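mk_calls <- function(probs, ref_pos = 100L, mod_type = "psi",
                     sample = "test", timepoint = "0h") {
  tibble::tibble(
    read_id = sprintf("r%04d", seq_along(probs)), ref_pos = ref_pos,
    mod_type = mod_type, probability = probs, sample = sample,
    timepoint = timepoint
  )
}

test_that("site stoichiometry thresholds call probabilities strictly", {
  calls <- mk_calls(c(rep(0.95, 80), rep(0.1, 20)))
  st <- site_stoichiometry(calls)
  expect_equal(st$stoichiometry, 0.80)
  expect_equal(st$coverage, 100L)
  expect_false(st$low_coverage)

  # strictly greater than the threshold
  st2 <- site_stoichiometry(mk_calls(c(0.8, 0.81)), prob_threshold = 0.8)
  expect_equal(st2$n_modified, 1L)

  low <- site_stoichiometry(mk_calls(rep(0.9, 10)), min_cov = 30)
  expect_true(low$low_coverage)
})

test_that("stoichiometry is monotone non-increasing in the threshold", {
  set.seed(61)
  for (i in 1:20) {
    probs <- runif(50)
    s1 <- site_stoichiometry(mk_calls(probs), prob_threshold = 0.6)
    s2 <- site_stoichiometry(mk_calls(probs), prob_threshold = 0.8)
    s3 <- site_stoichiometry(mk_calls(probs), prob_threshold = 0.9)
    expect_true(s1$stoichiometry >= s2$stoichiometry)
    expect_true(s2$stoichiometry >= s3$stoichiometry)
    expect_true(s1$stoichiometry >= 0 && s1$stoichiometry <= 1)
  }
})

test_that("IVT subtraction keeps strictly positive deltas only", {
  test_sites <- tibble::tibble(
    ref_pos = c(10L, 20L, 30L), mod_type = "m5C", sample = "test",
    timepoint = "0h", coverage = 100L, n_modified = c(50L, 10L, 30L),
    stoichiometry = c(0.5, 0.1, 0.3), low_coverage = FALSE
  )
  ivt_sites <- tibble::tibble(
    ref_pos = c(10L, 20L), mod_type = "m5C", sample = "ivt",
    timepoint = "0h", coverage = 100L, n_modified = c(10L, 10L),
    stoichiometry = c(0.1, 0.1), low_coverage = FALSE
  )
  out <- ivt_subtract(test_sites, ivt_sites)
  expect_setequal(out$ref_pos, c(10L, 30L)) # site 20: 0.1 - 0.1 dropped
  expect_equal(out$delta[out$ref_pos == 10L], 0.4)
  expect_equal(out$delta[out$ref_pos == 30L], 0.3) # absent from IVT -> 0
})

test_that("Fisher significance matches the exact hypergeometric tail", {
  sig <- site_significance(80L, 100L, 5L, 100L)
  expect_lt(sig$p_value, 1e-15)
  expect_equal(sig$p_value, oracle_fisher2(80L, 20L, 5L, 95L),
               tolerance = 1e-12)

  same <- site_significance(50L, 100L, 50L, 100L)
  expect_equal(same$p_value, 1.0)

  z <- site_significance(c(5L, 0L), c(10L, 0L), c(1L, 5L), c(10L, 10L))
  expect_true(z$skipped[2])
  expect_true(is.na(z$p_value[2]))
})

test_that("BH q-values match the brute-force step-up exactly", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(71)
  # agreement to machine precision (the two implementations associate the
  # multiplications differently, so the last ulp can differ)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-15)
  }
})

test_that("temporal classification labels consecutive-pair dynamics", {
  mk_sites <- function(stoich, tps, cov = 500L, frac = "gt3000") {
    tibble::tibble(
      ref_pos = 924L, mod_type = "psi", sample = "test", timepoint = tps,
      length_fraction = frac, coverage = cov,
      n_modified = as.integer(round(stoich * cov)),
      stoichiometry = stoich, low_coverage = FALSE
    )
  }
  tps <- c("0h", "20min", "40min")
  dyn <- temporal_classification(mk_sites(c(0.6, 0.3, 0.6), tps), tps)
  expect_equal(dyn$pair_1, "decrease")
  expect_equal(dyn$pair_2, "increase")
  expect_equal(dyn$dynamic_label, "decrease,increase")
  expect_equal(dyn$preset, "blue")

  flat <- temporal_classification(mk_sites(c(0.5, 0.5, 0.5), tps), tps)
  expect_equal(flat$dynamic_label, "no_difference,no_difference")
  expect_true(is.na(flat$preset))

  purple <- temporal_classification(mk_sites(c(0.6, 0.3, 0.3), tps), tps)
  expect_equal(purple$preset, "purple")

  # short-fraction presets use the final pair
  cy <- temporal_classification(mk_sites(c(0.1, 0.1, 0.5), tps,
                                         frac = "lt800"), tps)
  expect_equal(cy$preset, "cyan")

  single <- temporal_classification(mk_sites(0.5, "0h"), "0h")
  expect_equal(single$dynamic_label, "static_insufficient")
})

test_that("site context returns the centred 5-mer", {
  g <- fixture_genome()
  ctx <- site_context(g, 923L) # 1-based 924
  expect_equal(nchar(ctx), 5L)
  expect_equal(substr(ctx, 3, 3), genome_seq(g, 923L, 924L))
})
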