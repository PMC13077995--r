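# Per-site modification stoichiometry, IVT background subtraction,
# Fisher/BH significance and temporal dynamic labels.
#
# Stoichiometry at a site = fraction of covering reads whose modification
# call probability exceeds the threshold (> 80% by default). Direct RNA
# modification calling has a high systematic false-positive rate; an
# unmodified in-vitro-transcribed (IVT) control is subtracted and only sites
# with stoichiometry(test) - stoichiometry(IVT) > 0 are retained.

#' Per-site per-sample stoichiometry from per-read calls
#'
#' @param mod_calls ModCallRecord tibble: `read_id`, `ref_pos` (0-based),
#'   `mod_type`, `probability`, `sample`, `timepoint`, and optionally
#'   `length_fraction` (kept as a stratification key when present).
#' @param prob_threshold a read counts as modified when its call probability
#'   is strictly greater than this (default 0.8).
#' @param min_cov sites with coverage below this are flagged `low_coverage`
#'   and excluded from significance testing.
#' @return tibble keyed by (`ref_pos`, `mod_type`, `sample`, `timepoint`
#'   [, `length_fraction`]) with `coverage`, `n_modified`, `stoichiometry`,
#'   `low_coverage`.
#' @export
site_stoichiometry <- function(mod_calls, prob_threshold = 0.8, min_cov = 30L) {
  keys <- intersect(c("ref_pos", "mod_type", "sample", "timepoint",
                      "length_fraction"), names(mod_calls))
  grp <- dplyr::group_by(mod_calls, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    grp,
    coverage = dplyr::n(),
    n_modified = sum(probability > prob_threshold),
    .groups = "drop"
  )
  out$stoichiometry <- out$n_modified / out$coverage
  out$low_coverage <- out$coverage < min_cov
  out
}

#' Subtract the IVT background and keep positive-delta sites
#'
#' Sites are matched on (`ref_pos`, `mod_type` [, `length_fraction`,
#' `timepoint`]); a test site absent from the IVT table gets
#' `ivt_stoichiometry = 0`. Only sites with `delta > 0` (strictly) are
#' retained.
#'
#' @param test_sites,ivt_sites outputs of [site_stoichiometry()].
#' @param match_timepoint if FALSE (default) the IVT stoichiometry per site
#'   is its maximum over IVT samples/timepoints — one IVT library serves all
#'   timepoints; if TRUE sites are matched per timepoint.
#' @return retained test sites with `ivt_stoichiometry` and `delta` columns.
#' @export
ivt_subtract <- function(test_sites, ivt_sites, match_timepoint = FALSE) {
  keys <- intersect(c("ref_pos", "mod_type", "length_fraction",
                      if (match_timepoint) "timepoint"),
                    intersect(names(test_sites), names(ivt_sites)))
  ivt <- dplyr::group_by(ivt_sites, dplyr::across(dplyr::all_of(keys)))
  ivt <- dplyr::summarise(ivt, ivt_stoichiometry = max(stoichiometry),
                          .groups = "drop")
  out <- dplyr::left_join(test_sites, ivt, by = keys)
  out$ivt_stoichiometry[is.na(out$ivt_stoichiometry)] <- 0
  out$delta <- out$stoichiometry - out$ivt_stoichiometry
  out[out$delta > 0, ]
}

#' Two-sided Fisher exact test per site with BH correction
#'
#' Compares modified/unmodified counts between two samples (test vs IVT, or
#' a pair of timepoints) site by site; BH is applied across all tested sites
#' within the comparison family.
#'
#' @param n_mod_1,cov_1 modified count and coverage in sample 1 (vectors).
#' @param n_mod_2,cov_2 same for sample 2.
#' @return tibble with `p_value`, `q_value`, `skipped` (TRUE where a sample
#'   had zero coverage — no test performed).
#' @export
site_significance <- function(n_mod_1, cov_1, n_mod_2, cov_2) {
  n <- length(n_mod_1)
  stopifnot(length(cov_1) == n, length(n_mod_2) == n, length(cov_2) == n)
  p <- rep(NA_real_, n)
  skipped <- cov_1 == 0 | cov_2 == 0 | is.na(cov_1) | is.na(cov_2)
  for (i in which(!skipped)) {
    tab <- matrix(c(n_mod_1[i], cov_1[i] - n_mod_1[i],
                    n_mod_2[i], cov_2[i] - n_mod_2[i]), nrow = 2)
    p[i] <- fisher.test(tab)$p.value
  }
  tibble(p_value = p, q_value = p.adjust(p, method = "BH"), skipped = skipped)
}

#' Label temporal stoichiometry dynamics per site
#'
#' For each consecutive ordered timepoint pair, a site is labelled
#' `increase`/`decrease` when the Fisher/BH q-value is below `alpha` (BH
#' within one family per timepoint pair x mod_type [x length fraction]) with
#' the corresponding sign of the stoichiometry change, else `no_difference`.
#' The ordered tuple is joined with "," into `dynamic_label`, and the named
#' presets are flagged: over (0h vs 20min, 20min vs 40min) blue =
#' decrease,increase; purple = decrease,no_difference; brown =
#' increase,no_difference (long-read fraction); cyan/red = final-pair
#' increase / no_difference (short-read fraction).
#'
#' @param sites [site_stoichiometry()] output for one sample across
#'   timepoints (one row per site per timepoint).
#' @param timepoints ordered timepoint labels.
#' @param alpha significance level on q (default 0.05).
#' @param min_cov required coverage in every compared timepoint.
#' @return tibble per site: key columns, per-pair labels (`pair_i`),
#'   `dynamic_label`, `preset`.
#' @export
temporal_classification <- function(sites, timepoints, alpha = 0.05,
                                    min_cov = 30L) {
  keys <- intersect(c("ref_pos", "mod_type", "length_fraction"), names(sites))
  sites <- sites[sites$timepoint %in% timepoints, ]
  wide_key <- do.call(paste, c(sites[keys], sep = "\r"))
  usites <- sites[!duplicated(wide_key), keys, drop = FALSE]
  ukey <- do.call(paste, c(usites[keys], sep = "\r"))
  npair <- length(timepoints) - 1L
  if (npair < 1L) {
    usites$dynamic_label <- "static_insufficient"
    usites$preset <- NA_character_
    return(as_tibble(usites))
  }
  labels <- matrix(NA_character_, nrow(usites), npair)
  for (k in seq_len(npair)) {
    t1 <- timepoints[k]; t2 <- timepoints[k + 1L]
    s1 <- sites[sites$timepoint == t1, ]
    s2 <- sites[sites$timepoint == t2, ]
    i1 <- match(ukey, do.call(paste, c(s1[keys], sep = "\r")))
    i2 <- match(ukey, do.call(paste, c(s2[keys], sep = "\r")))
    cov1 <- s1$coverage[i1]; cov2 <- s2$coverage[i2]
    m1 <- s1$n_modified[i1]; m2 <- s2$n_modified[i2]
    ok <- !is.na(cov1) & !is.na(cov2) & cov1 >= min_cov & cov2 >= min_cov
    # one BH family per timepoint pair (x mod_type handled by testing all
    # sites of the stratum together; families separated by mod_type)
    lab <- rep(NA_character_, nrow(usites))
    for (mt in unique(usites$mod_type)) {
      fam <- ok & usites$mod_type == mt
      if (!any(fam)) next
      sig <- site_significance(m1[fam], cov1[fam], m2[fam], cov2[fam])
      d <- (m2[fam] / cov2[fam]) - (m1[fam] / cov1[fam])
      l <- ifelse(!is.na(sig$q_value) & sig$q_value < alpha,
                  ifelse(d > 0, "increase", "decrease"), "no_difference")
      lab[fam] <- l
    }
    lab[!ok] <- "insufficient_coverage"
    labels[, k] <- lab
  }
  usites <- as_tibble(usites)
  for (k in seq_len(npair)) usites[[paste0("pair_", k)]] <- labels[, k]
  usites$dynamic_label <- apply(labels, 1, paste, collapse = ",")
  usites$preset <- preset_flag(labels, usites, npair)
  usites
}

# named Fig-style preset patterns; long fraction uses the first two pairs,
# short fraction the final pair
preset_flag <- function(labels, usites, npair) {
  n <- nrow(usites)
  preset <- rep(NA_character_, n)
  frac <- if ("length_fraction" %in% names(usites)) usites$length_fraction
          else rep("gt3000", n)
  if (npair >= 2L) {
    long <- frac == "gt3000"
    p12 <- paste(labels[, 1], labels[, 2], sep = ",")
    preset[long & p12 == "decrease,increase"] <- "blue"
    preset[long & p12 == "decrease,no_difference"] <- "purple"
    preset[long & p12 == "increase,no_difference"] <- "brown"
  }
  last <- labels[, npair]
  short <- frac == "lt800"
  preset[short & last == "increase"] <- "cyan"
  preset[short & last == "no_difference"] <- "red"
  preset
}

#' Sequence context around a site (5-mer by default)
#' @param genome a [genome_model()].
#' @param ref_pos 0-based site positions.
#' @param k context width (odd; default 5).
#' @return character vector of contexts (site centred).
#' @export
site_context <- function(genome, ref_pos, k = 5L) {
  h <- k %/% 2L
  lo <- pmax(0L, ref_pos - h)
  hi <- pmin(genome$length, ref_pos + h + 1L)
  substring(genome$sequence, lo + 1L, hi)
}
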