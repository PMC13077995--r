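# Read length fractionation and class decomposition.
#
# Short positive-strand reads decompose into three blocks: 3'-anchored reads
# (DRS 3'-end bias: sequencing starts from the transcript 3' end, so
# incomplete reads keep the 3' terminus), 5'-anchored reads (degraded RNA),
# and internal subgenomic reads containing the coat (or coat+lys) ORFs.

#' Label reads by length fraction
#'
#' @param reads aligned-read tibble.
#' @param bounds strictly increasing pair of span bounds; default
#'   `c(800, 3000)` gives the fractions lt800 (< 800 nt), mid, gt3000
#'   (> 3000 nt). Span is the reference extent `ref_end - ref_start`.
#' @return `reads` with a `length_fraction` column.
#' @export
fraction_by_length <- function(reads, bounds = c(800L, 3000L)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  span <- reads$ref_end - reads$ref_start
  reads$length_fraction <- ifelse(span < bounds[1], "lt800",
                           ifelse(span > bounds[2], "gt3000", "mid"))
  reads
}

#' Classify reads into the block/subgenomic vocabulary
#'
#' Precedence order (first match wins):
#' 1. `full_length` — span >= 0.90 * L;
#' 2. `three_prime_anchored` — read keeps the transcript 3' terminus and
#'    lost the 5' end (DRS bias block);
#' 3. `five_prime_anchored` — read keeps the 5' terminus (degradation block);
#' 4. `coat_lys_subgenomic` — covers >= 90% of both coat and lys ORFs;
#' 5. `coat_subgenomic` — covers >= 90% of the coat ORF;
#' 6. `other_internal`.
#'
#' For negative-strand reads the anchoring tests swap genome ends: the
#' biological 3' end of a "-" read is genome position 0.
#'
#' @param reads aligned-read tibble.
#' @param genome a [genome_model()].
#' @param delta anchoring tolerance in nt (default 25): a terminus within
#'   `delta` of the genome end counts as anchored.
#' @param cover_frac ORF coverage fraction for the subgenomic classes.
#' @return `reads` with a `read_class` column.
#' @export
classify_reads <- function(reads, genome, delta = 25L, cover_frac = 0.9) {
  L <- genome$length
  st <- reads$ref_start; en <- reads$ref_end
  span <- en - st
  neg <- reads$strand == "-"

  # genome-frame anchoring conditions
  at_hi <- en >= L - delta # touches genome end
  at_lo <- st <= delta # touches genome start
  # biological 3'-anchoring: '+' reads at the high end, '-' reads at the low end
  three_anch <- ifelse(neg, at_lo & !at_hi, at_hi & !at_lo)
  five_anch <- ifelse(neg, at_hi & !at_lo, at_lo & !at_hi)

  cov_ge <- function(orf) {
    ov <- pmax(0L, pmin(en, orf[2]) - pmax(st, orf[1]))
    ov >= cover_frac * (orf[2] - orf[1])
  }
  coat <- orf_interval(genome, "coat", 2L)
  lys <- orf_interval(genome, "lys", 3L)
  coat_cov <- cov_ge(coat)
  lys_cov <- cov_ge(lys)

  cls <- rep("other_internal", nrow(reads))
  cls[coat_cov] <- "coat_subgenomic"
  cls[coat_cov & lys_cov] <- "coat_lys_subgenomic"
  cls[five_anch] <- "five_prime_anchored"
  cls[three_anch] <- "three_prime_anchored"
  cls[span >= 0.90 * L] <- "full_length"
  reads$read_class <- cls
  reads
}

#' Classify a single read (scalar convenience wrapper)
#' @param read one-row aligned-read tibble (or list with strand, ref_start,
#'   ref_end).
#' @inheritParams classify_reads
#' @return class label.
#' @export
classify_read <- function(read, genome, delta = 25L, cover_frac = 0.9) {
  r <- as_tibble(read[c("strand", "ref_start", "ref_end")])
  classify_reads(r, genome, delta = delta, cover_frac = cover_frac)$read_class
}

#' Per-group class counts and proportions
#'
#' @param classified reads with a `read_class` column.
#' @param group_by grouping columns (default timepoint and strand).
#' @return tibble with one row per group x class: `n`, `proportion`
#'   (proportions sum to 1 within each group).
#' @export
class_proportions <- function(classified, group_by = c("timepoint", "strand")) {
  group_by <- intersect(group_by, names(classified))
  tab <- dplyr::count(classified,
                      dplyr::across(dplyr::all_of(c(group_by, "read_class"))),
                      name = "n")
  grp <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(group_by)))
  out <- dplyr::mutate(grp, proportion = n / sum(n))
  dplyr::ungroup(out)
}

#' Count reads containing each ORF
#'
#' A read counts toward an ORF when its overlap covers at least
#' `cover_frac` of the ORF; a read may count toward several ORFs (a
#' full-length read counts toward all four). Proportions are relative to the
#' total mapped viral reads in the group.
#'
#' @param reads aligned-read tibble.
#' @param genome a [genome_model()] (source of the ORF table).
#' @param cover_frac required ORF coverage fraction in (0, 1].
#' @param group_by grouping columns.
#' @return tibble with group columns, `orf`, `n_reads`, `n_total`,
#'   `proportion`.
#' @export
count_orf_containment <- function(reads, genome, cover_frac = 0.9,
                                  group_by = "timepoint") {
  stopifnot(cover_frac > 0, cover_frac <= 1)
  group_by <- intersect(group_by, names(reads))
  orfs <- genome$orfs
  res <- list()
  key <- if (length(group_by)) {
    interaction(reads[group_by], drop = TRUE, lex.order = TRUE)
  } else factor(rep("all", nrow(reads)))
  for (g in levels(key)) {
    sub <- reads[key == g, ]
    for (k in seq_len(nrow(orfs))) {
      o <- c(orfs$start[k], orfs$end[k])
      ov <- pmax(0L, pmin(sub$ref_end, o[2]) - pmax(sub$ref_start, o[1]))
      n_in <- sum(ov >= cover_frac * (o[2] - o[1]))
      row <- tibble(orf = orfs$name[k], n_reads = n_in,
                    n_total = nrow(sub),
                    proportion = if (nrow(sub)) n_in / nrow(sub) else NA_real_)
      if (length(group_by)) {
        gvals <- sub[1, group_by, drop = FALSE]
        row <- dplyr::bind_cols(gvals, row)
      }
      res[[length(res) + 1L]] <- row
    }
  }
  bind_rows(res)
}
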