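# 5-bp-window read start/end statistics, hotspot calls, codon overlay and
# AG-richness testing.
#
# For each non-overlapping window the statistic is the count of reads whose
# biological 5' (start) or 3' (end) terminus falls in the window, relative
# to the window's mean per-base depth, expressed as a fold change over the
# genome-wide median of that ratio. Negative-strand reads use biological
# orientation: their 5' terminus is the genome-maximum coordinate.

#' Per-window start/end coverage statistics
#'
#' @param reads aligned-read tibble (primary alignments).
#' @param genome a [genome_model()].
#' @param window window size in nt (default 5).
#' @param min_depth windows with mean depth below this are flagged missing
#'   (ratios/folds NA) and never contribute to the baseline.
#' @return tibble with one row per window per strand: `window_start`
#'   (0-based, multiple of `window`), `strand`, `depth`, `start_count`,
#'   `end_count`, `start_ratio`, `end_ratio`, `start_fold`, `end_fold`,
#'   `ok_depth`.
#' @export
window_site_stats <- function(reads, genome, window = 5L, min_depth = 50) {
  stopifnot(window >= 1L)
  L <- genome$length
  wstarts <- seq.int(0L, L - 1L, by = window)
  nw <- length(wstarts)
  out <- list()
  for (sd in c("+", "-")) {
    sub <- reads[reads$strand == sd, ]
    if (nrow(sub) > 0L) {
      covr <- IRanges::coverage(
        IRanges::IRanges(start = sub$ref_start + 1L, end = sub$ref_end),
        width = L
      )
      cov_vec <- as.numeric(covr)
      # mean depth per window (last window may be short)
      idx <- findInterval(seq_len(L) - 1L, wstarts)
      depth <- as.numeric(tapply(cov_vec, idx, mean))
      # biological termini
      start_pos <- ifelse(sub$strand == "-", sub$ref_end - 1L, sub$ref_start)
      end_pos <- ifelse(sub$strand == "-", sub$ref_start, sub$ref_end - 1L)
      start_count <- tabulate(start_pos %/% window + 1L, nbins = nw)
      end_count <- tabulate(end_pos %/% window + 1L, nbins = nw)
    } else {
      depth <- rep(0, nw)
      start_count <- end_count <- rep(0L, nw)
    }
    ok <- depth >= min_depth
    start_ratio <- ifelse(ok, start_count / depth, NA_real_)
    end_ratio <- ifelse(ok, end_count / depth, NA_real_)
    # baseline = genome-wide median ratio over qualifying windows; when that
    # median is zero (terminus-free interior), fall back to the median of the
    # positive ratios so folds stay finite and comparable
    baseline <- function(ratio) {
      b <- median(ratio[ok], na.rm = TRUE)
      if (is.finite(b) && b > 0) return(b)
      b <- median(ratio[ok & ratio > 0], na.rm = TRUE)
      if (is.finite(b) && b > 0) b else NA_real_
    }
    base_s <- baseline(start_ratio)
    base_e <- baseline(end_ratio)
    out[[sd]] <- tibble(
      window_start = wstarts, strand = sd, depth = depth,
      start_count = as.integer(start_count), end_count = as.integer(end_count),
      start_ratio = start_ratio, end_ratio = end_ratio,
      start_fold = start_ratio / base_s, end_fold = end_ratio / base_e,
      ok_depth = ok
    )
  }
  bind_rows(out)
}

#' Call start/end hotspots from window statistics
#'
#' A window is a start-hotspot when its start fold change is at least
#' `fold_threshold`, its depth passes `min_depth` (already encoded in
#' `ok_depth`), and its position lies within `start_range` (1-based genome
#' positions, matching the reporting ranges 100-3500 for starts and 0-3400
#' for ends); end-hotspots analogously. Output is sorted by fold, descending.
#'
#' @param window_stats output of [window_site_stats()].
#' @param fold_threshold minimum fold enrichment (default 5; 2 matches the
#'   looser coat-region enrichment convention).
#' @param start_range,end_range 1-based position ranges eligible for calls.
#' @return tibble: `window_start` (0-based), `pos` (1-based report
#'   coordinate), `strand`, `site` ("start"/"end"), `count`, `depth`,
#'   `ratio`, `fold`.
#' @export
call_hotspots <- function(window_stats, fold_threshold = 5,
                          start_range = c(100L, 3500L),
                          end_range = c(0L, 3400L)) {
  stopifnot(fold_threshold > 1)
  pick <- function(site, rng) {
    fold <- window_stats[[paste0(site, "_fold")]]
    pos1 <- window_stats$window_start + 1L
    sel <- !is.na(fold) & fold >= fold_threshold & window_stats$ok_depth &
      pos1 >= rng[1] & pos1 <= rng[2]
    if (!any(sel)) return(NULL)
    cnt <- window_stats[[paste0(site, "_count")]][sel]
    rat <- window_stats[[paste0(site, "_ratio")]][sel]
    tibble(
      window_start = window_stats$window_start[sel],
      pos = pos1[sel],
      strand = window_stats$strand[sel],
      site = site,
      count = cnt,
      depth = window_stats$depth[sel],
      ratio = rat,
      fold = fold[sel]
    )
  }
  empty <- tibble(window_start = integer(), pos = integer(),
                  strand = character(), site = character(),
                  count = integer(), depth = numeric(), ratio = numeric(),
                  fold = numeric())
  res <- bind_rows(empty, pick("start", start_range), pick("end", end_range))
  if (nrow(res) == 0L) return(res)
  res[order(-res$fold), ]
}

#' Annotate hotspots with nearby start/stop codons
#'
#' Lists ATG and stop-codon (TAA/TAG/TGA) occurrences on both strands within
#' `flank` nt of each hotspot window. Purely annotational (motif search
#' overlay).
#'
#' @param genome a [genome_model()].
#' @param hotspots output of [call_hotspots()].
#' @param flank flank size in nt on each side of the window (default 10).
#' @param window window size used for the stats (default 5).
#' @return `hotspots` with `start_codons` and `stop_codons` columns
#'   (comma-separated 1-based positions with strand, "" when none) and
#'   logical `start_codon_nearby` / `stop_codon_nearby`.
#' @export
annotate_codons <- function(genome, hotspots, flank = 10L, window = 5L) {
  if (nrow(hotspots) == 0L) {
    hotspots$start_codons <- character(0)
    hotspots$stop_codons <- character(0)
    hotspots$start_codon_nearby <- logical(0)
    hotspots$stop_codon_nearby <- logical(0)
    return(hotspots)
  }
  g <- Biostrings::DNAString(genome$sequence)
  find_pos <- function(motifs) {
    hits <- list()
    for (m in motifs) {
      fw <- Biostrings::start(Biostrings::matchPattern(m, g))
      rv <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(m)), g))
      if (length(fw)) hits[[length(hits) + 1L]] <-
          data.frame(pos = fw, strand = "+")
      if (length(rv)) hits[[length(hits) + 1L]] <-
          data.frame(pos = rv, strand = "-")
    }
    do.call(rbind, hits)
  }
  atg <- find_pos("ATG")
  stp <- find_pos(c("TAA", "TAG", "TGA"))
  fmt_near <- function(codons, lo, hi) {
    if (is.null(codons)) return("")
    sel <- codons$pos >= lo & codons$pos <= hi
    if (!any(sel)) return("")
    paste(sprintf("%d(%s)", codons$pos[sel], codons$strand[sel]), collapse = ",")
  }
  n <- nrow(hotspots)
  sc <- character(n); pc <- character(n)
  for (i in seq_len(n)) {
    lo <- hotspots$pos[i] - flank
    hi <- hotspots$pos[i] + window - 1L + flank
    sc[i] <- fmt_near(atg, lo, hi)
    pc[i] <- fmt_near(stp, lo, hi)
  }
  hotspots$start_codons <- sc
  hotspots$stop_codons <- pc
  hotspots$start_codon_nearby <- sc != ""
  hotspots$stop_codon_nearby <- pc != ""
  hotspots
}

#' Test AG-richness of the region 5' of each hotspot
#'
#' Computes the purine (A+G) fraction of the `flank` nt immediately 5' of
#' each hotspot window on the requested strand (strand-aware: 5' of a
#' negative-strand hotspot lies at higher genome coordinates, and purines on
#' the negative strand are T/C on the genome frame), then a one-sided exact
#' binomial test against the genome-wide purine fraction of that strand,
#' with Benjamini-Hochberg correction across the tested hotspots.
#'
#' @param genome a [genome_model()].
#' @param hotspot_windows tibble with `window_start` (0-based) and `strand`
#'   columns (e.g. the start-hotspot rows of [call_hotspots()]).
#' @param flank flank length in nt (>= 5).
#' @param window window size (default 5).
#' @return input with `purine_fraction`, `background`, `p_value`, `q_value`,
#'   `flank_truncated` columns.
#' @export
ag_richness_test <- function(genome, hotspot_windows, flank = 20L, window = 5L) {
  stopifnot(flank >= 5L)
  L <- genome$length
  counts <- table(factor(strsplit(genome$sequence, "")[[1]],
                         levels = DNA_BASES))
  bg_plus <- as.numeric((counts["A"] + counts["G"]) / L)
  bg_minus <- as.numeric((counts["T"] + counts["C"]) / L)
  n <- nrow(hotspot_windows)
  pf <- numeric(n); pv <- numeric(n); bg <- numeric(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    ws <- hotspot_windows$window_start[i]
    sd <- hotspot_windows$strand[i]
    if (sd == "+") {
      lo <- max(0L, ws - flank); hi <- ws
      purines <- c("A", "G"); bgi <- bg_plus
    } else {
      lo <- ws + window; hi <- min(L, ws + window + flank)
      purines <- c("T", "C"); bgi <- bg_minus # A/G on the negative strand
    }
    trunc[i] <- (hi - lo) < flank
    fl <- strsplit(substr(genome$sequence, lo + 1L, hi), "")[[1]]
    k <- sum(fl %in% purines); m <- length(fl)
    pf[i] <- if (m) k / m else NA_real_
    pv[i] <- if (m) binom.test(k, m, bgi, alternative = "greater")$p.value
             else NA_real_
    bg[i] <- bgi
  }
  hotspot_windows$purine_fraction <- pf
  hotspot_windows$background <- bg
  hotspot_windows$p_value <- pv
  hotspot_windows$q_value <- p.adjust(pv, method = "BH")
  hotspot_windows$flank_truncated <- trunc
  hotspot_windows
}
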