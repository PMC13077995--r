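# Pipeline orchestration: ingest -> classes -> hotspots -> hybrids -> mods,
# with a machine-readable JSON report. Internal coordinates are 0-based
# half-open; every TSV/BED written here converts positional columns to the
# report convention (TSV 1-based inclusive, BED 0-based half-open).

#' Write a tibble as TSV (deterministic formatting)
#' @param x tibble.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv_out <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

to_1based <- function(x, start_cols, end_cols = character(0)) {
  for (cc in intersect(start_cols, names(x))) x[[cc]] <- x[[cc]] + 1L
  # half-open ends already equal the 1-based inclusive end
  x
}

#' Run the full pipeline from a configuration
#'
#' Stages run in order ingest -> classes -> hotspots -> hybrids -> mods;
#' stages whose inputs are absent from the config are skipped and noted in
#' the report. All outputs are plain TSV/BED/JSON under `outdir`; rerunning
#' with the same config and seed reproduces them byte-identically.
#'
#' @param config list (or path to a JSON file) with entries:
#'   `genome_fasta`, `orf_annotation`; `alignments` — named list
#'   timepoint -> SAM/BAM path; optional `hybrid_reads` — named list
#'   timepoint -> FASTQ/FASTA path for the chimera scan; optional
#'   `mod_calls_test` / `mod_calls_ivt` — ModCallRecord TSV paths
#'   (1-based `ref_pos` column); `timepoints` — ordered labels; `outdir`;
#'   `seed`; optional `params` overriding stage defaults (`min_phred`,
#'   `delta`, `window`, `min_depth`, `fold_threshold`, `min_score`,
#'   `prob_threshold`, `min_cov`, `alpha`, `length_bounds`).
#' @return list report (also written to `outdir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  p <- config$params
  par <- list(
    min_phred = p$min_phred %||% 10, delta = p$delta %||% 25L,
    window = p$window %||% 5L, min_depth = p$min_depth %||% 50,
    fold_threshold = p$fold_threshold %||% 5, min_score = p$min_score %||% 60L,
    prob_threshold = p$prob_threshold %||% 0.8, min_cov = p$min_cov %||% 30L,
    alpha = p$alpha %||% 0.05,
    length_bounds = p$length_bounds %||% c(800L, 3000L)
  )
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  report <- list(seed = seed, params = par, stages = list())
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  # ingest -------------------------------------------------------------
  if (is.null(config$genome_fasta) || is.null(config$orf_annotation)) {
    stop("stage ingest: genome_fasta and orf_annotation are required")
  }
  genome <- load_genome(config$genome_fasta, config$orf_annotation)
  msg("ingest", "genome ", genome$name, " (", genome$length, " nt)")
  if (is.null(config$alignments)) stop("stage ingest: alignments are required")
  reads <- list(); supp <- list()
  for (tp in names(config$alignments)) {
    al <- read_alignments(config$alignments[[tp]], min_phred = par$min_phred,
                          timepoint = tp, sample = "test")
    reads[[tp]] <- al$reads
    supp[[tp]] <- al$supplementary
  }
  reads <- bind_rows(reads)
  msg("ingest", nrow(reads), " primary reads retained")
  report$stages$ingest <- list(
    n_reads = nrow(reads),
    n_supplementary = sum(vapply(supp, nrow, integer(1))),
    n_positive = sum(reads$strand == "+"),
    n_negative = sum(reads$strand == "-")
  )

  # classes ------------------------------------------------------------
  classified <- classify_reads(fraction_by_length(reads, par$length_bounds),
                               genome, delta = par$delta)
  class_sum <- class_proportions(classified)
  orf_counts <- count_orf_containment(classified, genome)
  write_tsv_out(to_1based(classified, "ref_start"),
                file.path(outdir, "read_classes.tsv"))
  write_tsv_out(class_sum, file.path(outdir, "class_summary.tsv"))
  write_tsv_out(orf_counts, file.path(outdir, "orf_counts.tsv"))
  tps <- config$timepoints %||% unique(classified$timepoint)
  if (length(tps) >= 2L) {
    folds <- compare_timepoints(class_sum, orf_counts, tps)
    write_tsv_out(folds, file.path(outdir, "timepoint_folds.tsv"))
  }
  report$stages$classes <- list(
    n_reads = nrow(classified),
    classes = as.list(table(classified$read_class))
  )
  msg("classes", nrow(class_sum), " summary rows")

  # hotspots (per the reporting convention: short-read population) ------
  ws <- window_site_stats(classified, genome, window = par$window,
                          min_depth = par$min_depth)
  hs <- call_hotspots(ws, fold_threshold = par$fold_threshold)
  hs <- annotate_codons(genome, hs, window = par$window)
  hs_start <- hs[hs$site == "start", ]
  if (nrow(hs_start)) {
    ag <- ag_richness_test(genome, hs_start, window = par$window)
    hs <- left_join(hs,
                    ag[, c("window_start", "strand", "site", "purine_fraction",
                           "p_value", "q_value")],
                    by = c("window_start", "strand", "site"))
  } else {
    hs$purine_fraction <- rep(NA_real_, nrow(hs))
    hs$p_value <- rep(NA_real_, nrow(hs))
    hs$q_value <- rep(NA_real_, nrow(hs))
  }
  write_tsv_out(to_1based(ws, "window_start"),
                file.path(outdir, "window_stats.tsv"))
  write_tsv_out(hs[, setdiff(names(hs), "window_start")],
                file.path(outdir, "hotspots_annotated.tsv"))
  bed <- hs
  if (nrow(bed)) {
    bed_lines <- sprintf("%s\t%d\t%d\t%s_%s\t%d\t%s", genome$name,
                         bed$window_start, bed$window_start + par$window,
                         bed$site, bed$pos, round(bed$fold), bed$strand)
  } else bed_lines <- character(0)
  writeLines(bed_lines, file.path(outdir, "hotspots.bed"))
  report$stages$hotspots <- list(n_windows = nrow(ws), n_hotspots = nrow(hs))
  msg("hotspots", nrow(hs), " hotspot windows")

  # hybrids -------------------------------------------------------------
  if (!is.null(config$hybrid_reads)) {
    hreads <- list()
    for (tp in names(config$hybrid_reads)) {
      fq <- read_fastx(config$hybrid_reads[[tp]])
      fq$timepoint <- tp
      fq$sample <- "test"
      hreads[[tp]] <- fq
    }
    hreads <- bind_rows(hreads)
    calls <- detect_hybrids(hreads, genome, min_score = par$min_score)
    hsum <- hybrid_summary(calls, hreads)
    write_tsv_out(to_1based(calls, c("j1_ref", "j2_ref", "ref_start1",
                                     "ref_start2", "q_start2")),
                  file.path(outdir, "hybrid_calls.tsv"))
    write_tsv_out(hsum, file.path(outdir, "hybrid_summary.tsv"))
    report$stages$hybrids <- list(
      n_reads_scanned = nrow(hreads),
      n_hybrid = length(unique(calls$read_id)),
      by_type = as.list(table(calls$junction_type[calls$junction_index == 1]))
    )
    msg("hybrids", length(unique(calls$read_id)), " hybrid reads")
  } else {
    report$stages$hybrids <- list(skipped = TRUE)
    msg("hybrids", "skipped (no hybrid_reads input)")
  }

  # mods ----------------------------------------------------------------
  if (!is.null(config$mod_calls_test)) {
    test_calls <- read_mod_calls(config$mod_calls_test)
    frac_map <- setNames(classified$length_fraction, classified$read_id)
    test_calls$length_fraction <- unname(frac_map[test_calls$read_id])
    test_sites <- site_stoichiometry(test_calls,
                                     prob_threshold = par$prob_threshold,
                                     min_cov = par$min_cov)
    if (!is.null(config$mod_calls_ivt)) {
      # the IVT library is one background for all fractions: no
      # length_fraction column, so subtraction matches on (ref_pos, mod_type)
      ivt_calls <- read_mod_calls(config$mod_calls_ivt)
      ivt_sites <- site_stoichiometry(ivt_calls,
                                      prob_threshold = par$prob_threshold,
                                      min_cov = par$min_cov)
      retained <- ivt_subtract(test_sites, ivt_sites)
    } else {
      retained <- test_sites
      retained$ivt_stoichiometry <- NA_real_
      retained$delta <- NA_real_
    }
    retained$context <- site_context(genome, retained$ref_pos)
    tps <- config$timepoints %||% sort(unique(retained$timepoint))
    dyn <- temporal_classification(retained[!retained$low_coverage, ], tps,
                                   alpha = par$alpha, min_cov = par$min_cov)
    write_tsv_out(to_1based(retained, "ref_pos"),
                  file.path(outdir, "mod_sites.tsv"))
    write_tsv_out(to_1based(dyn, "ref_pos"),
                  file.path(outdir, "mod_dynamics.tsv"))
    report$stages$mods <- list(
      n_sites_retained = length(unique(retained$ref_pos)),
      n_dynamic = sum(!is.na(dyn$preset))
    )
    msg("mods", length(unique(retained$ref_pos)), " sites retained")
  } else {
    report$stages$mods <- list(skipped = TRUE)
    msg("mods", "skipped (no mod_calls_test input)")
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA/FASTQ file into a read tibble
#' @param path FASTA or FASTQ path (plain text).
#' @return tibble with `read_id`, `seq`.
#' @export
read_fastx <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@")) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    s <- Biostrings::readDNAStringSet(path, format = "fasta")
  }
  tibble(read_id = sub("\\s.*$", "", names(s)), seq = as.character(s))
}

#' Read a ModCallRecord TSV (1-based ref_pos on disk)
#' @param path TSV with columns read_id, ref_pos, mod_type, probability,
#'   sample, timepoint.
#' @return tibble with `ref_pos` converted to the internal 0-based frame.
#' @export
read_mod_calls <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  x$ref_pos <- as.integer(x$ref_pos) - 1L
  x
}

#' Write ModCallRecords to TSV (1-based ref_pos on disk)
#' @param calls ModCallRecord tibble (internal 0-based `ref_pos`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mod_calls <- function(calls, path) {
  calls$ref_pos <- calls$ref_pos + 1L
  write_tsv_out(calls, path)
}

#' Fold changes of class and ORF counts across timepoints
#'
#' Ratios are relative to the first timepoint. Alongside the raw ratio a
#' pseudo-count-adjusted ratio `(n + 1) / (n_first + 1)` is reported, finite
#' even when the baseline count is zero (immediately after infection some
#' classes are absent).
#'
#' @param class_summary output of [class_proportions()] (needs `timepoint`,
#'   `read_class`, `n`).
#' @param orf_counts output of [count_orf_containment()] (needs `timepoint`,
#'   `orf`, `n_reads`); optional.
#' @param timepoints ordered timepoint labels.
#' @return tibble: `feature_type` ("class"/"orf"), `feature`, `timepoint`,
#'   `n`, `fold_raw`, `fold_adjusted`. Empty when fewer than 2 timepoints.
#' @export
compare_timepoints <- function(class_summary, orf_counts = NULL, timepoints) {
  if (length(timepoints) < 2L) {
    return(tibble(feature_type = character(), feature = character(),
                  timepoint = character(), n = numeric(),
                  fold_raw = numeric(), fold_adjusted = numeric()))
  }
  pieces <- list()
  add <- function(tab, type, feat_col, n_col) {
    feats <- unique(tab[[feat_col]])
    for (f in feats) {
      sub <- tab[tab[[feat_col]] == f, ]
      n <- vapply(timepoints, function(tp) {
        v <- sub[[n_col]][sub$timepoint == tp]
        if (length(v)) sum(v) else 0
      }, numeric(1))
      n <- unname(n)
      base <- n[1]
      pieces[[length(pieces) + 1L]] <<- tibble(
        feature_type = type, feature = f, timepoint = timepoints, n = n,
        fold_raw = if (base > 0) n / base else rep(NA_real_, length(n)),
        fold_adjusted = (n + 1) / (base + 1)
      )
    }
  }
  add(class_summary, "class", "read_class", "n")
  if (!is.null(orf_counts)) add(orf_counts, "orf", "orf", "n_reads")
  bind_rows(pieces)
}
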