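#!/usr/bin/env Rscript
# Classify the simulated reads per timepoint into length fractions and the
# three-block / subgenomic vocabulary; tabulate proportions and ORF
# containment; compare recovered labels against the generator's truth.

suppressMessages(library(ms2drs))

indir <- "results/sim"
outdir <- "results/classes"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(file.path(indir, "genome.fasta"),
                      file.path(indir, "genome.gff3"))
timepoints <- c("0h", "20min", "40min", "3h", "6h")

classified <- list(); truth <- list()
for (tp in timepoints) {
  al <- read_alignments(file.path(indir, paste0("reads_", tp, ".sam")),
                        min_phred = 10, timepoint = tp, sample = "test")
  classified[[tp]] <- classify_reads(fraction_by_length(al$reads), genome)
  truth[[tp]] <- readr::read_tsv(file.path(indir, paste0("truth_", tp, ".tsv")),
                                 show_col_types = FALSE)
}
classified <- dplyr::bind_rows(classified)
truth <- dplyr::bind_rows(truth)

m <- match(classified$read_id, truth$read_id)
expected <- ifelse(truth$true_class[m] == "negative_full_length",
                   "full_length", truth$true_class[m])
acc <- mean(classified$read_class == expected)
message(sprintf("per-read class recovery vs truth: %.2f%%", 100 * acc))

summary_tbl <- class_proportions(classified)
orf_tbl <- count_orf_containment(classified, genome)
folds <- compare_timepoints(summary_tbl, orf_tbl, timepoints)

write_tsv_out(classified[, c("read_id", "timepoint", "strand",
                             "length_fraction", "read_class")],
              file.path(outdir, "read_classes.tsv"))
write_tsv_out(summary_tbl, file.path(outdir, "class_summary.tsv"))
write_tsv_out(orf_tbl, file.path(outdir, "orf_counts.tsv"))
write_tsv_out(folds, file.path(outdir, "timepoint_folds.tsv"))

coat <- summary_tbl[summary_tbl$read_class == "coat_subgenomic" &
                      summary_tbl$strand == "+", ]
message("coat-subgenomic proportion per timepoint:")
for (i in seq_len(nrow(coat))) {
  message(sprintf("  %-6s %5.2f%%", coat$timepoint[i],
                  100 * coat$proportion[i]))
}
fl <- folds[folds$feature == "full_length", ]
message(sprintf("full-length fold change %s -> %s: %.1f (pseudo-count %.1f)",
                timepoints[1], timepoints[length(timepoints)],
                fl$fold_raw[nrow(fl)], fl$fold_adjusted[nrow(fl)]))
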