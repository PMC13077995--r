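#!/usr/bin/env Rscript
# End-to-end run of the orchestrated pipeline over the simulated inputs
# (equivalent to scripts 02-05 in one call) with a consolidated JSON report.

suppressMessages(library(ms2drs))

indir <- "results/sim"
timepoints <- c("0h", "20min", "40min", "3h", "6h")
config <- list(
  genome_fasta = file.path(indir, "genome.fasta"),
  orf_annotation = file.path(indir, "genome.gff3"),
  alignments = stats::setNames(
    as.list(file.path(indir, paste0("reads_", timepoints, ".sam"))),
    timepoints),
  hybrid_reads = list("6h" = file.path(indir, "hybrid_candidates_6h.fastq")),
  mod_calls_test = file.path(indir, "mod_calls_test.tsv"),
  mod_calls_ivt = file.path(indir, "mod_calls_ivt.tsv"),
  timepoints = timepoints,
  outdir = "results/pipeline",
  seed = 1L
)
report <- run_pipeline(config)
message("stages completed: ", paste(names(report$stages), collapse = ", "))
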