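#!/usr/bin/env Rscript
# Scan the chimera candidate reads for template-switch hybrids and
# foldbacks; type junctions and events; compare against the planted truth.

suppressMessages(library(ms2drs))

indir <- "results/sim"
outdir <- "results/hybrids"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(file.path(indir, "genome.fasta"),
                      file.path(indir, "genome.gff3"))
cand <- read_fastx(file.path(indir, "hybrid_candidates_6h.fastq"))
cand$timepoint <- "6h"; cand$sample <- "test"
truth <- readr::read_tsv(file.path(indir, "truth_hybrids.tsv"),
                         show_col_types = FALSE)

calls <- detect_hybrids(cand, genome, min_score = 60L)
write_tsv_out(calls, file.path(outdir, "hybrid_calls.tsv"))

first <- calls[calls$junction_index == 1L, ]
m <- match(truth$read_id, first$read_id)
message(sprintf("recovered %d / %d planted hybrids", sum(!is.na(m)),
                nrow(truth)))
ok <- !is.na(m)
same_ev <- truth$event[ok] == first$event[m[ok]]
message(sprintf("event typing correct: %d / %d", sum(same_ev), sum(ok)))

# hybrid-to-total ratio against the full 6 h read population
al6 <- read_alignments(file.path(indir, "reads_6h.sam"), min_phred = 10,
                       timepoint = "6h", sample = "test")
pool <- dplyr::bind_rows(
  al6$reads[, c("read_id", "timepoint")],
  cand[, c("read_id", "timepoint")])
hsum <- hybrid_summary(calls, pool)
write_tsv_out(hsum, file.path(outdir, "hybrid_summary.tsv"))
message(sprintf("hybrid/total ratio at 6 h: %.4f (%d / %d)",
                hsum$ratio[1], hsum$n_hybrid[1], hsum$n_total[1]))
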