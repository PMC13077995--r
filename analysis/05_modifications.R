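#!/usr/bin/env Rscript
# Per-site modification stoichiometry with IVT subtraction, significance
# and temporal dynamics, stratified by read-length fraction.

suppressMessages(library(ms2drs))

indir <- "results/sim"
outdir <- "results/mods"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(file.path(indir, "genome.fasta"),
                      file.path(indir, "genome.gff3"))
timepoints <- c("0h", "20min", "40min", "3h", "6h")

reads <- dplyr::bind_rows(lapply(timepoints, function(tp) {
  al <- read_alignments(file.path(indir, paste0("reads_", tp, ".sam")),
                        min_phred = 10, timepoint = tp, sample = "test")
  al$reads
}))
frac <- fraction_by_length(reads)
frac_map <- stats::setNames(frac$length_fraction, frac$read_id)

test_calls <- read_mod_calls(file.path(indir, "mod_calls_test.tsv"))
ivt_calls <- read_mod_calls(file.path(indir, "mod_calls_ivt.tsv"))
test_calls$length_fraction <- unname(frac_map[test_calls$read_id])

test_sites <- site_stoichiometry(test_calls, prob_threshold = 0.8,
                                 min_cov = 30L)
ivt_sites <- site_stoichiometry(ivt_calls, prob_threshold = 0.8,
                                min_cov = 30L)
retained <- ivt_subtract(test_sites, ivt_sites)
retained$context <- site_context(genome, retained$ref_pos)
write_tsv_out(retained, file.path(outdir, "mod_sites.tsv"))

truth_sites <- readr::read_tsv(file.path(indir, "truth_mod_sites.tsv"),
                               show_col_types = FALSE)
message("retained sites (delta > 0) at 1-based positions: ",
        paste(sort(unique(retained$ref_pos + 1L)), collapse = ", "))
message("planted true sites at: ",
        paste(sort(unique(truth_sites$ref_pos + 1L)), collapse = ", "))

dyn <- temporal_classification(
  retained[!retained$low_coverage & retained$length_fraction %in%
             c("gt3000", "lt800"), ],
  timepoints, alpha = 0.05)
write_tsv_out(dyn, file.path(outdir, "mod_dynamics.tsv"))
for (i in seq_len(nrow(dyn))) {
  message(sprintf("site %d (%s, %s): %s%s", dyn$ref_pos[i] + 1L,
                  dyn$mod_type[i], dyn$length_fraction[i],
                  dyn$dynamic_label[i],
                  ifelse(is.na(dyn$preset[i]), "",
                         paste0(" [", dyn$preset[i], "]"))))
}
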