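#!/usr/bin/env Rscript
# Simulate an MS2-like DRS time course: genome, per-timepoint read
# populations, hybrid/foldback candidate reads, and per-read modification
# call tables with an IVT control. Writes everything the downstream stages
# consume under results/sim/.
#
# The mixtures move across the time course the way an infection does:
# at 0 h essentially only full-length genomic RNA; from 40 min a dominant
# short-read population (DRS 3' bias + degradation), growing coat-containing
# subgenomic reads, and negative-strand replication intermediates.

suppressMessages(library(ms2drs))

seed <- 1L
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- make_genome(seed = seed)
write_genome(genome, file.path(outdir, "genome.fasta"),
             file.path(outdir, "genome.gff3"))
message("genome: ", genome$name, " with ORFs ",
        paste(genome$orfs$name, collapse = ", "))

timepoints <- c("0h", "20min", "40min", "3h", "6h")
mixtures <- list(
  "0h" = c(full_length = 0.96, three_prime_anchored = 0.03,
           other_internal = 0.01),
  "20min" = c(full_length = 0.55, three_prime_anchored = 0.25,
              five_prime_anchored = 0.10, coat_subgenomic = 0.03,
              other_internal = 0.05, negative_full_length = 0.02),
  "40min" = c(full_length = 0.25, three_prime_anchored = 0.33,
              five_prime_anchored = 0.15, coat_subgenomic = 0.10,
              coat_lys_subgenomic = 0.02, other_internal = 0.10,
              negative_full_length = 0.05),
  "3h" = c(full_length = 0.22, three_prime_anchored = 0.35,
           five_prime_anchored = 0.16, coat_subgenomic = 0.11,
           coat_lys_subgenomic = 0.02, other_internal = 0.09,
           negative_full_length = 0.05),
  "6h" = c(full_length = 0.20, three_prime_anchored = 0.36,
           five_prime_anchored = 0.17, coat_subgenomic = 0.12,
           coat_lys_subgenomic = 0.02, other_internal = 0.08,
           negative_full_length = 0.05)
)
n_per_tp <- c("0h" = 600L, "20min" = 1500L, "40min" = 4000L,
              "3h" = 4000L, "6h" = 4000L)

all_reads <- list()
for (i in seq_along(timepoints)) {
  tp <- timepoints[i]
  sim <- simulate_reads(genome, n_per_tp[[tp]], mixture = mixtures[[tp]],
                        error_rate = 0.02, seed = seed + i, timepoint = tp,
                        sequences = TRUE)
  write_sam(sim$reads, genome, file.path(outdir, paste0("reads_", tp, ".sam")))
  write_tsv_out(sim$truth, file.path(outdir, paste0("truth_", tp, ".tsv")))
  all_reads[[tp]] <- sim$reads
  message(tp, ": ", nrow(sim$reads), " reads (",
          sum(sim$truth$true_class == "full_length"), " full-length truth)")
}

# hybrid candidates appear once replication is running
hspec <- data.frame(
  type = c("pos_pos", "pos_pos", "neg_neg", "neg_neg", "foldback"),
  event = c("deletion", "duplication", "deletion", "duplication", NA),
  n = c(10L, 6L, 3L, 2L, 1L), delta_min = 20L, delta_max = 60L
)
hyb <- simulate_hybrids(genome, hspec, seed = seed + 50L, error_rate = 0.02,
                        timepoint = "6h")
write_fastq(hyb$reads, file.path(outdir, "hybrid_candidates_6h.fastq"))
write_tsv_out(hyb$truth, file.path(outdir, "truth_hybrids.tsv"))
message("hybrids: ", nrow(hyb$truth), " planted chimeric/foldback reads")

# modification sites: one high-stoichiometry pseudouridine (the 924-like
# conserved site) plus lower m5C sites whose stoichiometry moves in time
chars <- strsplit(genome$sequence, "")[[1]]
tpos <- which(chars == "T") - 1L
cposn <- which(chars == "C") - 1L
psi_site <- tpos[which.min(abs(tpos - 923L))]
mod_sites <- rbind(
  do.call(rbind, lapply(seq_along(timepoints), function(k)
    data.frame(ref_pos = psi_site, mod_type = "psi",
               timepoint = timepoints[k],
               stoichiometry = 0.80))),
  do.call(rbind, lapply(seq_along(timepoints), function(k)
    data.frame(ref_pos = cposn[500], mod_type = "m5C",
               timepoint = timepoints[k],
               stoichiometry = c(0.60, 0.30, 0.60, 0.62, 0.61)[k]))),
  do.call(rbind, lapply(seq_along(timepoints), function(k)
    data.frame(ref_pos = cposn[800], mod_type = "m5C",
               timepoint = timepoints[k],
               stoichiometry = c(0.25, 0.25, 0.26, 0.24, 0.25)[k])))
)
artifacts <- data.frame(ref_pos = cposn[650], mod_type = "m5C",
                        stoichiometry = 0.30)
reads_tbl <- dplyr::bind_rows(all_reads)
write_mod_calls(
  simulate_modifications(genome, mod_sites, reads_tbl,
                         artifact_sites = artifacts, seed = seed + 60L),
  file.path(outdir, "mod_calls_test.tsv"))
write_mod_calls(
  simulate_modifications(genome, mod_sites, reads_tbl, ivt = TRUE,
                         artifact_sites = artifacts, seed = seed + 61L),
  file.path(outdir, "mod_calls_ivt.tsv"))
write_tsv_out(mod_sites, file.path(outdir, "truth_mod_sites.tsv"))
message("modification tables written (incl. one planted artifact site)")
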