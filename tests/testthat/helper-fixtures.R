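# Shared fixtures, built in code.

# one default genome per test session
fixture_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_genome(seed = 1L)
    g
  }
})

# truth classes use negative_full_length for the (-)-strand genomic reads;
# the classifier reports class and strand separately
expected_class <- function(true_class) {
  ifelse(true_class == "negative_full_length", "full_length", true_class)
}

orf_interval_test <- function(g, name) {
  i <- match(name, g$orfs$name)
  c(g$orfs$start[i], g$orfs$end[i])
}

default_mixture_test <- function() {
  c(full_length = 0.30, three_prime_anchored = 0.30,
    five_prime_anchored = 0.20, coat_subgenomic = 0.15,
    other_internal = 0.05)
}

# build a complete on-disk input set for run_pipeline under `dir`
build_pipeline_inputs <- function(dir, seed = 1L, n_per_tp = 400L,
                                  timepoints = c("0h", "40min")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- make_genome(seed = seed)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genome.gff3")
  write_genome(g, fa, gff)

  alignments <- list()
  all_reads <- list()
  for (i in seq_along(timepoints)) {
    tp <- timepoints[i]
    sim <- simulate_reads(g, n_per_tp, seed = seed + i, timepoint = tp,
                          sequences = TRUE)
    sam <- file.path(dir, paste0("reads_", tp, ".sam"))
    write_sam(sim$reads, g, sam)
    alignments[[tp]] <- sam
    all_reads[[tp]] <- sim$reads
  }

  hspec <- data.frame(
    type = c("pos_pos", "neg_neg", "foldback"),
    event = c("deletion", "duplication", NA),
    n = c(6L, 5L, 3L), delta_min = 25L, delta_max = 55L
  )
  hyb <- simulate_hybrids(g, hspec, seed = seed + 50L,
                          timepoint = timepoints[length(timepoints)])
  fq <- file.path(dir, "hybrid_candidates.fastq")
  write_fastq(hyb$reads, fq)

  cg <- which(strsplit(g$sequence, "")[[1]] == "C") - 1L
  tg <- which(strsplit(g$sequence, "")[[1]] == "T") - 1L
  mod_sites <- do.call(rbind, lapply(timepoints, function(tp) {
    data.frame(ref_pos = c(cg[300], tg[500]), mod_type = c("m5C", "psi"),
               timepoint = tp, stoichiometry = c(0.6, 0.4))
  }))
  reads_tbl <- do.call(rbind, all_reads)
  mc_test <- simulate_modifications(g, mod_sites, reads_tbl, seed = seed + 60L)
  mc_ivt <- simulate_modifications(g, mod_sites, reads_tbl, ivt = TRUE,
                                   seed = seed + 61L)
  test_tsv <- file.path(dir, "mod_calls_test.tsv")
  ivt_tsv <- file.path(dir, "mod_calls_ivt.tsv")
  write_mod_calls(mc_test, test_tsv)
  write_mod_calls(mc_ivt, ivt_tsv)

  list(
    genome_fasta = fa, orf_annotation = gff, alignments = alignments,
    hybrid_reads = stats::setNames(list(fq), timepoints[length(timepoints)]),
    mod_calls_test = test_tsv, mod_calls_ivt = ivt_tsv,
    timepoints = timepoints, seed = seed,
    truth_hybrids = hyb$truth, genome = g
  )
}

# minimal hand-written SAM for reader tests
write_test_sam <- function(path, records,
                           header = c("@HD\tVN:1.6",
                                      "@SQ\tSN:synthMS2_L3569\tLN:3569")) {
  writeLines(c(header, records), path)
}

sam_record <- function(qname, flag, pos, seqlen, qual_char = "I",
                       rname = "synthMS2_L3569", cigar = NULL) {
  if (is.null(cigar)) cigar <- paste0(seqlen, "M")
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, cigar,
          strrep("A", seqlen), strrep(qual_char, seqlen))
}
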