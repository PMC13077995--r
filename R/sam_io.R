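# SAM ingestion and the shared read-filtering / strand conventions.
#
# Internal read table ("aligned_reads"): one row per primary alignment with
# read_id, strand, ref_start, ref_end (0-based half-open, genome frame),
# query_length, mean_phred, timepoint, sample, is_primary. Negative-strand
# reads keep genome-frame coordinates plus strand = "-"; their biological
# 5' end is the genome-maximum coordinate.

SAM_FLAG_UNMAPPED <- 4L
SAM_FLAG_REVERSE <- 16L
SAM_FLAG_SECONDARY <- 256L
SAM_FLAG_SUPPLEMENTARY <- 2048L

#' Read alignments from SAM/BAM with the pipeline's QC conventions
#'
#' Drops unmapped and secondary records, drops primary records whose mean
#' base quality is below `min_phred` (the PHRED >= 10 retention rule), keeps
#' supplementary records in a side list for the chimera stage, and assigns
#' strand "-" to reverse-flag records while keeping coordinates in the
#' positive-strand genome frame.
#'
#' @param sam_path SAM or BAM file with a header.
#' @param min_phred minimum read-mean base quality (arithmetic mean of the
#'   per-base PHRED scores) for primary records. Default 10.
#' @param timepoint,sample labels attached to every returned read.
#' @return list with `reads` (tibble of primary alignments) and
#'   `supplementary` (tibble of supplementary records, unfiltered by quality).
#' @export
read_alignments <- function(sam_path, min_phred = 10, timepoint = NA_character_,
                            sample = NA_character_) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    hdr <- readLines(sam_path, n = 1L)
    if (!startsWith(hdr, "@")) stop("SAM file has no header: ", sam_path)
    bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "pos", "cigar", "qwidth", "qual")
  p <- Rsamtools::ScanBamParam(what = what)
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    empty <- empty_reads()
    return(list(reads = empty, supplementary = empty))
  }
  flag <- res$flag
  mapped <- bitwAnd(flag, SAM_FLAG_UNMAPPED) == 0L
  has_cigar <- !is.na(res$cigar)
  if (any(mapped & !has_cigar)) {
    warning(sum(mapped & !has_cigar), " mapped record(s) without CIGAR skipped")
  }
  keepable <- mapped & has_cigar
  secondary <- bitwAnd(flag, SAM_FLAG_SECONDARY) != 0L
  supp <- bitwAnd(flag, SAM_FLAG_SUPPLEMENTARY) != 0L

  ref_start <- res$pos - 1L
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  qints <- methods::as(res$qual, "IntegerList")
  mean_q <- vapply(seq_len(n), function(i) {
    q <- qints[[i]]
    if (length(q) == 0L) return(NA_real_)
    mean(q)
  }, numeric(1))

  tab <- tibble(
    read_id = res$qname,
    strand = ifelse(bitwAnd(flag, SAM_FLAG_REVERSE) != 0L, "-", "+"),
    ref_start = ref_start,
    ref_end = ref_start + ref_width,
    query_length = res$qwidth,
    mean_phred = mean_q,
    timepoint = timepoint,
    sample = sample,
    is_primary = !secondary & !supp
  )
  # records with no stored qualities ("*") are retained: there is nothing to
  # filter on, mirroring upstream QC having already happened
  primary <- tab[keepable & !secondary & !supp &
                   (is.na(tab$mean_phred) | tab$mean_phred >= min_phred), ]
  supplementary <- tab[keepable & supp, ]
  list(reads = primary, supplementary = supplementary)
}

empty_reads <- function() {
  tibble(
    read_id = character(), strand = character(), ref_start = integer(),
    ref_end = integer(), query_length = integer(), mean_phred = numeric(),
    timepoint = character(), sample = character(), is_primary = logical()
  )
}

#' Partition reads by biological strand
#'
#' @param reads aligned-read tibble.
#' @return list with `positive` and `negative` tibbles; exhaustive and
#'   disjoint, so the two row counts sum to the input count.
#' @export
split_strands <- function(reads) {
  list(positive = reads[reads$strand == "+", ],
       negative = reads[reads$strand == "-", ])
}

#' Write aligned reads (with sequences) to SAM
#'
#' Used by the simulator to emit truth placements. Substitution-only reads
#' have CIGAR `<span>M`; negative-strand reads are stored reverse-complemented
#' with flag 16, per SAM convention.
#'
#' @param reads tibble with read_id, strand, ref_start, ref_end and optionally
#'   `seq` and `qual` columns (plain strings; qual as PHRED+33).
#' @param genome a [genome_model()] (for the header and default sequences).
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(reads, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length))
  if (nrow(reads) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  span <- reads$ref_end - reads$ref_start
  seq <- if ("seq" %in% names(reads)) reads$seq else
    substring(genome$sequence, reads$ref_start + 1L, reads$ref_end)
  qual <- if ("qual" %in% names(reads)) reads$qual else strrep("I", nchar(seq))
  # `seq` arrives in biological orientation; SAM stores the forward-reference
  # frame, so reverse-complement (and reverse quals of) negative-strand rows
  neg <- reads$strand == "-"
  if (any(neg)) {
    seq[neg] <- revcomp(seq[neg])
    qual[neg] <- vapply(qual[neg], function(s) {
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  flag <- ifelse(reads$strand == "-", SAM_FLAG_REVERSE, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                   reads$read_id, flag, genome$name, reads$ref_start + 1L,
                   span, seq, qual)
  writeLines(c(header, lines), path)
  invisible(path)
}

phred_to_qual <- function(phred_ints) {
  vapply(phred_ints, function(q) {
    rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
  }, character(1))
}
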