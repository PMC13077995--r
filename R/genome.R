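#' @useDynLib ms2drs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate group_by summarise ungroup n left_join
#'   select filter bind_rows across all_of
#' @importFrom stats median p.adjust fisher.test binom.test rbinom runif
#'   rnorm setNames chisq.test
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of A/C/G/T(/U/N) sequences.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a genome model
#'
#' The genome model is the coordinate frame for every downstream stage: a
#' single positive-sense reference sequence plus ORF annotations. All internal
#' coordinates are 0-based half-open; report/TSV output is 1-based inclusive.
#'
#' @param name reference name.
#' @param sequence nucleotide string (U is normalised to T internally).
#' @param orfs data frame with columns `name`, `start`, `end` (0-based
#'   half-open) and optionally `strand` (always "+": the genome frame).
#' @return an object of class `genome_model` with fields `name`, `sequence`,
#'   `length` and `orfs` (tibble sorted by start).
#' @export
genome_model <- function(name, sequence, orfs) {
  sequence <- toupper(gsub("U", "T", sequence, fixed = TRUE))
  L <- nchar(sequence)
  if (L < 100L) stop("genome sequence must be at least 100 nt")
  orfs <- as_tibble(orfs)
  stopifnot(all(c("name", "start", "end") %in% names(orfs)))
  if (!"strand" %in% names(orfs)) orfs$strand <- "+"
  if (any(orfs$start < 0L | orfs$end > L | orfs$start >= orfs$end)) {
    stop("ORF interval outside sequence [0, ", L, ")")
  }
  if (anyDuplicated(orfs$name)) stop("ORF names must be unique")
  orfs <- orfs[order(orfs$start), c("name", "start", "end", "strand")]
  structure(
    list(name = name, sequence = sequence, length = L, orfs = orfs),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", x$name, ": ", x$length, " nt, ",
      nrow(x$orfs), " ORFs (", paste(x$orfs$name, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Load a genome from FASTA plus ORF annotations
#'
#' @param fasta_path single-record FASTA.
#' @param annotation_path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) with at least
#'   one interval. BED is 0-based half-open; GFF3 1-based inclusive — both are
#'   normalised to the internal 0-based half-open frame.
#' @return a [genome_model()].
#' @export
load_genome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("ambiguous reference: FASTA must contain exactly one record")
  nm <- sub("\\s.*$", "", names(seqs)[1])
  ann <- rtracklayer::import(annotation_path)
  if (length(ann) < 1L) stop("annotation contains no intervals")
  labels <- if (!is.null(ann$Name) && !all(is.na(ann$Name))) {
    as.character(ann$Name)
  } else if (!is.null(ann$name) && !all(is.na(ann$name))) {
    as.character(ann$name)
  } else if (!is.null(ann$ID)) {
    as.character(ann$ID)
  } else {
    paste0("orf", seq_along(ann))
  }
  orfs <- tibble(
    name = labels,
    start = GenomicRanges::start(ann) - 1L, # rtracklayer imports as 1-based
    end = GenomicRanges::end(ann),
    strand = "+"
  )
  genome_model(nm, as.character(seqs[[1]]), orfs)
}

#' Write a genome model to FASTA (+ optional GFF3)
#'
#' @param genome a [genome_model()].
#' @param fasta_path output FASTA path.
#' @param gff_path optional GFF3 path for the ORFs.
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff_path = NULL) {
  s <- Biostrings::DNAStringSet(genome$sequence)
  names(s) <- genome$name
  Biostrings::writeXStringSet(s, fasta_path, width = 70L)
  if (!is.null(gff_path)) {
    lines <- c(
      "##gff-version 3",
      sprintf("%s\tms2drs\tCDS\t%d\t%d\t.\t+\t0\tID=%s;Name=%s",
              genome$name, genome$orfs$start + 1L, genome$orfs$end,
              genome$orfs$name, genome$orfs$name)
    )
    writeLines(lines, gff_path)
  }
  invisible(genome)
}

#' Extract a subsequence of the genome (0-based half-open)
#' @param genome a [genome_model()].
#' @param start,end 0-based half-open coordinates.
#' @return character subsequence.
#' @export
genome_seq <- function(genome, start, end) {
  substr(genome$sequence, start + 1L, end)
}
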