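# Chimeric (template-switch) and foldback read detection.
#
# A hybrid read carries >= 2 local-alignment segments mapping to distinct
# genome loci. Segments come from an affine-gap Smith-Waterman scan of the
# read against the genome and its reverse complement (compiled core,
# .sw_local), recursively applied to unaligned query remainders; alignments
# bridging a junction with one long gap are split at the gap and realigned.
# Junctions are typed pos_pos / neg_neg / neg_pos / pos_neg / foldback and
# same-strand junctions classified as deletion (delta > 0) or duplication
# (delta < 0), with the 20-60 nt recombination window flagged.

#' Find local-alignment segments of a read against the genome
#'
#' Scoring: match +1, mismatch -2, and a gap of length k costs
#' `gap_open + k * gap_ext` (default 4 + 2k). Alignments containing an
#' internal insertion/deletion of at least `indel_split` nt are split at the
#' gap and each side realigned, so template-switch junctions always separate
#' into distinct segments.
#'
#' @param read_seq read sequence (biological orientation, A/C/G/T).
#' @param genome a [genome_model()].
#' @param min_score minimum alignment score for a reported segment.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @param indel_split minimum internal gap length (nt) that splits an
#'   alignment into two segments.
#' @param min_piece smallest query remainder worth aligning.
#' @return tibble of segments sorted by `query_start`: `query_start`,
#'   `query_end` (0-based half-open on the read), `ref_start`, `ref_end`
#'   (genome frame), `strand`, `score`, `n_match`. Zero rows when the read is
#'   shorter than 60 nt or nothing reaches `min_score`.
#' @export
find_segments <- function(read_seq, genome, min_score = 60L, match = 1L,
                          mismatch = -2L, gap_open = 4L, gap_ext = 2L,
                          indel_split = 15L, min_piece = 30L,
                          strand_screen = TRUE) {
  L <- genome$length
  rc_genome <- rc_genome_cached(genome)
  segs <- list()
  if (nchar(read_seq) < 60L) {
    attr_out <- empty_segments()
    attr(attr_out, "note") <- "read shorter than 60 nt: not scanned"
    return(attr_out)
  }
  # k-mer strand screen: a strand is scanned only when at least one sampled
  # read 15-mer occurs on it (an alignable >= 60 nt arm at a few percent
  # substitution error contains a clean sampled 15-mer with overwhelming
  # probability); with screening off both strands are always scanned
  if (strand_screen) {
    hits <- strand_kmer_hits(read_seq, genome)
    scan_plus <- hits["plus"] > 0L
    scan_minus <- hits["minus"] > 0L
    if (!scan_plus && !scan_minus) return(empty_segments())
  } else {
    scan_plus <- scan_minus <- TRUE
  }
  none <- list(score = -1L)

  recurse <- function(qlo, qhi) {
    if (qhi - qlo < min_piece) return(invisible(NULL))
    sub <- substr(read_seq, qlo + 1L, qhi)
    ap <- if (scan_plus)
      .sw_local(sub, genome$sequence, match, mismatch, gap_open, gap_ext)
      else none
    am <- if (scan_minus)
      .sw_local(sub, rc_genome, match, mismatch, gap_open, gap_ext)
      else none
    use_minus <- am$score > ap$score
    a <- if (use_minus) am else ap
    if (a$score < min_score) return(invisible(NULL))

    gaps <- a$gaps
    big <- which(gaps[, "len"] >= indel_split)
    if (length(big) > 0L) {
      # split the query at the first long gap and realign both sides;
      # insertion bases (type 2) are handed to the downstream side
      gq <- gaps[big[1], "q_pos"]
      split_at <- qlo + gq
      if (split_at > qlo && split_at < qhi) {
        recurse(qlo, split_at)
        recurse(split_at, qhi)
        return(invisible(NULL))
      }
    }
    if (use_minus) {
      ref_start <- L - a$r_end
      ref_end <- L - a$r_start
      strand <- "-"
    } else {
      ref_start <- a$r_start
      ref_end <- a$r_end
      strand <- "+"
    }
    segs[[length(segs) + 1L]] <<- tibble(
      query_start = qlo + a$q_start, query_end = qlo + a$q_end,
      ref_start = ref_start, ref_end = ref_end, strand = strand,
      score = a$score, n_match = a$n_match
    )
    recurse(qlo, qlo + a$q_start)
    recurse(qlo + a$q_end, qhi)
    invisible(NULL)
  }
  recurse(0L, nchar(read_seq))
  if (length(segs) == 0L) return(empty_segments())
  out <- bind_rows(segs)
  out[order(out$query_start), ]
}

empty_segments <- function() {
  tibble(query_start = integer(), query_end = integer(), ref_start = integer(),
         ref_end = integer(), strand = character(), score = integer(),
         n_match = integer())
}

# Assign the unaligned query gap between two chained segments to the
# segments themselves: the first s gap bases continue segment 1 forwards,
# the remaining G - s continue segment 2 backwards, with the split point s
# chosen to minimise total mismatches against the genome continuations
# (substitution errors pass through; truly alien gap content refuses
# refinement). Recovers exact junction coordinates that local-alignment end
# trimming obscures, in particular across the ambiguity region of tandem
# duplications.
refine_junction <- function(s1, s2, read_seq, genome, max_gap = 150L,
                            max_mismatch_frac = 0.3) {
  G <- s2$query_start - s1$query_end
  if (G <= 0L || G > max_gap) {
    return(list(s1 = s1[c("query_start", "query_end", "ref_start", "ref_end")],
                s2 = s2[c("query_start", "query_end", "ref_start", "ref_end")]))
  }
  L <- genome$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gap_chars <- strsplit(substr(read_seq, s1$query_end + 1L,
                               s2$query_start), "")[[1]]
  gchar <- function(pos0) { # genome base at 0-based pos, "" out of range
    if (pos0 < 0L || pos0 >= L) return("")
    substr(genome$sequence, pos0 + 1L, pos0 + 1L)
  }
  # continuation of segment 1 under gap offset t = 0..G-1
  fwd1 <- vapply(seq_len(G) - 1L, function(t) {
    if (s1$strand == "+") gchar(s1$ref_end + t)
    else { b <- gchar(s1$ref_start - 1L - t); if (b == "") "" else comp[[b]] }
  }, character(1))
  # continuation of segment 2 (backwards) at gap offset t
  back2 <- vapply(seq_len(G) - 1L, function(t) {
    if (s2$strand == "+") gchar(s2$ref_start - (G - t))
    else { b <- gchar(s2$ref_end + (G - t) - 1L); if (b == "") "" else comp[[b]] }
  }, character(1))
  m1 <- as.integer(fwd1 != gap_chars | fwd1 == "")
  m2 <- as.integer(back2 != gap_chars | back2 == "")
  cost <- vapply(0:G, function(s) {
    sum(m1[seq_len(s)]) + sum(m2[seq_len(G - s) + s])
  }, numeric(1))
  s <- which.min(cost) - 1L
  if (cost[s + 1L] > max_mismatch_frac * G) {
    return(list(s1 = s1[c("query_start", "query_end", "ref_start", "ref_end")],
                s2 = s2[c("query_start", "query_end", "ref_start", "ref_end")]))
  }
  s1$query_end <- s1$query_end + s
  if (s1$strand == "+") s1$ref_end <- s1$ref_end + s
  else s1$ref_start <- s1$ref_start - s
  s2$query_start <- s2$query_start - (G - s)
  if (s2$strand == "+") s2$ref_start <- s2$ref_start - (G - s)
  else s2$ref_end <- s2$ref_end + (G - s)
  list(s1 = s1[c("query_start", "query_end", "ref_start", "ref_end")],
       s2 = s2[c("query_start", "query_end", "ref_start", "ref_end")])
}

# per-genome caches (reverse complement, k-mer presence index), keyed on
# sequence content, not just the name (distinct simulated genomes share one)
.ms2drs_cache <- new.env(parent = emptyenv())

genome_cache_key <- function(genome) {
  L <- genome$length
  paste0(genome$name, "_", L, "_",
         substr(genome$sequence, 1L, 32L),
         substr(genome$sequence, L - 31L, L))
}

rc_genome_cached <- function(genome) {
  key <- paste0("rc_", genome_cache_key(genome))
  if (!exists(key, envir = .ms2drs_cache, inherits = FALSE)) {
    assign(key, revcomp(genome$sequence), envir = .ms2drs_cache)
  }
  get(key, envir = .ms2drs_cache, inherits = FALSE)
}

genome_kmer_index <- function(genome, k = 15L) {
  key <- paste0("kmer_", genome_cache_key(genome), "_", k)
  if (!exists(key, envir = .ms2drs_cache, inherits = FALSE)) {
    mk <- function(s) {
      n <- nchar(s) - k + 1L
      e <- new.env(parent = emptyenv(), size = 2L * n)
      km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
      for (x in km) assign(x, TRUE, envir = e)
      e
    }
    assign(key, list(plus = mk(genome$sequence),
                     minus = mk(rc_genome_cached(genome)), k = k),
           envir = .ms2drs_cache)
  }
  get(key, envir = .ms2drs_cache, inherits = FALSE)
}

# count sampled read k-mers present on each genome strand (stride 10)
strand_kmer_hits <- function(read_seq, genome, stride = 10L) {
  idx <- genome_kmer_index(genome)
  k <- idx$k
  n <- nchar(read_seq) - k + 1L
  if (n < 1L) return(c(plus = 1L, minus = 1L)) # too short to screen
  at <- unique(c(seq.int(1L, n, by = stride), n))
  kms <- substring(read_seq, at, at + k - 1L)
  c(plus = sum(vapply(kms, exists, logical(1), envir = idx$plus,
                      inherits = FALSE)),
    minus = sum(vapply(kms, exists, logical(1), envir = idx$minus,
                       inherits = FALSE)))
}

#' Classify a same-strand junction as deletion or duplication
#'
#' The junction offset is computed in transcript orientation: for "+"
#' junctions `delta = ref_start2 - ref_end1 - query_gap`; for "-" junctions
#' the reverse-complement frame gives `delta = ref_start1 - ref_end2 -
#' query_gap`. `delta > 0` means the replicase skipped template (deletion of
#' delta nt), `delta < 0` re-copied template (duplication), `delta == 0` is
#' contiguous (no event).
#'
#' @param strand shared strand of the two segments.
#' @param rs1,re1,rs2,re2 segment reference intervals (genome frame, 0-based
#'   half-open), in query order.
#' @param query_gap unaligned query bases between the segments (may be 0).
#' @return list with `event` ("deletion"/"duplication"/"none") and `delta`.
#' @export
classify_event <- function(strand, rs1, re1, rs2, re2, query_gap = 0L) {
  if (length(strand) == 2L) {
    if (strand[1] != strand[2]) {
      stop("use foldback/strand-switch typing for opposite-strand junctions")
    }
    strand <- strand[1]
  }
  delta <- if (strand == "+") rs2 - re1 - query_gap else rs1 - re2 - query_gap
  event <- if (delta > 0) "deletion" else if (delta < 0) "duplication" else "none"
  list(event = event, delta = as.integer(delta))
}

#' Chain segments of one read and call a hybrid
#'
#' Orders segments by query position, greedily keeps the highest-scoring
#' non-conflicting set, requires consecutive segments to be query-adjacent
#' (gap <= `query_gap_tol`, overlap <= `query_overlap_tol`), and requires at
#' least `min_loci` distinct reference loci (reciprocal overlap < 50% or
#' differing strand). When the read and genome sequences are supplied, each
#' junction is refined by extending the downstream segment backwards across
#' the unaligned query gap with exact base matches (recovers the exact
#' junction of duplications, where local alignment trims ambiguously).
#'
#' @param segments output of [find_segments()] for one read.
#' @param read_seq,genome optional; enable junction refinement.
#' @param query_gap_tol,query_overlap_tol adjacency tolerances (nt).
#' @param min_loci minimum distinct loci (default 2).
#' @param junction_min_delta same-strand junctions with |delta| at or below
#'   this are treated as contiguous (alignment noise, not template
#'   switching); a read whose junctions are all contiguous is not a hybrid.
#' @param read_id identifier stamped on the output.
#' @return `NULL` when the read is not a hybrid, else a tibble with one row
#'   per junction: `read_id`, `junction_index`, `junction_type`, `event`,
#'   `delta`, `in_paper_range` (20 <= |delta| <= 60), `j1_ref`, `j2_ref`
#'   (0-based donor/acceptor genome positions), segment bookkeeping columns
#'   and `n_segments`.
#' @export
chain_and_call <- function(segments, read_seq = NULL, genome = NULL,
                           query_gap_tol = 20L, query_overlap_tol = 20L,
                           min_loci = 2L, junction_min_delta = 5L,
                           read_id = NA_character_) {
  if (is.null(segments) || nrow(segments) < 2L) return(NULL)
  seg <- segments[order(-segments$score), ]
  keep <- rep(FALSE, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(seg$query_end[i], seg$query_end[j]) -
        max(seg$query_start[i], seg$query_start[j])
      if (ov > query_overlap_tol) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  seg <- seg[keep, ]
  seg <- seg[order(seg$query_start), ]
  if (nrow(seg) < 2L) return(NULL)

  # refine junctions before the adjacency test: close unaligned query gaps
  # by exact-match extension (a duplication junction legitimately leaves a
  # gap up to |delta| nt that the local aligner assigns to neither segment)
  refine <- !is.null(read_seq) && !is.null(genome)
  if (refine) {
    for (k in seq_len(nrow(seg) - 1L)) {
      ext <- refine_junction(as.list(seg[k, ]), as.list(seg[k + 1L, ]),
                             read_seq, genome)
      seg[k, names(ext$s1)] <- ext$s1
      seg[k + 1L, names(ext$s2)] <- ext$s2
    }
  }

  # maximal run of query-adjacent segments with the highest total score
  gapvec <- seg$query_start[-1] - seg$query_end[-nrow(seg)]
  adj <- gapvec <= query_gap_tol & gapvec >= -query_overlap_tol
  runs <- split(seq_len(nrow(seg)), cumsum(c(TRUE, !adj)))
  scores <- vapply(runs, function(ix) sum(seg$score[ix]), numeric(1))
  seg <- seg[runs[[which.max(scores)]], ]
  if (nrow(seg) < 2L) return(NULL)

  # distinct loci: strand differs or reciprocal reference overlap < 50%
  same_locus <- function(i, j) {
    if (seg$strand[i] != seg$strand[j]) return(FALSE)
    ov <- min(seg$ref_end[i], seg$ref_end[j]) -
      max(seg$ref_start[i], seg$ref_start[j])
    if (ov <= 0) return(FALSE)
    w1 <- seg$ref_end[i] - seg$ref_start[i]
    w2 <- seg$ref_end[j] - seg$ref_start[j]
    (ov / w1 >= 0.5) && (ov / w2 >= 0.5)
  }
  locus <- integer(nrow(seg))
  nl <- 0L
  for (i in seq_len(nrow(seg))) {
    assigned <- FALSE
    for (j in seq_len(i - 1L)) {
      if (same_locus(i, j)) { locus[i] <- locus[j]; assigned <- TRUE; break }
    }
    if (!assigned) { nl <- nl + 1L; locus[i] <- nl }
  }
  if (nl < min_loci) return(NULL)

  junctions <- list()
  for (k in seq_len(nrow(seg) - 1L)) {
    s1 <- as.list(seg[k, ]); s2 <- as.list(seg[k + 1L, ])
    gap <- s2$query_start - s1$query_end
    # foldback: opposite strands with overlapping reference intervals
    ov <- min(s1$ref_end, s2$ref_end) - max(s1$ref_start, s2$ref_start)
    shorter <- min(s1$ref_end - s1$ref_start, s2$ref_end - s2$ref_start)
    if (s1$strand != s2$strand) {
      jtype <- if (ov > 0 && ov >= 0.5 * shorter) "foldback"
               else if (s1$strand == "-") "neg_pos" else "pos_neg"
      ev <- list(event = "none", delta = NA_integer_)
      jpos <- if (s1$strand == "+") c(s1$ref_end, s2$ref_end)
              else c(s1$ref_start, s2$ref_start)
    } else {
      jtype <- if (s1$strand == "+") "pos_pos" else "neg_neg"
      ev <- classify_event(s1$strand, s1$ref_start, s1$ref_end,
                           s2$ref_start, s2$ref_end, query_gap = gap)
      jpos <- if (s1$strand == "+") c(s1$ref_end, s2$ref_start)
              else c(s1$ref_start, s2$ref_end)
    }
    junctions[[k]] <- tibble(
      read_id = read_id, junction_index = k, junction_type = jtype,
      event = ev$event, delta = ev$delta,
      in_paper_range = !is.na(ev$delta) && abs(ev$delta) >= 20 &
        abs(ev$delta) <= 60,
      j1_ref = jpos[1], j2_ref = jpos[2],
      q_end1 = s1$query_end, q_start2 = s2$query_start,
      strand1 = s1$strand, strand2 = s2$strand,
      ref_start1 = s1$ref_start, ref_end1 = s1$ref_end,
      ref_start2 = s2$ref_start, ref_end2 = s2$ref_end,
      n_segments = nrow(seg)
    )
  }
  out <- bind_rows(junctions)
  real <- out$strand1 != out$strand2 |
    (!is.na(out$delta) & abs(out$delta) > junction_min_delta)
  if (!any(real)) return(NULL)
  out
}

#' Scan a read table for hybrid reads
#'
#' Runs [find_segments()] + [chain_and_call()] over every read with a
#' sequence.
#'
#' @param reads tibble with `read_id`, `seq` and optionally `timepoint`,
#'   `sample` columns.
#' @param genome a [genome_model()].
#' @param ... passed to [find_segments()] and [chain_and_call()].
#' @return tibble of junction rows (zero rows when no hybrids found), with
#'   `timepoint`/`sample`/`query_length` carried over, and a `strand` column
#'   (strand of the first segment).
#' @export
detect_hybrids <- function(reads, genome, min_score = 60L,
                           query_gap_tol = 20L, query_overlap_tol = 20L,
                           min_loci = 2L, ...) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    segs <- find_segments(reads$seq[i], genome, min_score = min_score, ...)
    call <- chain_and_call(segs, read_seq = reads$seq[i], genome = genome,
                           query_gap_tol = query_gap_tol,
                           query_overlap_tol = query_overlap_tol,
                           min_loci = min_loci, read_id = reads$read_id[i])
    if (!is.null(call)) {
      call$timepoint <- if ("timepoint" %in% names(reads)) reads$timepoint[i] else NA_character_
      call$sample <- if ("sample" %in% names(reads)) reads$sample[i] else NA_character_
      call$query_length <- nchar(reads$seq[i])
      call$strand <- call$strand1
      out[[length(out) + 1L]] <- call
    }
  }
  if (length(out) == 0L) return(empty_hybrid_calls())
  bind_rows(out)
}

empty_hybrid_calls <- function() {
  tibble(read_id = character(), junction_index = integer(),
         junction_type = character(), event = character(), delta = integer(),
         in_paper_range = logical(), j1_ref = integer(), j2_ref = integer(),
         q_end1 = integer(), q_start2 = integer(), strand1 = character(),
         strand2 = character(), ref_start1 = integer(), ref_end1 = integer(),
         ref_start2 = integer(), ref_end2 = integer(), n_segments = integer(),
         timepoint = character(), sample = character(),
         query_length = integer(), strand = character())
}

#' Hybrid-to-total read ratios per group
#'
#' @param calls junction table from [detect_hybrids()] (the first junction of
#'   each read defines its type for the breakdown).
#' @param all_reads the full read table the scan ran over (denominator).
#' @param group_by grouping columns present in both tables.
#' @return tibble per group: `n_hybrid`, `n_total`, `ratio`, one column per
#'   junction type count, and deletion/duplication counts.
#' @export
hybrid_summary <- function(calls, all_reads, group_by = "timepoint") {
  group_by <- intersect(group_by, names(all_reads))
  key_all <- if (length(group_by)) {
    interaction(all_reads[group_by], drop = FALSE, lex.order = TRUE)
  } else factor(rep("all", nrow(all_reads)))
  first_j <- calls[!duplicated(calls$read_id) & calls$junction_index == 1L, ]
  key_call <- if (length(group_by) && nrow(first_j)) {
    interaction(first_j[group_by], drop = FALSE, lex.order = TRUE)
  } else factor(rep("all", nrow(first_j)), levels = levels(key_all))
  res <- list()
  for (g in levels(key_all)) {
    n_total <- sum(key_all == g)
    if (n_total == 0L) next
    sub <- first_j[as.character(key_call) == g, ]
    row <- tibble(
      group = g, n_hybrid = nrow(sub), n_total = n_total,
      ratio = nrow(sub) / n_total,
      n_pos_pos = sum(sub$junction_type == "pos_pos"),
      n_neg_neg = sum(sub$junction_type == "neg_neg"),
      n_neg_pos = sum(sub$junction_type %in% c("neg_pos", "pos_neg")),
      n_foldback = sum(sub$junction_type == "foldback"),
      n_deletion = sum(sub$event == "deletion", na.rm = TRUE),
      n_duplication = sum(sub$event == "duplication", na.rm = TRUE),
      median_length = if (nrow(sub)) median(sub$query_length) else NA_real_
    )
    res[[length(res) + 1L]] <- row
  }
  bind_rows(res)
}
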