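# Independent oracles used by the test suite.

# Exhaustive local-alignment segment oracle built on Biostrings'
# Smith-Waterman: find the best local alignment against the genome and its
# reverse complement; alignments carrying an internal gap of >= indel_split
# nt are split at the gap (the declared segment semantics) and each side
# realigned; accepted segments are hard-masked in the query with N (N scores
# -1000 against everything, so no later alignment can reuse or bridge them)
# and the search repeats until the score drops below min_score.
oracle_segments <- function(read_seq, genome, min_score = 60,
                            max_segments = 6L, indel_split = 15L) {
  letters5 <- c("A", "C", "G", "T", "N")
  sm <- matrix(-2, 5, 5, dimnames = list(letters5, letters5))
  diag(sm) <- 1
  sm["N", ] <- -1000
  sm[, "N"] <- -1000
  L <- genome$length
  gplus <- Biostrings::DNAString(genome$sequence)
  gminus <- Biostrings::reverseComplement(gplus)

  best_local <- function(q) {
    qs <- Biostrings::DNAString(q)
    ap <- Biostrings::pairwiseAlignment(qs, gplus, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 4, gapExtension = 2)
    am <- Biostrings::pairwiseAlignment(qs, gminus, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 4, gapExtension = 2)
    use_minus <- Biostrings::score(am) > Biostrings::score(ap)
    a <- if (use_minus) am else ap
    list(a = a, use_minus = use_minus, score = Biostrings::score(a))
  }

  # query coordinate (0-based) of the first gap run >= indel_split, or NA
  long_gap_split <- function(a, q0) {
    pat <- strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]]
    gap <- pat == "-" | sub == "-"
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    big <- which(r$values & r$lengths >= indel_split)
    if (length(big) == 0L) return(NA_integer_)
    col <- starts[big[1]]
    q0 + sum(pat[seq_len(col - 1L)] != "-")
  }

  q <- read_seq
  out <- list()
  for (iter in seq_len(max_segments)) {
    bl <- best_local(q)
    if (bl$score < min_score) break
    a <- bl$a
    q0 <- Biostrings::start(Biostrings::pattern(a)) - 1L
    q1 <- Biostrings::end(Biostrings::pattern(a))
    split_at <- long_gap_split(a, q0)
    if (!is.na(split_at) && split_at > 0L && split_at < nchar(q)) {
      # mask nothing; instead forbid bridging by N-filling the split point?
      # cleaner: realign the two query sides independently and take the
      # better one this round (the other side remains for later rounds)
      left <- paste0(substr(q, 1, split_at),
                     strrep("N", nchar(q) - split_at))
      right <- paste0(strrep("N", split_at),
                      substr(q, split_at + 1L, nchar(q)))
      bl_l <- best_local(left)
      bl_r <- best_local(right)
      bl <- if (bl_l$score >= bl_r$score) bl_l else bl_r
      if (bl$score < min_score) break
      a <- bl$a
      q0 <- Biostrings::start(Biostrings::pattern(a)) - 1L
      q1 <- Biostrings::end(Biostrings::pattern(a))
    }
    sr <- Biostrings::subject(a)
    s0 <- Biostrings::start(sr) - 1L
    s1 <- Biostrings::end(sr)
    if (bl$use_minus) {
      ref_start <- L - s1; ref_end <- L - s0; strand <- "-"
    } else {
      ref_start <- s0; ref_end <- s1; strand <- "+"
    }
    out[[iter]] <- data.frame(
      query_start = q0, query_end = q1, ref_start = ref_start,
      ref_end = ref_end, strand = strand,
      score = as.integer(bl$score)
    )
    substr(q, q0 + 1L, q1) <- strrep("N", q1 - q0)
  }
  if (length(out) == 0L) {
    return(data.frame(query_start = integer(), query_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), score = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$query_start), ]
}

# brute-force Benjamini-Hochberg step-up q-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher exact p-value from the hypergeometric distribution:
# sum of the probabilities of all tables at least as unlikely as observed
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# segment-set agreement for the oracle-equivalence checks: every production
# segment matches an oracle segment with same strand and loci within tol nt
segments_agree <- function(prod, oracle, tol = 3L) {
  if (nrow(prod) != nrow(oracle)) return(FALSE)
  if (nrow(prod) == 0L) return(TRUE)
  used <- rep(FALSE, nrow(oracle))
  for (i in seq_len(nrow(prod))) {
    hit <- FALSE
    for (j in which(!used)) {
      if (prod$strand[i] == oracle$strand[j] &&
          abs(prod$ref_start[i] - oracle$ref_start[j]) <= tol &&
          abs(prod$ref_end[i] - oracle$ref_end[j]) <= tol) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}
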