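# Synthetic MS2-like data generator.
#
# Emulates the read populations a DRS time course of an ssRNA phage
# produces: full-length genomic reads, 3'-anchored truncated reads (DRS 3'
# bias), 5'-anchored degraded reads, coat / coat+lys subgenomic reads,
# other internal fragments, negative-strand full-length intermediates,
# template-switch hybrids (deletion/duplication, 20-60 nt emphasis),
# (+-) foldback reads, and per-read modification-probability tables with an
# IVT (modification-free) control. Every read carries a ground-truth label.

READ_CLASSES <- c("full_length", "three_prime_anchored", "five_prime_anchored",
                  "coat_subgenomic", "coat_lys_subgenomic", "other_internal",
                  "negative_full_length")

# MS2 ORF coordinates (1-based inclusive in the literature), stored 0-based
# half-open. Scaled proportionally for non-default genome lengths.
MS2_ORF_LAYOUT <- data.frame(
  name = c("mat", "coat", "lys", "rep"),
  start = c(129L, 1334L, 1677L, 1760L),
  end = c(1311L, 1727L, 1905L, 3398L),
  stringsAsFactors = FALSE
)

#' Generate an MS2-like reference genome
#'
#' Random sequence with four ORFs in MS2 order (lys overlaps the coat/rep
#' boundary region), an ATG planted at each ORF start, a stop codon at each
#' ORF end, and an AG-rich hexamer (Shine-Dalgarno-like) 8-12 nt upstream of
#' each ORF start.
#'
#' @param length genome length in nt (default 3569, the MS2 genome size).
#' @param orf_layout data frame with `name`, `start`, `end` (0-based
#'   half-open); default is the MS2 layout, scaled if `length != 3569`.
#' @param seed RNG seed; same seed gives a byte-identical genome.
#' @return a [genome_model()].
#' @export
make_genome <- function(length = 3569L, orf_layout = NULL, seed = 1L) {
  length <- as.integer(length)
  if (length < 600L) stop("genome length must be >= 600 nt")
  if (is.null(orf_layout)) {
    sc <- length / 3569
    orf_layout <- MS2_ORF_LAYOUT
    orf_layout$start <- as.integer(floor(orf_layout$start * sc))
    orf_layout$end <- as.integer(floor(orf_layout$end * sc))
  }
  if (any(orf_layout$end > length) || any(orf_layout$start < 20L) ||
      any(orf_layout$end - orf_layout$start < 60L)) {
    stop("ORF layout does not fit in a ", length, " nt genome")
  }
  set.seed(seed)
  seq <- sample(DNA_BASES, length, replace = TRUE)

  planted <- list()
  plant <- function(seq, at, motif) {
    iv <- c(at, at + nchar(motif)) # 0-based half-open
    for (p in planted) {
      if (iv[1] < p[2] && p[1] < iv[2]) {
        stop("overlapping ORF layout: planted features collide at ", iv[1])
      }
    }
    planted[[length(planted) + 1L]] <<- iv
    seq[(at + 1L):(at + nchar(motif))] <- strsplit(motif, "")[[1]]
    seq
  }
  stops <- c("TAA", "TAG", "TGA")
  for (k in seq_len(nrow(orf_layout))) {
    s <- orf_layout$start[k]; e <- orf_layout$end[k]
    seq <- plant(seq, s, "ATG")
    seq <- plant(seq, e - 3L, stops[1L + (k - 1L) %% 3L])
    gap <- sample(8:12, 1L)
    seq <- plant(seq, s - gap - 6L, "AGGAGG")
  }
  genome_model(sprintf("synthMS2_L%d", length), paste(seq, collapse = ""),
               orf_layout)
}

default_class_mixture <- function() {
  c(full_length = 0.25, three_prime_anchored = 0.30,
    five_prime_anchored = 0.15, coat_subgenomic = 0.10,
    coat_lys_subgenomic = 0.02, other_internal = 0.13,
    negative_full_length = 0.05)
}

orf_interval <- function(genome, which_name, fallback_idx) {
  o <- genome$orfs
  i <- match(which_name, o$name)
  if (is.na(i)) i <- min(fallback_idx, nrow(o))
  c(o$start[i], o$end[i])
}

#' Simulate a read population with ground-truth class labels
#'
#' Draws each read's class from `mixture` (multinomial), then draws genome
#' coordinates from that class's generator. Class generators respect the
#' downstream classifier's precedence rules with a safety margin, so on
#' error-free data the truth labels and recovered labels agree except for
#' rare boundary draws.
#'
#' @param genome a [genome_model()].
#' @param n_reads number of reads.
#' @param mixture named proportions over the class vocabulary (must sum to 1).
#' @param error_rate per-base substitution probability (no indels).
#' @param seed RNG seed.
#' @param timepoint,sample labels stamped on every read.
#' @param sequences if TRUE, materialise read sequences and per-base PHRED
#'   strings (mean about 14); if FALSE only coordinates, lengths and per-read
#'   mean quality are generated (sufficient for the classification, hotspot
#'   and coverage stages).
#' @param anchor_tol maximum distance of an anchored read's terminal end from
#'   the genome terminus (nt).
#' @return list with `reads` (aligned-read tibble, plus `seq`/`qual` when
#'   `sequences = TRUE`) and `truth` (read_id, true_class, true_strand,
#'   true_ref_start, true_ref_end).
#' @export
simulate_reads <- function(genome, n_reads, mixture = default_class_mixture(),
                           error_rate = 0, seed = 1L, timepoint = "0h",
                           sample = "test", sequences = TRUE,
                           anchor_tol = 10L) {
  stopifnot(all(names(mixture) %in% READ_CLASSES))
  if (abs(sum(mixture) - 1) > 1e-8) stop("class mixture must sum to 1")
  L <- genome$length
  set.seed(seed)
  cls <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)

  coat <- orf_interval(genome, "coat", 2L)
  lys <- orf_interval(genome, "lys", 3L)
  lys_len <- lys[2] - lys[1]
  # end coordinate beyond which a coat-containing read also covers >=90% of lys
  lys_cov_end <- lys[1] + ceiling(0.9 * lys_len)

  n <- n_reads
  start <- integer(n); end <- integer(n); strand <- rep("+", n)
  runif_int <- function(k, lo, hi) lo + floor(runif(k) * (hi - lo + 1))

  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    k <- length(idx)
    if (cl %in% c("full_length", "negative_full_length")) {
      span <- pmin(L, floor(runif(k, 0.93, 1.0) * L) + 1L)
      st <- runif_int(k, 0L, L - span)
      start[idx] <- st; end[idx] <- st + span
      if (cl == "negative_full_length") strand[idx] <- "-"
    } else if (cl == "three_prime_anchored") {
      en <- L - runif_int(k, 0L, anchor_tol - 1L)
      st <- runif_int(k, ceiling(0.103 * L), en - 60L)
      start[idx] <- st; end[idx] <- en
    } else if (cl == "five_prime_anchored") {
      st <- runif_int(k, 0L, anchor_tol - 1L)
      en <- runif_int(k, st + 60L, floor(0.897 * L))
      start[idx] <- st; end[idx] <- en
    } else if (cl == "coat_subgenomic") {
      max_end <- min(coat[1] + 775L, lys_cov_end - 5L)
      en <- runif_int(k, coat[2] + 5L, max_end)
      st <- runif_int(k, pmax(30L, en - 775L), coat[1] - 5L)
      start[idx] <- st; end[idx] <- en
    } else if (cl == "coat_lys_subgenomic") {
      st <- runif_int(k, coat[1] - 80L, coat[1] - 5L)
      en <- runif_int(k, lys[2] + 5L, min(lys[2] + 90L, L - 30L))
      start[idx] <- st; end[idx] <- en
    } else { # other_internal
      span <- runif_int(k, 60L, min(349L, floor(0.9 * (coat[2] - coat[1])) - 5L))
      st <- runif_int(k, 30L, L - span - 30L)
      start[idx] <- st; end[idx] <- st + span
    }
  }

  read_id <- sprintf("%s_%s_r%06d", sample, timepoint, seq_len(n))
  reads <- tibble(
    read_id = read_id, strand = strand,
    ref_start = as.integer(start), ref_end = as.integer(end),
    query_length = as.integer(end - start),
    mean_phred = NA_real_, timepoint = timepoint, sample = sample,
    is_primary = TRUE
  )
  if (sequences) {
    seqs <- substring(genome$sequence, start + 1L, end)
    if (error_rate > 0) seqs <- apply_substitutions(seqs, error_rate)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg]) # biological orientation
    qual <- random_quals(nchar(seqs))
    reads$seq <- seqs
    reads$qual <- qual$strings
    reads$mean_phred <- qual$means
  } else {
    reads$mean_phred <- round(rnorm(n, 14, 0.8), 2)
  }
  truth <- tibble(
    read_id = read_id, true_class = cls, true_strand = strand,
    true_ref_start = as.integer(start), true_ref_end = as.integer(end)
  )
  list(reads = reads, truth = truth)
}

# per-base PHRED scores centred on 14, clamped to [3, 30]
random_quals <- function(lens) {
  total <- sum(lens)
  q <- pmin(pmax(round(rnorm(total, 14, 3)), 3L), 30L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  raw_all <- as.raw(q + 33L)
  strings <- vapply(seq_along(lens), function(i) {
    if (lens[i] == 0L) return("")
    rawToChar(raw_all[starts[i]:ends[i]])
  }, character(1))
  means <- vapply(seq_along(lens), function(i) {
    if (lens[i] == 0L) return(NA_real_)
    mean(q[starts[i]:ends[i]])
  }, numeric(1))
  list(strings = strings, means = means)
}

# substitution-only error model: each base flips to one of the three other
# bases with probability `rate`
apply_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate template-switch hybrid and foldback reads
#'
#' Constructs chimeric reads by concatenating genome blocks:
#' * pos_pos deletion: `genome[a:j1) + genome[j1+delta:b)`
#' * pos_pos duplication: `genome[a:j1) + genome[j1-delta:b)`
#' * neg_neg: the reverse complement of the analogous construct (both
#'   segments on the negative strand)
#' * foldback: `genome[a:b) + revcomp(genome[b-arm:b))` — a (+-) copyback.
#'
#' @param genome a [genome_model()].
#' @param hybrid_spec data frame with columns `type` (pos_pos, neg_neg,
#'   foldback), `event` (deletion, duplication; ignored for foldback), `n`,
#'   `delta_min`, `delta_max`. Optional `j1` fixes the first junction
#'   coordinate (0-based) instead of drawing it.
#' @param seed RNG seed.
#' @param error_rate per-base substitution probability.
#' @param timepoint,sample labels.
#' @return list with `reads` (read_id, seq, mean_phred, ...) and `truth`
#'   (read_id, type, event, delta, junction coordinates `j1`, `j2` (0-based),
#'   block bounds `a`, `b`, `arm` for foldbacks).
#' @export
simulate_hybrids <- function(genome, hybrid_spec, seed = 1L, error_rate = 0,
                             timepoint = "6h", sample = "test") {
  L <- genome$length
  set.seed(seed)
  spec <- as_tibble(hybrid_spec)
  if (!"j1" %in% names(spec)) spec$j1 <- NA_integer_
  if (!"event" %in% names(spec)) spec$event <- NA_character_
  rows <- list()
  rid <- 0L
  runif_int <- function(k, lo, hi) lo + floor(runif(k) * (hi - lo + 1))
  for (r in seq_len(nrow(spec))) {
    ty <- spec$type[r]; ev <- spec$event[r]; nn <- spec$n[r]
    dmin <- spec$delta_min[r]; dmax <- spec$delta_max[r]
    if (ty != "foldback" && (dmin < 1L || dmax < dmin)) {
      stop("delta range must lie in [1, 200]: a zero offset is not a hybrid")
    }
    for (i in seq_len(nn)) {
      rid <- rid + 1L
      id <- sprintf("%s_%s_h%05d", sample, timepoint, rid)
      if (ty == "foldback") {
        seglen <- runif_int(1L, 300L, 800L)
        a <- runif_int(1L, 0L, L - seglen)
        b <- a + seglen
        arm <- runif_int(1L, 100L, seglen - 50L)
        sq <- paste0(genome_seq(genome, a, b),
                     revcomp(genome_seq(genome, b - arm, b)))
        rows[[rid]] <- tibble(read_id = id, type = ty, event = "none",
                              delta = NA_integer_, j1 = b, j2 = b,
                              a = a, b = b, arm = arm, seq = sq)
      } else {
        delta <- runif_int(1L, dmin, dmax)
        j1 <- spec$j1[r]
        if (is.na(j1)) j1 <- runif_int(1L, 600L, L - 600L)
        if (j1 - 150L < 0L) stop("junction too close to genome start")
        a <- runif_int(1L, max(0L, j1 - 800L), j1 - 150L)
        if (ev == "deletion") {
          j2 <- j1 + delta
        } else if (ev == "duplication") {
          j2 <- j1 - delta
        } else stop("event must be deletion or duplication for ", ty)
        bmax <- min(L, j2 + 800L)
        # second block of at least 150 nt, relaxing to 80 nt near the 3' end
        bmin <- if (j2 + 150L <= bmax) j2 + 150L else j2 + 80L
        if (bmin > bmax) stop("junction too close to genome end")
        b <- runif_int(1L, bmin, bmax)
        sq <- paste0(genome_seq(genome, a, j1), genome_seq(genome, j2, b))
        if (ty == "neg_neg") sq <- revcomp(sq)
        rows[[rid]] <- tibble(read_id = id, type = ty, event = ev,
                              delta = delta, j1 = j1, j2 = j2,
                              a = a, b = b, arm = NA_integer_, seq = sq)
      }
    }
  }
  truth <- bind_rows(rows)
  seqs <- truth$seq
  if (error_rate > 0) seqs <- apply_substitutions(seqs, error_rate)
  reads <- tibble(
    read_id = truth$read_id, seq = seqs,
    query_length = nchar(seqs), mean_phred = round(rnorm(nrow(truth), 14, 0.8), 2),
    timepoint = timepoint, sample = sample
  )
  truth$seq <- NULL
  list(reads = reads, truth = truth)
}

MOD_BASE <- c(m5C = "C", psi = "T", m6A = "A", inosine = "A")

#' Simulate per-read modification-probability calls
#'
#' For each positive-strand read covering a configured site, the read is
#' modified with probability equal to the site's true stoichiometry
#' (Bernoulli); modified reads receive a call probability ~ Uniform(0.85, 1),
#' unmodified reads ~ Uniform(0, 0.30). With `ivt = TRUE` the true
#' stoichiometry is forced to 0 everywhere except at `artifact_sites`, which
#' are planted identically in test and IVT samples to exercise the IVT
#' background subtraction.
#'
#' @param genome a [genome_model()].
#' @param mod_sites data frame with `ref_pos` (0-based), `mod_type` and
#'   either one `stoichiometry` column or one row per (`timepoint`,
#'   `stoichiometry`) pair.
#' @param reads aligned-read tibble (strand, ref_start, ref_end, timepoint).
#' @param ivt logical; see above.
#' @param artifact_sites optional data frame like `mod_sites` giving apparent
#'   (systematic false-positive) stoichiometries present in both conditions.
#' @param seed RNG seed.
#' @param sample sample label stamped on the records.
#' @return tibble of ModCallRecords: read_id, ref_pos (0-based), mod_type,
#'   probability, sample, timepoint.
#' @export
simulate_modifications <- function(genome, mod_sites, reads, ivt = FALSE,
                                   artifact_sites = NULL, seed = 1L,
                                   sample = if (ivt) "ivt" else "test") {
  set.seed(seed)
  norm_sites <- function(s) {
    s <- as_tibble(s)
    if (!"timepoint" %in% names(s)) s$timepoint <- NA_character_
    s[, c("ref_pos", "mod_type", "timepoint", "stoichiometry")]
  }
  sites <- if (is.null(mod_sites) || nrow(as_tibble(mod_sites)) == 0L) {
    NULL
  } else norm_sites(mod_sites)
  if (ivt && !is.null(sites)) sites$stoichiometry <- 0
  if (!is.null(artifact_sites) && nrow(as_tibble(artifact_sites)) > 0L) {
    sites <- bind_rows(sites, norm_sites(artifact_sites))
  }
  if (is.null(sites) || nrow(sites) == 0L) return(empty_mod_calls())

  base_at <- substring(genome$sequence, sites$ref_pos + 1L, sites$ref_pos + 1L)
  need <- MOD_BASE[sites$mod_type]
  bad <- !is.na(need) & base_at != need
  if (any(bad)) {
    stop("mod site base incompatible with type: position ",
         sites$ref_pos[which(bad)[1]] + 1L, " is ", base_at[which(bad)[1]],
         " but ", sites$mod_type[which(bad)[1]], " requires ",
         need[which(bad)[1]])
  }
  pos_reads <- reads[reads$strand == "+", ]
  out <- list()
  for (k in seq_len(nrow(sites))) {
    p <- sites$ref_pos[k]
    cov <- pos_reads[pos_reads$ref_start <= p & pos_reads$ref_end > p, ]
    if (!is.na(sites$timepoint[k])) {
      cov <- cov[cov$timepoint == sites$timepoint[k], ]
    }
    m <- nrow(cov)
    if (m == 0L) next
    modified <- runif(m) < sites$stoichiometry[k]
    prob <- ifelse(modified, runif(m, 0.85, 1.0), runif(m, 0.0, 0.30))
    out[[length(out) + 1L]] <- tibble(
      read_id = cov$read_id, ref_pos = p, mod_type = sites$mod_type[k],
      probability = round(prob, 4), sample = sample,
      timepoint = cov$timepoint
    )
  }
  if (length(out) == 0L) return(empty_mod_calls())
  bind_rows(out)
}

empty_mod_calls <- function() {
  tibble(read_id = character(), ref_pos = integer(), mod_type = character(),
         probability = numeric(), sample = character(), timepoint = character())
}

#' Write simulated reads to FASTQ
#' @param reads tibble with read_id, seq and optionally qual.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
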