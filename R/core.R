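# Shared sequence primitives: interval arithmetic, local alignment and
# low-complexity scoring. Coordinates are 0-based half-open internally,
# matching BED conventions.

#' Merge intervals into a disjoint sorted set
#'
#' Collapses a set of 0-based half-open intervals on one sequence into the
#' minimal sorted set of pairwise-disjoint intervals covering the same bases.
#'
#' @param intervals A data.frame with integer columns `start` and `end`
#'   (0-based half-open, `start < end`), or a zero-row data.frame.
#' @return A data.frame with columns `start`, `end`, sorted by `start`,
#'   pairwise disjoint, covering exactly the union of the input.
#' @examples
#' merge_intervals(data.frame(start = c(0, 5), end = c(10, 15)))
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  stopifnot(all(intervals$start >= 0), all(intervals$end > intervals$start))
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir)
  data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

# Total number of bases covered by a set of (possibly overlapping) intervals.
.interval_coverage <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

#' Shannon entropy of word usage in a sequence
#'
#' Sequence complexity as the Shannon entropy (bits) of the empirical
#' distribution of overlapping words. Homopolymers score 0; uniform word
#' usage scores `2 * word_size` bits. Used as the low-complexity filter in
#' repeat discovery.
#'
#' @param sequence Character string or `DNAString`.
#' @param word_size Word length, one of 1, 2 or 3.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy("ACGTACGT", 1) # 2 bits
#' shannon_entropy("ACACACACA", 2) # 1 bit (4 x AC, 4 x CA)
#' @export
shannon_entropy <- function(sequence, word_size = 1L) {
  stopifnot(word_size %in% 1:3)
  s <- .as_seq_string(sequence)
  n <- nchar(s)
  stopifnot(n >= word_size)
  words <- substring(s, seq_len(n - word_size + 1L),
                     seq_len(n - word_size + 1L) + word_size - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0L) return(0)
  p <- table(words) / length(words)
  -sum(p * log2(p))
}

#' Best local alignment between two sequences
#'
#' Smith-Waterman optimal local alignment (via [Biostrings::pairwiseAlignment])
#' with affine gaps. For nucleotide input both strands of the query are
#' searched and the better hit is returned. Identity is computed over aligned
#' columns excluding gaps. An approximate Karlin-Altschul expectation value is
#' attached (ungapped lambda for the given match/mismatch scheme, K = 0.1;
#' for amino-acid input BLAST's gapped BLOSUM62 constants lambda = 0.267,
#' K = 0.041).
#'
#' @param query,subject Character strings, `DNAString`s, or `AAString`s (set
#'   `type = "aa"` for amino acids).
#' @param match,mismatch Match/mismatch scores (nucleotide mode). Ambiguity
#'   codes are converted to N and N never matches.
#' @param gap_open,gap_extend Gap penalties as positive costs; a gap of
#'   length k costs `gap_open + k * gap_extend`.
#' @param type `"nt"` (default) or `"aa"` (BLOSUM62).
#' @param both_strands Search the reverse complement too (nucleotide only).
#' @return A one-row data.frame: `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (0-based half-open, on the forward query), `strand`,
#'   `identity`, `score`, `evalue`, `aligned_len`.
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")
#' @export
local_align <- function(query, subject, match = 1, mismatch = -1,
                        gap_open = 2, gap_extend = 1, type = c("nt", "aa"),
                        both_strands = TRUE) {
  type <- match.arg(type)
  go <- abs(gap_open)
  ge <- abs(gap_extend)
  if (type == "aa") {
    q <- Biostrings::AAString(as.character(query))
    s <- Biostrings::AAString(as.character(subject))
    stopifnot(length(q) > 0L, length(s) > 0L)
    aln <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = go, gapExtension = ge)
    hit <- .aln_to_hit(aln, strand = "+", qlen = length(q))
    hit$evalue <- .approx_evalue(hit$score, length(q), length(s),
                                 lambda = 0.267, K = 0.041)
    return(hit)
  }
  qs <- .as_seq_string(query)
  ss <- .as_seq_string(subject)
  stopifnot(nchar(qs) > 0L, nchar(ss) > 0L)
  sm <- .nuc_matrix(match, mismatch)
  aln_f <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qs), Biostrings::DNAString(ss), type = "local",
    substitutionMatrix = sm, gapOpening = go, gapExtension = ge)
  best <- .aln_to_hit(aln_f, strand = "+", qlen = nchar(qs))
  if (both_strands) {
    qr <- .revcomp_chr(qs)
    aln_r <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qr), Biostrings::DNAString(ss), type = "local",
      substitutionMatrix = sm, gapOpening = go, gapExtension = ge)
    if (Biostrings::score(aln_r) > best$score) {
      best <- .aln_to_hit(aln_r, strand = "-", qlen = nchar(qs))
    }
  }
  lambda <- .ka_lambda(match, mismatch)
  best$evalue <- .approx_evalue(best$score, nchar(qs), nchar(ss), lambda)
  best
}

# Convert a PairwiseAlignments object (single pair) to a hit row. Query
# coordinates are reported on the forward strand of the original query.
.aln_to_hit <- function(aln, strand, qlen) {
  qrange <- Biostrings::pattern(aln)
  srange <- Biostrings::subject(aln)
  qs <- Biostrings::start(qrange)
  qe <- Biostrings::end(qrange)
  if (strand == "-") {
    tmp <- qs
    qs <- qlen - qe + 1L
    qe <- qlen - tmp + 1L
  }
  nmatch <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  ident <- if (nmatch + nmis > 0) nmatch / (nmatch + nmis) else 0
  data.frame(
    query_start = qs - 1L, query_end = qe,
    subject_start = Biostrings::start(srange) - 1L,
    subject_end = Biostrings::end(srange),
    strand = strand, identity = ident,
    score = Biostrings::score(aln),
    evalue = NA_real_,
    aligned_len = Biostrings::nchar(aln)
  )
}

# ---- vectorized read-vs-entry local alignment (internal workhorse) ----

# Align a DNAStringSet of read segments against one subject sequence on one
# strand; returns a data.frame of per-read best local hits. Scoring is a
# blast-like scheme tuned for ~70-100% identity hits.
.align_set <- function(patterns, subject_chr, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2) {
  sm <- .nuc_matrix(match, mismatch)
  # a single subject is aligned against every pattern; a vector of subjects
  # (one per pattern) is aligned elementwise
  subj <- if (length(subject_chr) == 1L) {
    Biostrings::DNAString(subject_chr)
  } else {
    Biostrings::DNAStringSet(subject_chr)
  }
  aln <- Biostrings::pairwiseAlignment(
    patterns, subj, type = "local",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  nmatch <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  data.frame(
    idx = seq_along(patterns),
    p_start = Biostrings::start(pr), p_end = Biostrings::end(pr),
    s_start = Biostrings::start(sr), s_end = Biostrings::end(sr),
    nmatch = nmatch,
    identity = ifelse(nmatch + nmis > 0, nmatch / (nmatch + nmis), 0),
    score = Biostrings::score(aln)
  )
}

# ---- 2-bit l-mer encoding (internal) ----

# Encode every l-mer window of each read as a double in [0, 4^l), with its
# reverse-complement value and the canonical (elementwise minimum) value.
# Windows containing N are dropped. Returns a data.frame with columns
# read (integer index), pos (1-based start within read), fwd, canon, strand
# ("+" if the forward value is canonical).
.lmer_index <- function(reads, l) {
  stopifnot(l >= 2, l <= 15)
  seqs <- as.character(reads)
  codes <- lapply(seqs, function(s) {
    x <- match(.chars(s), .BASES) - 1L
    x
  })
  out <- vector("list", length(codes))
  p4 <- 4^(0:(l - 1))
  for (i in seq_along(codes)) {
    x <- codes[[i]]
    n <- length(x)
    if (n < l) next
    k <- n - l + 1L
    fwd <- numeric(k)
    rev <- numeric(k)
    for (j in seq_len(l)) {
      xj <- x[j:(j + k - 1L)]
      fwd <- fwd * 4 + xj
      rev <- rev + (3 - xj) * p4[j]
    }
    bad <- is.na(fwd) | is.na(rev)
    canon <- pmin(fwd, rev)
    out[[i]] <- data.frame(
      read = i, pos = seq_len(k), fwd = fwd, canon = canon,
      strand = ifelse(fwd <= rev, "+", "-")
    )[!bad, , drop = FALSE]
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Decode a 2-bit l-mer value back to a string.
.lmer_decode <- function(val, l) {
  vapply(val, function(v) {
    ch <- character(l)
    for (j in l:1) {
      ch[j] <- .BASES[(v %% 4) + 1]
      v <- v %/% 4
    }
    paste(ch, collapse = "")
  }, character(1))
}

# Encode a single l-mer string to its forward value.
.lmer_encode <- function(kmer) {
  x <- match(.chars(kmer), .BASES) - 1L
  v <- 0
  for (j in seq_along(x)) v <- v * 4 + x[j]
  v
}
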