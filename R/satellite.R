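# Tandem satellite characterization: monomer extraction from reads,
# monomer statistics (length range, GC, pairwise identity, partner counts),
# position-frequency / information-content profiles, and in silico
# restriction-digest ladders.

#' Extract full-length satellite monomer copies from reads
#'
#' Locates arrays by local alignment of each read against the monomer
#' consensus tiled head-to-tail (both strands), then cuts out every complete
#' phased unit (units truncated by read ends are discarded). Copies are
#' strand-normalized and phased to the consensus start. When more than
#' `max_copies` copies are found, that many are sampled uniformly at random
#' (seeded).
#'
#' @param reads Read set.
#' @param monomer_consensus Monomer sequence (length >= 50 nt).
#' @param max_copies Maximum copies returned (default 1000).
#' @param min_identity Per-unit identity floor (default 0.7).
#' @param min_len_frac Minimum unit length as a fraction of the consensus
#'   length (default 0.9); shorter (partially deleted) units are dropped.
#' @param seed Seed for the subsampling step.
#' @return Object of class `monomer_set`: list with `copies`
#'   (`DNAStringSet`), `info` (data.frame: `read`, `offset` 0-based,
#'   `strand`), `n_hits` (number of reads with at least one full unit),
#'   `phased`.
#' @export
extract_monomers <- function(reads, monomer_consensus, max_copies = 1000L,
                             min_identity = 0.7, min_len_frac = 0.9,
                             seed = 1L) {
  reads <- .as_readset(reads)
  mono <- .as_seq_string(monomer_consensus)
  L <- nchar(mono)
  stopifnot(L >= 50L)
  if (length(reads) == 0L) {
    warning("no reads supplied")
    return(.empty_monomer_set())
  }
  max_w <- max(Biostrings::width(reads))
  reps <- max(2L, ceiling((1.2 * max_w + 2 * L) / L))
  tiled <- strrep(mono, reps)
  # prefilter reads sharing a seed k-mer with the monomer
  sl <- min(11L, L)
  midx <- .lmer_index(Biostrings::DNAStringSet(tiled), sl)
  ridx <- .lmer_index(reads, sl)
  cand_reads <- sort(unique(ridx$read[ridx$canon %in% unique(midx$canon)]))
  if (!length(cand_reads)) {
    warning("no monomer hits found in the reads")
    return(.empty_monomer_set())
  }
  copies <- list()
  info <- list()
  sub <- reads[cand_reads]
  S4Vectors::mcols(sub) <- NULL
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") sub else Biostrings::reverseComplement(sub)
    sm <- .nuc_matrix(2, -3)
    aln <- Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(tiled), type = "local",
      substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    for (k in seq_along(pats)) {
      if (Biostrings::nchar(aln[k]) < min_len_frac * L) next
      # choose the better strand per read: handled by comparing scores later;
      # here we simply harvest units from both and dedupe by score
      units <- .harvest_units(aln[k], as.character(pats[[k]]), L,
                              min_identity, min_len_frac)
      if (is.null(units)) next
      w <- Biostrings::width(pats)[k]
      for (u in units) {
        off <- u$start - 1L
        if (strand == "-") off <- w - u$end
        copies[[length(copies) + 1L]] <- u$seq
        info[[length(info) + 1L]] <- data.frame(
          read = names(sub)[k], offset = off, strand = strand,
          score = sc[k], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(copies)) {
    warning("no full-length monomer copies found")
    return(.empty_monomer_set())
  }
  info <- do.call(rbind, info)
  # keep only the better strand per read
  best_strand <- tapply(info$score, info$read, function(v) max(v))
  keep <- info$score == best_strand[info$read]
  # in the rare tie both strands survive; dedupe identical (read, offset)
  keep <- keep & !duplicated(info[, c("read", "offset")])
  copies <- unlist(copies)[keep]
  info <- info[keep, c("read", "offset", "strand"), drop = FALSE]
  n_hits <- length(unique(info$read))
  if (length(copies) > max_copies) {
    pick <- with_seed(seed, sample.int(length(copies), max_copies))
    pick <- sort(pick)
    copies <- copies[pick]
    info <- info[pick, , drop = FALSE]
  }
  cs <- Biostrings::DNAStringSet(copies)
  names(cs) <- sprintf("copy_%05d", seq_along(cs))
  rownames(info) <- NULL
  structure(list(copies = cs, info = info, n_hits = n_hits, phased = TRUE),
            class = "monomer_set")
}

.empty_monomer_set <- function() {
  structure(list(copies = Biostrings::DNAStringSet(),
                 info = data.frame(read = character(0), offset = integer(0),
                                   strand = character(0)),
                 n_hits = 0L, phased = TRUE),
            class = "monomer_set")
}

# Walk the alignment columns of one read-vs-tiled-monomer hit and cut out
# each complete unit [j*L, (j+1)*L) of the tiled subject, mapped back to
# pattern (read) coordinates. Insertions relative to the consensus are kept
# in the copy sequence; per-unit identity is checked column-wise.
.harvest_units <- function(aln, pat_chr, L, min_identity, min_len_frac) {
  pal <- .chars(as.character(Biostrings::alignedPattern(aln)))
  sal <- .chars(as.character(Biostrings::alignedSubject(aln)))
  ps <- Biostrings::start(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  ppos <- ps - 1L
  spos <- ss - 1L
  # unit index for subject position x (1-based): (x-1) %/% L
  first_unit <- ceiling((ss - 1L) / L)  # first unit fully at/after ss - 1
  units <- list()
  cur_unit <- -1L
  u_p_start <- NA_integer_
  match_cnt <- 0L
  col_cnt <- 0L
  for (i in seq_along(pal)) {
    if (sal[i] != "-") spos <- spos + 1L
    if (pal[i] != "-") ppos <- ppos + 1L
    if (sal[i] == "-") next
    unit <- (spos - 1L) %/% L
    in_unit_pos <- (spos - 1L) %% L + 1L
    if (in_unit_pos == 1L) {
      cur_unit <- unit
      u_p_start <- if (pal[i] == "-") ppos + 1L else ppos
      match_cnt <- 0L
      col_cnt <- 0L
    }
    if (unit == cur_unit) {
      col_cnt <- col_cnt + 1L
      if (pal[i] != "-" && pal[i] == sal[i]) match_cnt <- match_cnt + 1L
      if (in_unit_pos == L) {
        u_p_end <- ppos
        len <- u_p_end - u_p_start + 1L
        if (len >= min_len_frac * L && len <= (2 - min_len_frac) * L &&
            match_cnt / col_cnt >= min_identity) {
          units[[length(units) + 1L]] <- list(
            seq = substr(pat_chr, u_p_start, u_p_end),
            start = u_p_start, end = u_p_end)
        }
        cur_unit <- -1L
      }
    }
  }
  if (length(units)) units else NULL
}

#' @export
print.monomer_set <- function(x, ...) {
  cat("Monomer set:", length(x$copies), "copies from", x$n_hits,
      "reads\n")
  invisible(x)
}

#' Satellite monomer statistics
#'
#' Computes all pairwise identities among the copies (matched bases divided
#' by the shorter sequence's length), the mean pairwise identity, the length
#' range, pooled GC content, and the number of copies with an identity
#' strictly greater than `partner_identity` to at least one other copy.
#'
#' @param monomers A `monomer_set` or `DNAStringSet` of copies (>= 2).
#' @param partner_identity Partner threshold, strict `>` (default 0.94).
#' @return List of class `satellite_stats`: `n`, `mean_pairwise_identity`
#'   (percent), `length_range`, `gc_percent`, `partner_count`,
#'   `consensus`, `consensus_length`, `identity_to_consensus` (mean
#'   percent).
#' @export
monomer_stats <- function(monomers, partner_identity = 0.94) {
  copies <- if (inherits(monomers, "monomer_set")) monomers$copies else monomers
  if (is.character(copies)) copies <- Biostrings::DNAStringSet(copies)
  n <- length(copies)
  if (n < 2L) stop("at least 2 monomer copies are required")
  idm <- .pairwise_identity_matrix(copies)
  offdiag <- idm[upper.tri(idm)]
  maxpart <- apply(idm + diag(-Inf, n), 1L, max)
  cons <- .majority_consensus(copies)
  cons_id <- vapply(seq_len(n), function(i) {
    .pair_identity(as.character(copies[[i]]), cons)
  }, numeric(1))
  gc <- sum(Biostrings::letterFrequency(copies, c("G", "C"))) /
    sum(Biostrings::width(copies))
  structure(list(
    n = n,
    mean_pairwise_identity = 100 * mean(offdiag),
    length_range = range(Biostrings::width(copies)),
    gc_percent = 100 * gc,
    partner_count = sum(maxpart > partner_identity),
    consensus = cons,
    consensus_length = nchar(cons),
    identity_to_consensus = 100 * mean(cons_id),
    identity_matrix = idm
  ), class = "satellite_stats")
}

#' @export
print.satellite_stats <- function(x, ...) {
  cat("Satellite monomer statistics (", x$n, " copies)\n", sep = "")
  cat("  consensus length:", x$consensus_length, "nt; copy lengths",
      x$length_range[1], "-", x$length_range[2], "\n")
  cat("  GC:", round(x$gc_percent, 2), "%; mean pairwise identity:",
      round(x$mean_pairwise_identity, 1), "%\n")
  cat("  copies with a >94% partner:", x$partner_count, "\n")
  invisible(x)
}

# All-pairs identity. Equal-width copies use a fast one-hot cross-product
# (equivalent to ungapped column comparison); mixed widths fall back to
# pairwise global alignment with matches normalized by the shorter length.
.pairwise_identity_matrix <- function(copies) {
  n <- length(copies)
  w <- Biostrings::width(copies)
  if (length(unique(w)) == 1L) {
    m <- as.matrix(copies)
    A <- matrix(0, n, 4L * w[1])
    for (b in seq_along(.BASES)) {
      A[, ((b - 1L) * w[1] + 1L):(b * w[1])] <- m == .BASES[b]
    }
    idm <- tcrossprod(A) / w[1]
    diag(idm) <- 1
    return(idm)
  }
  sm <- .nuc_matrix(2, -3)
  idm <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      copies[(i + 1L):n], copies[[i]], type = "global",
      substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
    ids <- Biostrings::nmatch(aln) / pmin(w[(i + 1L):n], w[i])
    idm[i, (i + 1L):n] <- ids
    idm[(i + 1L):n, i] <- ids
  }
  idm
}

.pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    return(mean(.chars(a) == .chars(b)))
  }
  sm <- .nuc_matrix(2, -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# Column-majority consensus of copies projected onto the majority length.
.majority_consensus <- function(copies) {
  w <- Biostrings::width(copies)
  target <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
  same <- copies[w == target]
  m <- as.matrix(same)
  cons <- apply(m, 2L, function(col) {
    cnt <- tabulate(match(col, .BASES), nbins = 4L)
    .BASES[which.max(cnt)]
  })
  paste(cons, collapse = "")
}

#' Position frequency matrix and information content of phased monomers
#'
#' Copies must be phased to a common coordinate system. Copies whose length
#' equals the majority length are stacked directly; other copies are
#' projected onto the consensus by pairwise alignment with insertions
#' relative to the consensus dropped. Information content per column is
#' `2 - H(column)` bits with no small-sample correction.
#'
#' @param monomers `monomer_set` or `DNAStringSet` of phased copies.
#' @return List of class `conservation_profile`: `freq` (4 x L matrix,
#'   columns sum to 1), `information` (bits per position), `consensus`,
#'   `n_copies`.
#' @export
conservation_profile <- function(monomers) {
  phased <- !inherits(monomers, "monomer_set") || isTRUE(monomers$phased)
  copies <- if (inherits(monomers, "monomer_set")) monomers$copies else monomers
  if (is.character(copies)) copies <- Biostrings::DNAStringSet(copies)
  if (!phased) stop("monomer copies must be phased")
  if (length(copies) == 0L) stop("no copies")
  w <- Biostrings::width(copies)
  target <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
  cons <- .majority_consensus(copies)
  proj <- lapply(seq_along(copies), function(i) {
    s <- as.character(copies[[i]])
    if (nchar(s) == target) return(s)
    .project_onto(s, cons)
  })
  m <- do.call(rbind, lapply(proj, .chars))
  counts <- apply(m, 2L, function(col) tabulate(match(col, .BASES), nbins = 4L))
  rownames(counts) <- .BASES
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
  H <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, information = 2 - H, consensus = cons,
                 n_copies = length(copies)),
            class = "conservation_profile")
}

# Globally align a copy to the consensus and return the copy's bases in
# consensus coordinates (deletions become N? no: gaps vs consensus keep the
# consensus position with a gap character excluded from counts).
.project_onto <- function(s, cons) {
  sm <- .nuc_matrix(2, -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(cons), type = "global",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
  pal <- .chars(as.character(Biostrings::alignedPattern(aln)))
  sal <- .chars(as.character(Biostrings::alignedSubject(aln)))
  keep <- sal != "-"
  out <- pal[keep]
  out[out == "-"] <- "N"
  paste(out, collapse = "")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile over", ncol(x$freq), "positions,",
      x$n_copies, "copies; mean information",
      round(mean(x$information), 3), "bits\n")
  invisible(x)
}

#' Infer a satellite monomer consensus from raw reads
#'
#' Runs [detect_tandem()] on every read, takes the modal period across
#' tandem-positive reads, picks the read call with the highest adjacent-unit
#' identity at that period as the phase anchor, rotates every other read's
#' monomer onto the anchor's phase, and returns the column-majority
#' consensus.
#'
#' @param reads Read set.
#' @param min_period,min_identity [detect_tandem()] parameters.
#' @return List of class `monomer_inference`: `period` (modal period),
#'   `consensus`, `n_tandem_reads`, `periods` (per-read calls).
#' @export
infer_monomer <- function(reads, min_period = 100L, min_identity = 0.7) {
  reads <- .as_readset(reads)
  calls <- list()
  for (i in seq_along(reads)) {
    td <- detect_tandem(as.character(reads[[i]]), min_period, min_identity)
    if (!is.null(td)) calls[[length(calls) + 1L]] <- c(i, td$period)
  }
  if (!length(calls)) stop("no tandem-positive reads")
  cm <- do.call(rbind, calls)
  periods <- cm[, 2]
  P <- as.integer(names(sort(table(periods), decreasing = TRUE))[1])
  sel <- cm[periods == P, 1]
  monos <- character(0)
  anchors <- numeric(0)
  for (i in sel) {
    td <- detect_tandem(as.character(reads[[i]]), min_period, min_identity)
    if (td$period == P) {
      monos <- c(monos, td$monomer)
      anchors <- c(anchors, td$adjacent_identity)
    }
  }
  anchor <- monos[which.max(anchors)]
  rotated <- vapply(monos, function(m) .best_rotation(m, anchor), character(1))
  mm <- do.call(rbind, lapply(rotated, .chars))
  cons <- apply(mm, 2L, function(col) {
    cnt <- tabulate(match(col, .BASES), nbins = 4L)
    .BASES[which.max(cnt)]
  })
  structure(list(period = P, consensus = paste(cons, collapse = ""),
                 n_tandem_reads = nrow(cm), periods = periods),
            class = "monomer_inference")
}

# Best cyclic rotation (and strand) of monomer m against an anchor of the
# same length, by ungapped identity.
.best_rotation <- function(m, anchor) {
  L <- nchar(m)
  a <- .chars(anchor)
  best <- m
  best_id <- -1
  for (cand in c(m, .revcomp_chr(m))) {
    dd <- .chars(strrep(cand, 2L))
    for (r in 0:(L - 1L)) {
      rot <- dd[(r + 1L):(r + L)]
      id <- mean(rot == a)
      if (id > best_id) {
        best_id <- id
        best <- paste(rot, collapse = "")
      }
    }
  }
  best
}

#' @export
print.monomer_inference <- function(x, ...) {
  cat("Inferred satellite monomer: period", x$period, "nt from",
      x$n_tandem_reads, "tandem-positive reads\n")
  invisible(x)
}

#' In silico restriction digest of a satellite array
#'
#' Builds `flank_left + monomer x n_units + flank_right`, cuts after every
#' occurrence of the recognition site (for non-palindromic sites the minus
#' strand is searched too, cutting before the forward-strand footprint),
#' and returns the fragment lengths. With exactly one site per monomer the
#' interior fragments all equal the monomer length — the ladder-like
#' pattern tandem satellites produce on a Southern blot. A `blocked_fraction`
#' removes that fraction of cut sites uniformly at random (seeded), a
#' minimal model of methylation-blocked enzymes.
#'
#' @param monomer Monomer sequence.
#' @param n_units Number of tandem units (>= 1).
#' @param flank_left,flank_right Flanking sequences (may be `""`).
#' @param site Recognition sequence (length >= 4).
#' @param blocked_fraction Fraction of cut sites blocked (default 0).
#' @param seed Seed for the blocking draw.
#' @return Integer vector of fragment lengths (sums to the input length).
#' @examples
#' digest_ladder("ACGT", 1, "", "", "ACGT") # degenerate toy
#' @export
digest_ladder <- function(monomer, n_units, flank_left = "",
                          flank_right = "", site, blocked_fraction = 0,
                          seed = 1L) {
  stopifnot(n_units >= 1, nchar(site) >= 4)
  mono <- .as_seq_string(monomer)
  fl <- if (nchar(flank_left)) .as_seq_string(flank_left) else ""
  fr <- if (nchar(flank_right)) .as_seq_string(flank_right) else ""
  construct <- paste0(fl, strrep(mono, n_units), fr)
  total <- nchar(construct)
  d <- Biostrings::DNAString(construct)
  pat <- Biostrings::DNAString(.as_seq_string(site))
  fwd <- Biostrings::matchPattern(pat, d)
  cuts <- Biostrings::end(fwd)
  rcp <- Biostrings::reverseComplement(pat)
  if (as.character(rcp) != as.character(pat)) {
    rev <- Biostrings::matchPattern(rcp, d)
    cuts <- c(cuts, Biostrings::start(rev) - 1L)
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < total]))
  if (blocked_fraction > 0 && length(cuts)) {
    n_block <- round(blocked_fraction * length(cuts))
    if (n_block > 0) {
      drop <- with_seed(seed, sample.int(length(cuts), n_block))
      cuts <- cuts[-drop]
    }
  }
  diff(c(0L, cuts, total))
}
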