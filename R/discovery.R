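# De novo repeat discovery from unassembled reads: frequent l-mer seeds,
# greedy fit-preferred consensus extension, length / copy-number / complexity
# filters, relaxed overlap assembly of fragmented candidates, and greedy
# identity clustering into a representative library.

#' Parameters for de novo repeat discovery
#'
#' @param l Seed l-mer length; `NULL` chooses `ceil(log4(total read nt)) + 1`
#'   at run time (capped to `[10, 14]`), the usual genome-size-scaled seed
#'   heuristic.
#' @param min_seed_freq Minimum canonical l-mer count for a seed (default 4).
#' @param min_len Minimum candidate length after filtering (default 100 nt).
#' @param min_copies Copy filter: candidates must be present in **more than**
#'   this many copies (strict inequality; default 10).
#' @param entropy_min Low-complexity filter: minimum dinucleotide Shannon
#'   entropy in bits (default 1.5; a homopolymer scores 0, an AC microsatellite
#'   1, random sequence near 4).
#' @param c_penalty Fit-preferred extension tolerance: an occurrence is
#'   dropped once its running agreement score falls more than `c_penalty`
#'   below its own maximum (default 3).
#' @param col_cost Per-column extension cost subtracted from each position's
#'   net agreement gain (default 1), so that extension into sequence where
#'   agreement is only at chance level scores downhill.
#' @param stop_window X-drop: extension on a side stops once the cumulative
#'   (cost-adjusted) gain falls `stop_window` below its running maximum
#'   (default 20); the consensus is trimmed back to the maximum.
#' @param max_occ Maximum occurrences tracked per seed (default 100).
#' @param min_overlap,min_overlap_identity,min_overlap_score Overlap-assembly
#'   admissibility: overlap of at least `min_overlap` nt (default 30) at
#'   `min_overlap_identity` (default 0.80) scoring at least
#'   `min_overlap_score` (default 500) under the assembly scoring scheme
#'   (match +2, mismatch -5, gap -6/-1).
#' @param cluster_identity Library clustering identity over the shorter
#'   sequence (default 0.80).
#' @param max_candidates Cap on raw candidates per run (default 1000).
#' @return A `discovery_params` list.
#' @export
discovery_params <- function(l = NULL, min_seed_freq = 4L, min_len = 100L,
                             min_copies = 10L, entropy_min = 1.5,
                             c_penalty = 3, col_cost = 1, stop_window = 20L,
                             max_occ = 100L, min_overlap = 30L,
                             min_overlap_identity = 0.80,
                             min_overlap_score = 500,
                             cluster_identity = 0.80,
                             max_candidates = 1000L) {
  p <- list(l = l, min_seed_freq = min_seed_freq, min_len = min_len,
            min_copies = min_copies, entropy_min = entropy_min,
            c_penalty = c_penalty, col_cost = col_cost,
            stop_window = stop_window, max_occ = max_occ,
            min_overlap = min_overlap,
            min_overlap_identity = min_overlap_identity,
            min_overlap_score = min_overlap_score,
            cluster_identity = cluster_identity,
            max_candidates = max_candidates)
  stopifnot(is.null(p$l) || p$l >= 2, p$min_len >= 1, p$min_seed_freq >= 1)
  structure(p, class = "discovery_params")
}

.default_l <- function(total_nt) {
  min(14L, max(10L, as.integer(ceiling(log(max(total_nt, 2), 4))) + 1L))
}

#' Count canonical l-mers in a read set
#'
#' Every l-mer window is reduced to its canonical form (the lexicographic
#' minimum of the l-mer and its reverse complement) and counted. Windows
#' containing N and reads shorter than `l` contribute nothing.
#'
#' @param reads `DNAStringSet` or character vector.
#' @param l Word length (2-15).
#' @return Named integer vector of counts, sorted by decreasing count.
#' @examples
#' count_lmers(c("ACGTACGT"), 4)
#' @export
count_lmers <- function(reads, l) {
  reads <- .as_readset(reads)
  idx <- .lmer_index(reads, l)
  if (is.null(idx) || nrow(idx) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  vals <- sort(idx$canon)
  r <- rle(vals)
  counts <- stats::setNames(as.integer(r$lengths), .lmer_decode(r$values, l))
  sort(counts, decreasing = TRUE)
}

# ---- greedy fit-preferred extension ----

# One-sided extension over a matrix of flanking characters (rows =
# occurrences, columns = distance from the seed edge, NA past read ends).
# Returns consensus characters, per-occurrence aligned extents and
# match/total tallies.
.extend_side <- function(M, params) {
  n <- nrow(M)
  maxlen <- ncol(M)
  active <- rep(TRUE, n)
  score <- numeric(n)
  best <- numeric(n)
  extent <- integer(n)
  matches <- integer(n)
  total <- integer(n)
  cons <- character(0)
  cum <- 0
  best_cum <- 0
  last_good <- 0L
  t <- 0L
  while (t < maxlen) {
    t <- t + 1L
    avail <- active & !is.na(M[, t])
    # occurrences whose read ends here stop contributing
    active[active & is.na(M[, t])] <- FALSE
    # a lone surviving occurrence is no longer repeat evidence
    if (sum(avail) < 2L) break
    bases <- M[avail, t]
    cnt <- tabulate(match(bases, .BASES), nbins = 4L)
    b <- .BASES[which.max(cnt)]
    m <- bases == b
    cons[t] <- b
    score[avail] <- score[avail] + ifelse(m, 1, -1)
    matches[avail] <- matches[avail] + as.integer(m)
    total[avail] <- total[avail] + 1L
    extent[avail] <- t
    best <- pmax(best, score)
    drop <- avail & (score < best - params$c_penalty)
    active[drop] <- FALSE
    # cumulative cost-adjusted gain; trim to its maximum (X-drop stop)
    cum <- cum + (sum(m) - sum(!m)) - params$col_cost
    if (cum > best_cum) {
      best_cum <- cum
      last_good <- t
    } else if (cum <= best_cum - params$stop_window) {
      break
    }
  }
  list(cons = if (last_good > 0L) cons[seq_len(last_good)] else character(0),
       extent = pmin(extent, last_good), matches = matches, total = total)
}

# Core extension over explicit occurrences. `occ` is a data.frame with
# columns read (index), pos (1-based, forward coords of the seed start) and
# strand. `reads_chr` is a character vector of read sequences.
.extend_occurrences <- function(seed, reads_chr, occ, params) {
  l <- nchar(seed)
  n <- nrow(occ)
  widths <- nchar(reads_chr[occ$read])
  # orient each occurrence so the seed reads forward
  left_list <- vector("list", n)
  right_list <- vector("list", n)
  for (k in seq_len(n)) {
    s <- reads_chr[occ$read[k]]
    if (occ$strand[k] == "-") {
      s <- .revcomp_chr(s)
      p <- nchar(s) - (occ$pos[k] + l - 1L) + 1L
    } else {
      p <- occ$pos[k]
    }
    ch <- .chars(s)
    left_list[[k]] <- rev(ch[seq_len(p - 1L)])
    right_list[[k]] <- ch[seq(p + l, length.out = length(ch) - (p + l - 1L))]
  }
  pad <- function(lst) {
    mx <- max(1L, max(vapply(lst, length, integer(1))))
    do.call(rbind, lapply(lst, function(v) c(v, rep(NA_character_, mx - length(v)))))
  }
  L <- .extend_side(pad(left_list), params)
  R <- .extend_side(pad(right_list), params)
  consensus <- paste(c(rev(L$cons), .chars(seed), R$cons), collapse = "")
  mean_id <- mean((L$matches + R$matches + l) / (L$total + R$total + l))
  # aligned span per occurrence in forward read coordinates (0-based half-open)
  sp_start <- integer(n); sp_end <- integer(n)
  for (k in seq_len(n)) {
    w <- widths[k]
    if (occ$strand[k] == "-") {
      p <- w - (occ$pos[k] + l - 1L) + 1L
      a <- p - L$extent[k]; b <- p + l - 1L + R$extent[k]
      sp_start[k] <- w - b; sp_end[k] <- w - a + 1L
    } else {
      sp_start[k] <- occ$pos[k] - L$extent[k] - 1L
      sp_end[k] <- occ$pos[k] + l - 1L + R$extent[k]
    }
  }
  spans <- data.frame(read = occ$read, start = sp_start, end = sp_end,
                      strand = occ$strand)
  cand <- data.frame(id = seed, consensus = consensus, length = nchar(consensus),
                     n_occ = n, seed = seed, mean_identity = mean_id,
                     stringsAsFactors = FALSE)
  attr(cand, "occurrences") <- spans
  cand
}

#' Extend a seed l-mer into a repeat consensus
#'
#' Recruits every exact occurrence of the seed (both strands), then grows a
#' consensus one base at a time on each side, choosing the base with the
#' highest agreement among occurrences still aligned. An occurrence is
#' dropped once its running agreement score (+1 match / -1 mismatch) falls
#' more than `c_penalty` below its own maximum (fit-preferred extension).
#' Each extension column's net agreement gain, minus `col_cost`, accumulates
#' into a running total; extension on a side stops once that total drops
#' `stop_window` below its maximum, and the consensus is trimmed back to the
#' maximum (the boundary where overall agreement peaked).
#'
#' @param seed Seed l-mer (character).
#' @param reads Read set.
#' @param params [discovery_params()].
#' @return One-row candidate data.frame (`id`, `consensus`, `length`,
#'   `n_occ`, `seed`, `mean_identity`) with the per-occurrence aligned spans
#'   as attribute `"occurrences"`.
#' @export
extend_seed <- function(seed, reads, params = discovery_params()) {
  reads <- .as_readset(reads)
  seed <- toupper(seed)
  reads_chr <- as.character(reads)
  fwd <- Biostrings::vmatchPattern(seed, reads)
  rev <- Biostrings::vmatchPattern(.revcomp_chr(seed), reads)
  occ <- rbind(
    do.call(rbind, lapply(seq_along(fwd), function(i) {
      st <- Biostrings::start(fwd[[i]])
      if (length(st)) data.frame(read = i, pos = st, strand = "+") else NULL
    })),
    do.call(rbind, lapply(seq_along(rev), function(i) {
      st <- Biostrings::start(rev[[i]])
      if (length(st)) data.frame(read = i, pos = st, strand = "-") else NULL
    }))
  )
  if (is.null(occ) || nrow(occ) == 0L) {
    stop("seed '", seed, "' does not occur in the reads")
  }
  occ <- occ[order(occ$read, occ$pos), , drop = FALSE]
  if (nrow(occ) > params$max_occ) occ <- occ[seq_len(params$max_occ), ]
  .extend_occurrences(seed, reads_chr, occ, params)
}

# Count, per candidate, the reads carrying an admissible local hit
# (identity >= min_identity over >= min_hit_len nt, either strand).
# Candidate-read pairs are prefiltered by at least two distinct shared
# canonical 11-mers (the two-hit seeding rule), and counting a candidate
# stops as soon as its count exceeds `min_copies` — the only question the
# copy filter asks.
.recount_support <- function(reads, sq, min_copies, min_identity = 0.7,
                             min_hit_len = 30L, seed_l = 11L, chunk = 200L) {
  cnt <- stats::setNames(rep(0L, length(sq)), names(sq))
  if (!length(sq) || !length(reads)) return(cnt)
  ent_chr <- as.character(sq)
  seed_l <- min(seed_l, min(nchar(ent_chr)), max(Biostrings::width(reads)))
  eidx <- .lmer_index(Biostrings::DNAStringSet(ent_chr), seed_l)
  ridx <- .lmer_index(reads, seed_l)
  if (is.null(eidx) || is.null(ridx)) return(cnt)
  ep <- unique(eidx[, c("read", "canon")]); names(ep) <- c("entry", "canon")
  rp <- unique(ridx[, c("read", "canon")])
  shared <- merge(rp, ep, by = "canon")[, c("read", "entry")]
  key <- paste(shared$read, shared$entry)
  multi <- names(which(table(key) >= 2L))
  pairs <- unique(shared[key %in% multi, , drop = FALSE])
  if (nrow(pairs) == 0L) return(cnt)
  read_chr <- as.character(reads)
  for (e in sort(unique(pairs$entry))) {
    rids <- pairs$read[pairs$entry == e]
    got <- 0L
    for (from in seq(1L, length(rids), by = chunk)) {
      ids <- rids[from:min(from + chunk - 1L, length(rids))]
      pats_f <- Biostrings::DNAStringSet(read_chr[ids])
      pats_r <- Biostrings::reverseComplement(pats_f)
      hf <- .align_set(pats_f, ent_chr[e])
      hr <- .align_set(pats_r, ent_chr[e])
      okf <- (hf$p_end - hf$p_start + 1L) >= min_hit_len &
        hf$identity >= min_identity
      okr <- (hr$p_end - hr$p_start + 1L) >= min_hit_len &
        hr$identity >= min_identity
      got <- got + sum(okf | okr)
      if (got > min_copies) break
    }
    cnt[e] <- got
  }
  cnt
}

#' Filter raw candidates by length, copy number and complexity
#'
#' Retains candidates with length `>= min_len`, occurrence count strictly
#' greater than `min_copies`, and dinucleotide entropy `>= entropy_min`.
#' When `reads` is supplied, candidates that pass the length and entropy
#' predicates but whose exact seed-match count falls at or below the copy
#' threshold are given a second chance: their support is recounted as the
#' number of reads carrying an admissible local hit of the candidate
#' (identity >= 0.7 over >= 30 nt, both strands) — the copy count a masking
#' pass over the read sample attributes to the candidate — which is more
#' sensitive than the exact seed-match count when copies are diverged.
#'
#' The recount pairs each candidate with reads sharing at least two
#' distinct 11-mers (the two-hit seeding rule) and stops counting a
#' candidate once the threshold is exceeded.
#'
#' @param candidates Candidate data.frame (rows as from [extend_seed()]).
#' @param params [discovery_params()].
#' @param reads Optional read set for recounting candidate support.
#' @return Filtered candidate data.frame (with `n_occ` recounted when
#'   `reads` is given).
#' @export
filter_candidates <- function(candidates, params = discovery_params(),
                              reads = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  if (!is.null(reads)) {
    reads <- .as_readset(reads)
    # recounting is an alignment pass over the reads; restrict it to
    # candidates that already pass the cheap predicates and would otherwise
    # be rejected on their exact seed-match count
    ent0 <- vapply(candidates$consensus,
                   function(s) shannon_entropy(s, 2L), numeric(1))
    pre <- nchar(candidates$consensus) >= params$min_len &
      ent0 >= params$entropy_min &
      candidates$n_occ <= params$min_copies
    if (any(pre)) {
      sq <- Biostrings::DNAStringSet(candidates$consensus[pre])
      names(sq) <- candidates$id[pre]
      cnt <- .recount_support(reads, sq, min_copies = params$min_copies)
      candidates$n_occ[pre] <- pmax(candidates$n_occ[pre],
                                    as.integer(cnt[candidates$id[pre]]))
    }
  }
  ent <- vapply(candidates$consensus,
                function(s) shannon_entropy(s, 2L), numeric(1))
  keep <- nchar(candidates$consensus) >= params$min_len &
    candidates$n_occ > params$min_copies &
    ent >= params$entropy_min
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- overlap assembly ----

.CAP_SCORING <- list(match = 2, mismatch = -5, gap_open = 6, gap_extend = 1)

# Best ends-free overlap alignment between two sequences, in the given
# orientation. Returns NULL or a list describing the overlap.
.overlap_aln <- function(a, b) {
  sm <- .nuc_matrix(.CAP_SCORING$match, .CAP_SCORING$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = sm, gapOpening = .CAP_SCORING$gap_open,
    gapExtension = .CAP_SCORING$gap_extend)
  nmatch <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  ncol <- Biostrings::nchar(aln)
  list(score = Biostrings::score(aln),
       overlap_len = ncol,
       identity = if (nmatch + nmis > 0) nmatch / (nmatch + nmis) else 0,
       ps = Biostrings::start(Biostrings::pattern(aln)),
       pe = Biostrings::end(Biostrings::pattern(aln)),
       ss = Biostrings::start(Biostrings::subject(aln)),
       se = Biostrings::end(Biostrings::subject(aln)),
       pal = as.character(Biostrings::alignedPattern(aln)),
       sal = as.character(Biostrings::alignedSubject(aln)))
}

# Merge two sequences given their overlap alignment: flanks come from
# whichever sequence extends further; overlap columns take the first
# sequence's base unless it is a gap.
.merge_overlap <- function(a, b, ov) {
  pa <- .chars(ov$pal); sa <- .chars(ov$sal)
  mid <- ifelse(pa == "-", sa, pa)
  left <- if (ov$ps - 1L >= ov$ss - 1L) substr(a, 1, ov$ps - 1L) else substr(b, 1, ov$ss - 1L)
  ra <- nchar(a) - ov$pe; rb <- nchar(b) - ov$se
  right <- if (ra >= rb) substr(a, ov$pe + 1L, nchar(a)) else substr(b, ov$se + 1L, nchar(b))
  paste0(left, paste(mid, collapse = ""), right)
}

#' Assemble candidates by greedy overlap merging
#'
#' Repeatedly merges the candidate pair with the highest-scoring ends-free
#' overlap satisfying `min_overlap` columns, `min_overlap_identity` and
#' `min_overlap_score` under the assembly scoring scheme (match +2,
#' mismatch -5, gap -6/-1), considering both orientations. The merged
#' consensus takes flanks from whichever sequence extends further and the
#' first sequence's base across the overlap. Terminates when no admissible
#' overlap remains.
#'
#' @param candidates Candidate data.frame.
#' @param params [discovery_params()].
#' @return Candidate data.frame of merged consensi (`n_occ` summed over
#'   merged members, `id`s joined with `+`).
#' @export
assemble_candidates <- function(candidates, params = discovery_params()) {
  n0 <- nrow(candidates)
  if (n0 <= 1L) return(candidates)
  seqs <- candidates$consensus
  ids <- candidates$id
  occs <- candidates$n_occ
  seeds <- if (!is.null(candidates$seed)) candidates$seed else
    rep(NA_character_, n0)
  mid <- if (!is.null(candidates$mean_identity)) candidates$mean_identity else
    rep(NA_real_, n0)
  alive <- rep(TRUE, length(seqs))
  # candidate pairs prefiltered by a shared canonical 12-mer
  admissible_pairs <- function() {
    idxset <- which(alive)
    if (length(idxset) < 2L) return(NULL)
    km <- .lmer_index(Biostrings::DNAStringSet(seqs[idxset]),
                      min(12L, min(nchar(seqs[idxset]))))
    if (is.null(km)) return(NULL)
    km$orig <- idxset[km$read]
    sp <- split(km$orig, km$canon)
    sp <- sp[vapply(sp, function(v) length(unique(v)) > 1L, logical(1))]
    if (!length(sp)) return(NULL)
    prs <- unique(do.call(rbind, lapply(sp, function(v) {
      u <- sort(unique(v))
      t(utils::combn(u, 2L))
    })))
    prs
  }
  # overlap alignments are cached across merge rounds; only pairs touching
  # a freshly merged sequence need re-alignment
  ov_cache <- new.env(parent = emptyenv())
  repeat {
    prs <- admissible_pairs()
    if (is.null(prs) || nrow(prs) == 0L) break
    best <- NULL
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1]; j <- prs[r, 2]
      for (orient in c("+", "-")) {
        key <- paste(i, j, orient, sep = "|")
        ov <- if (exists(key, envir = ov_cache, inherits = FALSE)) {
          get(key, envir = ov_cache, inherits = FALSE)
        } else {
          bj0 <- if (orient == "+") seqs[j] else .revcomp_chr(seqs[j])
          o <- .overlap_aln(seqs[i], bj0)
          assign(key, o, envir = ov_cache)
          o
        }
        if (ov$overlap_len >= params$min_overlap &&
            ov$identity >= params$min_overlap_identity &&
            ov$score >= params$min_overlap_score &&
            (is.null(best) || ov$score > best$ov$score)) {
          bj <- if (orient == "+") seqs[j] else .revcomp_chr(seqs[j])
          best <- list(i = i, j = j, orient = orient, ov = ov, bj = bj)
        }
      }
    }
    if (is.null(best)) break
    merged <- .merge_overlap(seqs[best$i], best$bj, best$ov)
    seqs[best$i] <- merged
    ids[best$i] <- paste(ids[best$i], ids[best$j], sep = "+")
    w <- c(occs[best$i], occs[best$j])
    mid[best$i] <- sum(mid[c(best$i, best$j)] * w) / sum(w)
    occs[best$i] <- sum(w)
    alive[best$j] <- FALSE
    stale <- grep(sprintf("(^%d\\|)|(\\|%d\\|)", best$i, best$i),
                  ls(envir = ov_cache), value = TRUE)
    if (length(stale)) rm(list = stale, envir = ov_cache)
  }
  out <- data.frame(id = ids[alive], consensus = seqs[alive],
                    length = nchar(seqs[alive]), n_occ = occs[alive],
                    seed = seeds[alive], mean_identity = mid[alive],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster a candidate library at an identity threshold
#'
#' Greedy incremental clustering in the cd-hit style: sequences are sorted by
#' decreasing length and each joins the first existing representative with
#' identity at least `cluster_identity` over the shorter sequence's length
#' (both strands considered; identity is matched bases in the best local
#' alignment divided by the shorter length), otherwise it founds a new
#' cluster.
#'
#' @param candidates Candidate data.frame or `DNAStringSet`/character vector.
#' @param cluster_identity Identity threshold (default 0.80).
#' @return List with `representatives` (candidate data.frame) and
#'   `membership` (data.frame `member`, `representative`).
#' @export
cluster_library <- function(candidates, cluster_identity = 0.80) {
  if (!is.data.frame(candidates)) {
    sq <- as.character(candidates)
    ids <- names(sq)
    if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(sq))
    candidates <- data.frame(id = ids, consensus = unname(sq),
                             length = nchar(sq), n_occ = NA_integer_,
                             seed = NA_character_, mean_identity = NA_real_,
                             stringsAsFactors = FALSE)
  }
  n <- nrow(candidates)
  if (n == 0L) {
    return(list(representatives = candidates,
                membership = data.frame(member = character(0),
                                        representative = character(0))))
  }
  ord <- order(nchar(candidates$consensus), decreasing = TRUE)
  cand <- candidates[ord, , drop = FALSE]
  sm <- .nuc_matrix(2, -3)
  reps <- integer(0)
  assign_to <- integer(n)
  for (k in seq_len(n)) {
    s <- cand$consensus[k]
    hit <- 0L
    if (length(reps)) {
      pats <- Biostrings::DNAStringSet(c(s, .revcomp_chr(s)))
      for (ri in reps) {
        aln <- Biostrings::pairwiseAlignment(
          pats, Biostrings::DNAString(cand$consensus[ri]), type = "local",
          substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
        idmax <- max(Biostrings::nmatch(aln)) /
          min(nchar(s), nchar(cand$consensus[ri]))
        if (idmax >= cluster_identity) { hit <- ri; break }
      }
    }
    if (hit > 0L) {
      assign_to[k] <- hit
    } else {
      reps <- c(reps, k)
      assign_to[k] <- k
    }
  }
  representatives <- cand[reps, , drop = FALSE]
  rownames(representatives) <- NULL
  membership <- data.frame(member = cand$id,
                           representative = cand$id[assign_to])
  list(representatives = representatives, membership = membership)
}

#' Discover repeats de novo from a read set
#'
#' Full discovery pipeline: canonical l-mer counting, seed selection in
#' decreasing frequency order (read positions consumed by earlier candidates
#' are not re-seeded, and a seed is extended only while its unconsumed
#' occurrence count still meets `min_seed_freq`), greedy fit-preferred
#' consensus extension, the
#' length / copy-number / low-complexity filters, relaxed overlap assembly
#' and identity clustering.
#'
#' @param reads Read set (`DNAStringSet` or character vector).
#' @param params [discovery_params()].
#' @return An object of class `repeat_library`: list with `library`
#'   (representative candidate data.frame), `sequences` (`DNAStringSet`),
#'   `membership`, `raw_candidates`, `params`, `l`.
#' @export
discover_repeats <- function(reads, params = discovery_params()) {
  reads <- .as_readset(reads)
  total_nt <- sum(Biostrings::width(reads))
  l <- if (is.null(params$l)) .default_l(total_nt) else as.integer(params$l)
  reads_chr <- as.character(reads)
  idx <- .lmer_index(reads, l)
  if (is.null(idx) || nrow(idx) == 0L) {
    stop("no l-mers of length ", l, " in the reads")
  }
  vals <- sort(idx$canon)
  r <- rle(vals)
  seeds <- r$values[r$lengths >= params$min_seed_freq]
  seed_counts <- r$lengths[r$lengths >= params$min_seed_freq]
  ord <- order(seed_counts, seeds, decreasing = TRUE)
  seeds <- seeds[ord]
  if (!length(seeds)) {
    stop("no seed l-mer reaches the frequency threshold ",
         params$min_seed_freq)
  }
  sel <- idx$canon %in% seeds
  occ_by_seed <- split(which(sel), idx$canon[sel])
  # global used-base mask across concatenated reads
  widths <- nchar(reads_chr)
  offset <- c(0L, cumsum(widths))[seq_along(widths)]
  used <- logical(sum(widths))
  cands <- list()
  for (sv in seeds) {
    rows <- occ_by_seed[[as.character(sv)]]
    occ <- idx[rows, , drop = FALSE]
    seed_pos <- offset[occ$read] + occ$pos
    # a seed's effective frequency is its unconsumed occurrence count; it
    # must still meet the seed frequency threshold to found a candidate
    fresh <- !used[seed_pos]
    if (sum(fresh) < max(2L, params$min_seed_freq)) next
    occ <- occ[fresh, , drop = FALSE]
    if (nrow(occ) > params$max_occ) occ <- occ[seq_len(params$max_occ), ]
    seed_chr <- .lmer_decode(sv, l)
    cand <- .extend_occurrences(seed_chr, reads_chr,
                                data.frame(read = occ$read, pos = occ$pos,
                                           strand = occ$strand),
                                params)
    spans <- attr(cand, "occurrences")
    for (q in seq_len(nrow(spans))) {
      used[(offset[spans$read[q]] + spans$start[q] + 1L):
             (offset[spans$read[q]] + spans$end[q])] <- TRUE
    }
    # consume every exact l-mer match of the accepted consensus, so the
    # same family is not re-seeded from copies the extension did not use
    cidx <- .lmer_index(Biostrings::DNAStringSet(cand$consensus), l)
    if (!is.null(cidx)) {
      hitp <- which(idx$canon %in% unique(cidx$canon))
      if (length(hitp)) {
        p0 <- offset[idx$read[hitp]] + idx$pos[hitp]
        used[rep(p0, each = l) + rep.int(0:(l - 1L), length(p0))] <- TRUE
      }
    }
    cands[[length(cands) + 1L]] <- cand
    if (length(cands) >= params$max_candidates) break
  }
  raw <- do.call(rbind, cands)
  raw$id <- sprintf("cand_%04d", seq_len(nrow(raw)))
  filtered <- filter_candidates(raw, params, reads = reads)
  assembled <- assemble_candidates(filtered, params)
  clustered <- cluster_library(assembled, params$cluster_identity)
  lib <- clustered$representatives
  if (nrow(lib)) lib$id <- sprintf("rep_%04d", seq_len(nrow(lib)))
  sq <- Biostrings::DNAStringSet(lib$consensus)
  names(sq) <- lib$id
  structure(list(library = lib, sequences = sq,
                 membership = clustered$membership,
                 raw_candidates = raw, params = params, l = l),
            class = "repeat_library")
}

#' @export
print.repeat_library <- function(x, ...) {
  cat("De novo repeat library: ", nrow(x$library), " representatives (",
      nrow(x$raw_candidates), " raw candidates, seed l = ", x$l, ")\n",
      sep = "")
  if (nrow(x$library)) {
    cat("  lengths ", min(x$library$length), "-", max(x$library$length),
        " nt, median copies ", stats::median(x$library$n_occ), "\n", sep = "")
  }
  invisible(x)
}
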