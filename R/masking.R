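# Masking-based abundance estimation: local-alignment hit search of a repeat
# library against a read sample, exclusive attribution of overlapping hits,
# per-class masked fractions, copy-number extrapolation and reciprocal
# library-completeness percentages.

# Coerce a library argument to a named DNAStringSet with a class vector and
# tandem flags/periods (from mcols when present).
.as_library <- function(library, classes = NULL, tandem = NULL) {
  if (inherits(library, "repeat_library")) library <- library$sequences
  if (inherits(library, "planted_genome")) library <- library$consensi
  if (is.character(library)) library <- Biostrings::DNAStringSet(toupper(library))
  stopifnot(methods::is(library, "DNAStringSet"), length(library) > 0L)
  if (is.null(names(library))) {
    names(library) <- sprintf("lib_%04d", seq_along(library))
  }
  mc <- S4Vectors::mcols(library)
  if (is.null(classes)) {
    classes <- if (!is.null(mc) && "class" %in% colnames(mc)) {
      as.character(mc$class)
    } else {
      rep("repeat", length(library))
    }
  }
  if (length(classes) == 1L) classes <- rep(classes, length(library))
  if (is.null(tandem)) {
    tandem <- if (!is.null(mc) && "tandem" %in% colnames(mc)) {
      as.logical(mc$tandem)
    } else {
      rep(FALSE, length(library))
    }
  }
  list(seqs = library, classes = classes, tandem = tandem)
}

# Vectorized hit search of library entries against reads. Tandem entries are
# tiled head-to-tail beyond the longest read so one local hit can span a
# whole array region. Read/entry pairs are prefiltered by at least two
# distinct shared canonical seed k-mers and aligned seed-anchored (only
# against the entry window their shared words span, padded by one read
# length each side); accepted hits trigger a re-search of the remaining
# read segments so multiple hits per read/entry pair are found. Returns a
# data.frame of admissible hits with 0-based half-open read intervals.
.hit_search <- function(reads, seqs, classes, tandem,
                        min_identity = 0.7, min_hit_len = 30L,
                        seed_l = 11L, max_rounds = 6L) {
  n_reads <- length(reads)
  if (n_reads == 0L) {
    return(data.frame(read = character(0), start = integer(0),
                      end = integer(0), entry = character(0),
                      class = character(0), identity = numeric(0),
                      score = numeric(0), strand = character(0)))
  }
  max_w <- max(Biostrings::width(reads))
  ent_chr <- as.character(seqs)
  for (i in which(tandem)) {
    L <- nchar(ent_chr[i])
    reps <- max(2L, ceiling((1.2 * max_w + 2 * L) / L))
    ent_chr[i] <- strrep(ent_chr[i], reps)
  }
  seed_l <- min(seed_l, min(nchar(ent_chr)), max_w)
  eidx <- .lmer_index(Biostrings::DNAStringSet(ent_chr), seed_l)
  ridx <- .lmer_index(reads, seed_l)
  if (is.null(eidx) || is.null(ridx)) return(.hit_search(reads[0], seqs, classes, tandem))
  # read-entry pairs need at least two distinct shared canonical seed words
  # whose entry positions fall within one read length of each other (the
  # two-hit seeding rule); each pair is then aligned only against the entry
  # window spanned by that word cluster, padded by one read length on each
  # side (seed-anchored alignment)
  ep <- eidx[, c("read", "pos", "canon")]
  names(ep) <- c("entry", "epos", "canon")
  rp <- unique(ridx[, c("read", "canon")])
  sh <- merge(rp, ep, by = "canon")
  if (nrow(sh) == 0L) return(.hit_search(reads[0], seqs, classes, tandem))
  read_w <- Biostrings::width(reads)
  key <- paste(sh$read, sh$entry)
  rows_by_pair <- split(seq_len(nrow(sh)), key)
  anchor <- lapply(rows_by_pair, function(rws) {
    o <- order(sh$epos[rws])
    epos <- sh$epos[rws][o]
    canon <- sh$canon[rws][o]
    gap <- read_w[sh$read[rws[1L]]]
    brk <- cumsum(c(0L, as.integer(diff(epos) > gap)))
    best <- NULL
    for (g in split(seq_along(epos), brk)) {
      nw <- length(unique(canon[g]))
      if (nw >= 2L && (is.null(best) || nw > best$nw)) {
        best <- list(nw = nw, lo = epos[g[1L]], hi = epos[g[length(g)]])
      }
    }
    if (is.null(best)) NULL else
      data.frame(read = sh$read[rws[1L]], entry = sh$entry[rws[1L]],
                 lo = best$lo, hi = best$hi)
  })
  pairs <- do.call(rbind, anchor[!vapply(anchor, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(.hit_search(reads[0], seqs, classes, tandem))
  }
  read_chr <- as.character(reads)
  read_names <- names(reads)
  hits <- list()
  for (e in sort(unique(pairs$entry))) {
    pp <- pairs[pairs$entry == e, , drop = FALSE]
    rids <- pp$read
    rw <- nchar(read_chr[rids])
    win_lo <- pmax(1L, pp$lo - rw)
    win_hi <- pmin(nchar(ent_chr[e]), pp$hi + seed_l - 1L + rw)
    # segment queue: read index, 0-based offset of segment within read, seq,
    # and the entry window the read is anchored to
    segs <- data.frame(read = rids, off = 0L,
                       seq = read_chr[rids],
                       sub = substr(rep(ent_chr[e], length(rids)),
                                    win_lo, win_hi),
                       stringsAsFactors = FALSE)
    round <- 0L
    while (nrow(segs) > 0L && round < max_rounds) {
      round <- round + 1L
      pats_f <- Biostrings::DNAStringSet(segs$seq)
      pats_r <- Biostrings::reverseComplement(pats_f)
      hf <- .align_set(pats_f, segs$sub)
      hr <- .align_set(pats_r, segs$sub)
      w <- nchar(segs$seq)
      use_r <- hr$score > hf$score
      h <- hf
      h[use_r, ] <- hr[use_r, ]
      strand <- ifelse(use_r, "-", "+")
      # map minus-strand pattern coords back to the forward segment
      ps <- ifelse(use_r, w - h$p_end + 1L, h$p_start)
      pe <- ifelse(use_r, w - h$p_start + 1L, h$p_end)
      len <- pe - ps + 1L
      ok <- len >= min_hit_len & h$identity >= min_identity
      if (any(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          read = segs$read[ok],
          start = segs$off[ok] + ps[ok] - 1L,
          end = segs$off[ok] + pe[ok],
          entry = e, identity = h$identity[ok], score = h$score[ok],
          strand = strand[ok])
      }
      # re-search remaining flanks of accepted segments
      nxt <- list()
      for (k in which(ok)) {
        if (ps[k] - 1L >= min_hit_len) {
          nxt[[length(nxt) + 1L]] <- data.frame(
            read = segs$read[k], off = segs$off[k],
            seq = substr(segs$seq[k], 1L, ps[k] - 1L),
            sub = segs$sub[k], stringsAsFactors = FALSE)
        }
        if (w[k] - pe[k] >= min_hit_len) {
          nxt[[length(nxt) + 1L]] <- data.frame(
            read = segs$read[k], off = segs$off[k] + pe[k],
            seq = substr(segs$seq[k], pe[k] + 1L, w[k]),
            sub = segs$sub[k], stringsAsFactors = FALSE)
        }
      }
      segs <- if (length(nxt)) do.call(rbind, nxt) else segs[0, ]
    }
  }
  if (!length(hits)) return(.hit_search(reads[0], seqs, classes, tandem))
  out <- do.call(rbind, hits)
  data.frame(read = read_names[out$read], start = out$start, end = out$end,
             entry = names(seqs)[out$entry], class = classes[out$entry],
             identity = out$identity, score = out$score, strand = out$strand,
             stringsAsFactors = FALSE)
}

#' Mask a read set with a repeat library
#'
#' Collects all admissible local hits of every library entry against every
#' read on both strands (identity and minimum-length thresholds, with
#' repeated search of unmasked read segments), then resolves overlapping
#' hits exclusively to the higher-scoring entry (ties to the longer hit,
#' then entry name) and totals the masked nucleotides per repeat class.
#' Tandem entries (per `tandem` flags or library metadata) are tiled
#' head-to-tail so a single hit can span a whole array region of a read.
#'
#' @param reads Read set (`DNAStringSet` or character).
#' @param library Repeat library: `DNAStringSet` (optionally with `class`,
#'   `tandem` metadata columns), `repeat_library`, `planted_genome`
#'   (its true consensi), or character vector.
#' @param classes Optional class label per entry (recycled if length 1).
#' @param tandem Optional logical per entry; tandem entries are tiled.
#' @param min_identity Minimum aligned identity of a hit (default 0.7).
#' @param min_hit_len Minimum hit length in nt (default 30).
#' @return Object of class `mask_report`: list with `intervals` (per-read
#'   disjoint attributed intervals), `hits` (all admissible hits),
#'   `class_nt` (masked nt per class), `total_masked_nt`, `total_nt`,
#'   `n_reads`, `params`.
#' @export
mask_reads <- function(reads, library, classes = NULL, tandem = NULL,
                       min_identity = 0.7, min_hit_len = 30L) {
  reads <- .as_readset(reads)
  lib <- .as_library(library, classes, tandem)
  total_nt <- sum(Biostrings::width(reads))
  hits <- .hit_search(reads, lib$seqs, lib$classes, lib$tandem,
                      min_identity = min_identity, min_hit_len = min_hit_len)
  intervals <- .attribute_hits(hits)
  class_nt <- if (nrow(intervals)) {
    tapply(intervals$end - intervals$start, intervals$class, sum)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  class_nt <- stats::setNames(as.numeric(class_nt), names(class_nt))
  structure(list(intervals = intervals, hits = hits, class_nt = class_nt,
                 total_masked_nt = sum(class_nt), total_nt = total_nt,
                 n_reads = length(reads),
                 params = list(min_identity = min_identity,
                               min_hit_len = min_hit_len)),
            class = "mask_report")
}

# Resolve overlapping hits exclusively: process by decreasing score (ties:
# longer hit, then entry name) and attribute only the not-yet-covered bases
# of each hit.
.attribute_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(read = character(0), start = integer(0),
                      end = integer(0), entry = character(0),
                      class = character(0)))
  }
  out <- list()
  for (rd in unique(hits$read)) {
    h <- hits[hits$read == rd, , drop = FALSE]
    h <- h[order(-h$score, -(h$end - h$start), h$entry), , drop = FALSE]
    covered <- IRanges::IRanges()
    for (k in seq_len(nrow(h))) {
      rng <- IRanges::IRanges(h$start[k] + 1L, h$end[k])
      free <- IRanges::setdiff(rng, covered)
      if (length(free) == 0L) next
      covered <- IRanges::reduce(c(covered, free))
      out[[length(out) + 1L]] <- data.frame(
        read = rd, start = IRanges::start(free) - 1L,
        end = IRanges::end(free), entry = h$entry[k], class = h$class[k])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mask reads by planted-truth provenance (no alignment)
#'
#' Uses the provenance carried by [shear_reads()] output to intersect each
#' read with the planted truth intervals, producing a [mask_reads()]-style
#' report without any alignment. This is the ground-truth upper bound for
#' masking-based abundance estimates.
#'
#' @param reads Read set from [shear_reads()] (must carry provenance mcols).
#' @param truth Truth data.frame from [plant_genome()].
#' @return A `mask_report`.
#' @export
mask_reads_truth <- function(reads, truth) {
  mc <- S4Vectors::mcols(reads)
  stopifnot(!is.null(mc), all(c("start", "end") %in% colnames(mc)))
  total_nt <- sum(Biostrings::width(reads))
  rr <- IRanges::IRanges(mc$start + 1L, mc$end)
  tr <- IRanges::IRanges(truth$start + 1L, truth$end)
  ov <- IRanges::findOverlaps(rr, tr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  inter <- IRanges::pintersect(rr[qh], tr[sh])
  intervals <- data.frame(
    read = names(reads)[qh],
    start = IRanges::start(inter) - mc$start[qh] - 1L,
    end = IRanges::end(inter) - mc$start[qh],
    entry = truth$family[sh], class = truth$class[sh],
    stringsAsFactors = FALSE)
  class_nt <- if (nrow(intervals)) {
    tapply(intervals$end - intervals$start, intervals$class, sum)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  class_nt <- stats::setNames(as.numeric(class_nt), names(class_nt))
  structure(list(intervals = intervals, hits = intervals,
                 class_nt = class_nt, total_masked_nt = sum(class_nt),
                 total_nt = total_nt, n_reads = length(reads),
                 params = list(mode = "truth")),
            class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat("Mask report: ", x$n_reads, " reads, ", x$total_nt, " nt, ",
      round(100 * x$total_masked_nt / max(x$total_nt, 1), 2), "% masked\n",
      sep = "")
  invisible(x)
}

#' Genome abundance estimate from a mask report
#'
#' Percent of sampled read nucleotides masked, per repeat class and overall.
#' Under the low-pass assumption the masked fraction of a random read sample
#' estimates the genomic fraction of each class.
#'
#' @param report A [mask_reads()] report.
#' @return Object of class `abundance_estimate`: data.frame with `class`,
#'   `masked_nt`, `percent`; the overall percent is in attribute
#'   `"overall"`.
#' @export
abundance <- function(report) {
  stopifnot(inherits(report, "mask_report"))
  if (report$total_nt <= 0) stop("mask report has zero read nucleotides")
  cls <- names(report$class_nt)
  df <- data.frame(class = cls, masked_nt = as.numeric(report$class_nt),
                   percent = 100 * as.numeric(report$class_nt) / report$total_nt)
  df <- df[order(-df$percent), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "overall") <- 100 * report$total_masked_nt / report$total_nt
  class(df) <- c("abundance_estimate", "data.frame")
  df
}

#' @export
print.abundance_estimate <- function(x, ...) {
  print.data.frame(x)
  cat("overall:", round(attr(x, "overall"), 2), "%\n")
  invisible(x)
}

#' Extrapolate repeat copy number from a masked fraction
#'
#' `floor(percent/100 * genome_size / unit_length)`: the number of repeat
#' units implied by a genomic fraction, a genome size and a unit length.
#'
#' @param percent Percent of the genome occupied by the repeat.
#' @param genome_size Genome size in nt.
#' @param unit_length Repeat unit (e.g. satellite monomer) length in nt.
#' @return Estimated copy count (integer-valued double).
#' @examples
#' copy_number(4.54, 730e6, 169)
#' @export
copy_number <- function(percent, genome_size, unit_length) {
  stopifnot(percent > 0, genome_size > 0, unit_length > 0)
  floor(round(percent / 100 * genome_size / unit_length, 9))
}

#' Reciprocal library completeness
#'
#' Masks one library's candidate sequences with another library and reports
#' the percent of candidates counted as masked, a candidate counting when at
#' least `covered_fraction_min` of its length is covered by merged hits.
#'
#' @param masking_library Library used to mask (any [mask_reads()] library
#'   form).
#' @param candidate_set Candidate sequences to be masked.
#' @param covered_fraction_min Per-candidate coverage threshold (default 0.8).
#' @param min_identity,min_hit_len Hit thresholds as in [mask_reads()].
#' @return List: `percent_masked`, per-candidate `covered_fraction`,
#'   `n_candidates`.
#' @export
completeness <- function(masking_library, candidate_set,
                         covered_fraction_min = 0.8,
                         min_identity = 0.7, min_hit_len = 30L) {
  cands <- .as_library(candidate_set)$seqs
  if (length(cands) == 0L) stop("empty candidate set")
  rep_ <- mask_reads(cands, masking_library, min_identity = min_identity,
                     min_hit_len = min_hit_len)
  cov <- stats::setNames(numeric(length(cands)), names(cands))
  if (nrow(rep_$intervals)) {
    agg <- tapply(rep_$intervals$end - rep_$intervals$start,
                  rep_$intervals$read, sum)
    cov[names(agg)] <- as.numeric(agg)
  }
  frac <- cov / Biostrings::width(cands)
  list(percent_masked = 100 * mean(frac >= covered_fraction_min),
       covered_fraction = frac, n_candidates = length(cands))
}
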