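# Library characterization: similarity classification of candidates against
# a labelled exemplar library (nucleotide first, then translated search
# against protein exemplars), decoy-based removal, NHF flagging, and tandem
# structure detection with monomer inference.

#' Classify a repeat candidate by similarity to labelled exemplars
#'
#' Searches the candidate against every nucleotide exemplar on both strands
#' and, if no admissible nucleotide hit is found and protein exemplars are
#' provided, translates the candidate in six frames and searches at the
#' amino-acid level. The best admissible hit (approximate expectation value
#' `<= evalue_max`) determines the class label; with no admissible hit the
#' candidate is flagged `"NHF"` (no hits found). If a decoy library is
#' given (e.g. organellar or gene-family sequences) and the best decoy hit
#' outscores the best exemplar hit, the label is `"decoy"` and the caller
#' should drop the candidate. Equal-scoring hits of different classes break
#' to the longer aligned span, then to the lexicographically smaller class.
#'
#' @param candidate Nucleotide sequence.
#' @param reference Labelled exemplars: named `DNAStringSet`/character with
#'   names `"id|class"` or with a `class` metadata column.
#' @param protein_reference Optional labelled `AAStringSet`/character of
#'   protein exemplars (same naming convention).
#' @param decoy Optional decoy `DNAStringSet`/character.
#' @param evalue_max Expectation-value threshold (default 1e-5).
#' @return List: `label`, `best_id`, `evalue`, `score`, `level`
#'   (`"nt"`, `"aa"` or `NA`).
#' @export
classify_repeat <- function(candidate, reference, protein_reference = NULL,
                            decoy = NULL, evalue_max = 1e-5) {
  if (length(reference) == 0L) {
    warning("empty reference library; candidate flagged NHF")
    return(list(label = "NHF", best_id = NA_character_, evalue = NA_real_,
                score = NA_real_, level = NA_character_))
  }
  cand <- .as_seq_string(candidate)
  ref <- .labelled_set(reference)
  best <- .best_labelled_hit_nt(cand, ref, evalue_max)
  level <- if (!is.null(best)) "nt" else NA_character_
  if (is.null(best) && !is.null(protein_reference)) {
    pref <- .labelled_set(protein_reference, aa = TRUE)
    best <- .best_labelled_hit_aa(cand, pref, evalue_max)
    if (!is.null(best)) level <- "aa"
  }
  if (!is.null(decoy) && length(decoy) > 0L) {
    dref <- list(seqs = as.character(.as_library(decoy)$seqs),
                 ids = names(.as_library(decoy)$seqs),
                 classes = rep("decoy", length(decoy)))
    dbest <- .best_labelled_hit_nt(cand, dref, evalue_max)
    if (!is.null(dbest) && (is.null(best) || dbest$score > best$score)) {
      return(list(label = "decoy", best_id = dbest$id, evalue = dbest$evalue,
                  score = dbest$score, level = "nt"))
    }
  }
  if (is.null(best)) {
    return(list(label = "NHF", best_id = NA_character_, evalue = NA_real_,
                score = NA_real_, level = NA_character_))
  }
  list(label = best$class, best_id = best$id, evalue = best$evalue,
       score = best$score, level = level)
}

# Parse "id|class" names (or class metadata) into seqs / ids / classes.
.labelled_set <- function(x, aa = FALSE) {
  if (aa) {
    if (is.character(x)) x <- Biostrings::AAStringSet(x)
    seqs <- as.character(x)
  } else {
    lib <- .as_library(x)
    x <- lib$seqs
    seqs <- as.character(x)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("ref_%04d", seq_along(x))
  mc <- if (methods::is(x, "XStringSet")) S4Vectors::mcols(x) else NULL
  if (!is.null(mc) && "class" %in% colnames(mc)) {
    classes <- as.character(mc$class)
  } else if (all(grepl("|", ids, fixed = TRUE))) {
    classes <- sub("^[^|]*\\|", "", ids)
    ids <- sub("\\|.*$", "", ids)
  } else {
    classes <- rep("other", length(ids))
  }
  list(seqs = unname(seqs), ids = ids, classes = classes)
}

.best_labelled_hit_nt <- function(cand, ref, evalue_max) {
  best <- NULL
  for (i in seq_along(ref$seqs)) {
    h <- local_align(cand, ref$seqs[i], match = 1, mismatch = -1,
                     gap_open = 2, gap_extend = 1)
    if (h$evalue <= evalue_max) {
      span <- h$subject_end - h$subject_start
      if (is.null(best) || h$score > best$score ||
          (h$score == best$score && span > best$span) ||
          (h$score == best$score && span == best$span &&
             ref$classes[i] < best$class)) {
        best <- list(id = ref$ids[i], class = ref$classes[i],
                     score = h$score, evalue = h$evalue, span = span)
      }
    }
  }
  best
}

.best_labelled_hit_aa <- function(cand, pref, evalue_max) {
  frames <- .six_frame_translate(cand)
  best <- NULL
  for (f in seq_along(frames)) {
    aa <- frames[[f]]
    if (nchar(aa) < 10L) next
    for (i in seq_along(pref$seqs)) {
      h <- local_align(aa, pref$seqs[i], type = "aa",
                       gap_open = 11, gap_extend = 1)
      if (h$evalue <= evalue_max) {
        span <- h$subject_end - h$subject_start
        if (is.null(best) || h$score > best$score ||
            (h$score == best$score && span > best$span) ||
            (h$score == best$score && span == best$span &&
               pref$classes[i] < best$class)) {
          best <- list(id = pref$ids[i], class = pref$classes[i],
                       score = h$score, evalue = h$evalue, span = span)
        }
      }
    }
  }
  best
}

# Translate a nucleotide string in all six frames; N codons become X.
.six_frame_translate <- function(s) {
  d <- Biostrings::DNAString(s)
  r <- Biostrings::reverseComplement(d)
  out <- list()
  for (f in 1:3) {
    for (x in list(d, r)) {
      n <- length(x) - f + 1L
      n <- n - (n %% 3L)
      out[[length(out) + 1L]] <- if (n >= 3L) {
        as.character(Biostrings::translate(
          Biostrings::subseq(x, f, f + n - 1L), if.fuzzy.codon = "X"))
      } else {
        ""
      }
    }
  }
  out
}

#' Detect tandem structure and infer the monomer
#'
#' Scans lags `p >= min_period` and selects the lag maximizing the mean
#' identity between the sequence and itself shifted by `p`, provided that
#' identity reaches `min_identity` (default 0.7, chosen to admit satellite
#' arrays whose copies average ~79% similarity while rejecting random
#' sequence). The monomer consensus is the column-majority over the phased
#' full units.
#'
#' @param candidate Sequence of length at least `2 * min_period`.
#' @param min_period Minimum monomer length (default 100 nt).
#' @param min_identity Self-identity floor for a tandem call.
#' @return A list of class `tandem_call` (`period`, `monomer`,
#'   `span` = c(start, end) 0-based half-open, `adjacent_identity`,
#'   `self_identity`) or `NULL` when no lag qualifies.
#' @export
detect_tandem <- function(candidate, min_period = 100L, min_identity = 0.7) {
  s <- .chars(.as_seq_string(candidate))
  n <- length(s)
  if (n < 2L * min_period) return(NULL)
  lags <- seq.int(min_period, n %/% 2L)
  ids <- vapply(lags, function(p) {
    mean(s[seq_len(n - p)] == s[seq.int(p + 1L, n)])
  }, numeric(1))
  if (max(ids) < min_identity) return(NULL)
  # Multiples of the true period score near-identical self-identity, so the
  # argmax alone can land on a harmonic; take the smallest lag within a
  # small tolerance of the maximum.
  p <- lags[which(ids >= max(ids) - 0.02)[1L]]
  k <- n %/% p
  units <- matrix(s[seq_len(k * p)], nrow = k, ncol = p, byrow = TRUE)
  cons <- apply(units, 2L, function(col) {
    cnt <- tabulate(match(col, .BASES), nbins = 4L)
    .BASES[which.max(cnt)]
  })
  adj <- if (k >= 2L) {
    mean(vapply(seq_len(k - 1L), function(i) {
      mean(units[i, ] == units[i + 1L, ])
    }, numeric(1)))
  } else {
    NA_real_
  }
  structure(list(period = p, monomer = paste(cons, collapse = ""),
                 span = c(0L, n), adjacent_identity = adj,
                 self_identity = max(ids)),
            class = "tandem_call")
}

#' @export
print.tandem_call <- function(x, ...) {
  cat("Tandem call: period", x$period, "nt, adjacent-unit identity",
      round(x$adjacent_identity, 3), "\n")
  invisible(x)
}

#' Annotate a repeat library: classification and tandem structure
#'
#' Runs [classify_repeat()] and [detect_tandem()] over every candidate.
#' Candidates labelled `"decoy"` are dropped from the annotated library, as
#' organellar / gene-family contaminants are removed rather than kept.
#'
#' @param library Candidate library (any [mask_reads()] library form).
#' @param reference,protein_reference,decoy,evalue_max See
#'   [classify_repeat()].
#' @param min_period Tandem detection minimum period.
#' @return List of class `annotated_library`: `table` (data.frame: `id`,
#'   `length`, `class`, `best_id`, `evalue`, `score`, `tandem`, `period`),
#'   `sequences` (`DNAStringSet` with `class`/`tandem`/`period` metadata,
#'   decoys removed), `dropped` (ids removed as decoys).
#' @export
annotate_library <- function(library, reference, protein_reference = NULL,
                             decoy = NULL, evalue_max = 1e-5,
                             min_period = 100L) {
  lib <- .as_library(library)
  seqs <- lib$seqs
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    cl <- classify_repeat(as.character(seqs[[i]]), reference,
                          protein_reference = protein_reference,
                          decoy = decoy, evalue_max = evalue_max)
    td <- detect_tandem(as.character(seqs[[i]]), min_period = min_period)
    rows[[i]] <- data.frame(
      id = names(seqs)[i], length = Biostrings::width(seqs)[i],
      class = cl$label, best_id = ifelse(is.null(cl$best_id), NA, cl$best_id),
      evalue = cl$evalue, score = cl$score,
      tandem = !is.null(td),
      period = if (!is.null(td)) td$period else NA_integer_,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  keep <- tab$class != "decoy"
  out_seqs <- seqs[keep]
  S4Vectors::mcols(out_seqs) <- S4Vectors::DataFrame(
    class = tab$class[keep], tandem = tab$tandem[keep],
    period = tab$period[keep])
  structure(list(table = tab, sequences = out_seqs,
                 dropped = tab$id[!keep]),
            class = "annotated_library")
}

#' @export
print.annotated_library <- function(x, ...) {
  cat("Annotated library:", nrow(x$table), "candidates,",
      length(x$dropped), "dropped as decoys\n")
  print(table(x$table$class))
  invisible(x)
}
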