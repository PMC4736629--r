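# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so that seeded package functions do not disturb the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Coerce sequence input (character / DNAString / DNAStringSet element) to a
# single upper-case character string over A,C,G,T,N. Ambiguity codes become N.
.as_seq_string <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Coerce reads input to a named DNAStringSet.
.as_readset <- function(reads) {
  if (is.character(reads)) {
    reads <- Biostrings::DNAStringSet(toupper(reads))
  }
  stopifnot(methods::is(reads, "DNAStringSet"))
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  }
  reads
}

# Split a sequence string into a character vector of single bases.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.BASES <- c("A", "C", "G", "T")

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Nucleotide substitution matrix over A,C,G,T,N where N never matches
# (scores `mismatch` against everything, including itself).
.nuc_matrix <- function(match, mismatch) {
  letters5 <- c(.BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m)[1:4] <- match
  m
}

# Ungapped Karlin-Altschul lambda for a match/mismatch scheme under uniform
# base composition: solves sum_ij p_i p_j exp(lambda s_ij) = 1.
.ka_lambda <- function(match, mismatch) {
  f <- function(lam) {
    0.25 * exp(lam * match) + 0.75 * exp(lam * mismatch) - 1
  }
  stats::uniroot(f, c(1e-6, 10))$root
}

# Approximate E-value; K fixed at a documented ballpark constant. For
# amino-acid searches BLAST's gapped BLOSUM62 constants are used instead.
.approx_evalue <- function(score, m, n, lambda, K = 0.1) {
  K * m * n * exp(-lambda * score)
}
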