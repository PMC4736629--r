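# Paralog-based phylogenetics: translated-search mining of protein-domain
# tracts from reads, progressive multiple alignment, neighbor-joining trees
# with bootstrap supports, Kimura two-parameter distances and molecular-clock
# dating of subclade splits.

# BLAST-style gapped BLOSUM62 Karlin-Altschul constants.
.AA_LAMBDA <- 0.267
.AA_K <- 0.041

#' Mine protein-domain paralog tracts from reads by translated search
#'
#' Translates every read in six frames and locally aligns each frame against
#' the amino-acid query (BLOSUM62, gaps 11/1). Hits with an approximate
#' expectation value below `evalue_max` that cover at least `min_cov_aa`
#' residues of the query are retained; the best hit per read wins, and the
#' in-frame nucleotide tract underlying the aligned segment is extracted.
#'
#' @param reads Read set.
#' @param query_tract_aa Amino-acid query (e.g. a 100-residue reverse
#'   transcriptase tract).
#' @param evalue_max Expectation threshold (default 1e-5).
#' @param min_cov_aa Minimum aligned query coverage in residues (default 80).
#' @param sample_tag Optional tag (cultivar / species) recorded per tract
#'   and prefixed to tract ids.
#' @return Object of class `paralog_tracts`: data.frame with `id`, `aa`,
#'   `nt`, `frame` (+-1..3), `read`, `tag`, `score`, `evalue`, `coverage`.
#' @export
mine_paralogs <- function(reads, query_tract_aa, evalue_max = 1e-5,
                          min_cov_aa = 80L, sample_tag = NULL) {
  reads <- .as_readset(reads)
  query <- toupper(as.character(query_tract_aa))
  stopifnot(nchar(query) >= min_cov_aa)
  qaa <- Biostrings::AAString(query)
  n <- length(reads)
  best <- data.frame(score = rep(-Inf, n), evalue = NA_real_,
                     coverage = 0L, frame = NA_integer_,
                     aa = NA_character_, nt = NA_character_)
  read_chr <- as.character(reads)
  rc_chr <- as.character(Biostrings::reverseComplement(reads))
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    src <- if (fr > 0) read_chr else rc_chr
    f <- abs(fr)
    lens <- nchar(src)
    usable <- lens - f + 1L
    usable <- usable - (usable %% 3L)
    ok <- which(usable >= 3L * 20L)
    if (!length(ok)) next
    subs <- substr(src[ok], f, f + usable[ok] - 1L)
    aas <- suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(subs), if.fuzzy.codon = "X"))
    aln <- Biostrings::pairwiseAlignment(
      aas, qaa, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    cov <- Biostrings::width(Biostrings::subject(aln))
    ev <- .approx_evalue(sc, nchar(query), Biostrings::width(aas),
                         lambda = .AA_LAMBDA, K = .AA_K)
    adm <- which(ev <= evalue_max & cov >= min_cov_aa & sc > best$score[ok])
    for (j in adm) {
      i <- ok[j]
      pr <- Biostrings::pattern(aln[j])
      aa_s <- Biostrings::start(pr); aa_e <- Biostrings::end(pr)
      aa_tract <- substr(as.character(aas[[j]]), aa_s, aa_e)
      nt_s <- f + 3L * (aa_s - 1L)
      nt_e <- f + 3L * aa_e - 1L
      nt_tract <- substr(src[i], nt_s, nt_e)
      best[i, ] <- list(sc[j], ev[j], cov[j], fr, aa_tract, nt_tract)
    }
  }
  hit <- which(is.finite(best$score))
  tag <- rep(if (is.null(sample_tag)) NA_character_ else sample_tag,
             length(hit))
  ids <- if (is.null(sample_tag)) {
    names(reads)[hit]
  } else {
    paste(sample_tag, names(reads)[hit], sep = "_")
  }
  out <- data.frame(id = ids, aa = best$aa[hit], nt = best$nt[hit],
                    frame = best$frame[hit], read = names(reads)[hit],
                    tag = tag, score = best$score[hit],
                    evalue = best$evalue[hit], coverage = best$coverage[hit],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("paralog_tracts", "data.frame")
  out
}

# ---- progressive multiple alignment ----

#' Progressive multiple alignment of amino-acid tracts
#'
#' Builds a UPGMA guide tree from pairwise global-alignment identities and
#' merges profiles progressively with a profile-profile dynamic program
#' (BLOSUM62 expected column score, linear gap penalty).
#'
#' @param tracts `paralog_tracts`, named character vector or `AAStringSet`.
#' @param gap Linear gap penalty per residue-vs-gap column (default 4).
#' @return An `AAStringSet` of equal-width aligned sequences.
#' @export
align_tracts <- function(tracts, gap = 4) {
  seqs <- .tracts_to_aa(tracts)
  n <- length(seqs)
  if (n == 1L) return(Biostrings::AAStringSet(seqs))
  chr <- as.character(seqs)
  prof <- lapply(seq_len(n), function(i) {
    m <- matrix(.chars(chr[i]), nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  if (n == 2L) {
    merged <- .profile_align(prof[[1]], prof[[2]], gap)
  } else {
    d <- matrix(0, n, n)
    sm <- .blosum62()
    for (i in seq_len(n - 1L)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(chr[(i + 1L):n]), Biostrings::AAString(chr[i]),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 0, gapExtension = gap)
      pid <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      d[i, (i + 1L):n] <- 1 - pid
      d[(i + 1L):n, i] <- 1 - pid
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    node_prof <- vector("list", n + nrow(hc$merge))
    for (i in seq_len(n)) node_prof[[i]] <- prof[[i]]
    for (k in seq_len(nrow(hc$merge))) {
      a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
      pa <- if (a < 0) node_prof[[-a]] else node_prof[[n + a]]
      pb <- if (b < 0) node_prof[[-b]] else node_prof[[n + b]]
      node_prof[[n + k]] <- .profile_align(pa, pb, gap)
    }
    merged <- node_prof[[n + nrow(hc$merge)]]
  }
  # restore input order by row labels
  out <- apply(merged, 1L, paste, collapse = "")
  res <- Biostrings::AAStringSet(out[match(names(seqs), rownames(merged))])
  names(res) <- names(seqs)
  res
}

.tracts_to_aa <- function(tracts) {
  if (inherits(tracts, "paralog_tracts")) {
    seqs <- Biostrings::AAStringSet(tracts$aa)
    names(seqs) <- tracts$id
  } else if (is.character(tracts)) {
    seqs <- Biostrings::AAStringSet(toupper(tracts))
    if (is.null(names(seqs))) names(seqs) <- sprintf("t%03d", seq_along(seqs))
  } else {
    seqs <- tracts
    if (is.null(names(seqs))) names(seqs) <- sprintf("t%03d", seq_along(seqs))
  }
  stopifnot(length(seqs) >= 1L)
  seqs
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Align two profiles (character matrices, rows = sequences, "-" = gap) with
# a global DP: column score = mean pairwise BLOSUM62 over non-gap pairs,
# gap column vs residue column costs -gap. Returns the merged matrix.
.profile_align <- function(A, B, gap) {
  S <- .blosum62()
  la <- ncol(A); lb <- ncol(B)
  alf <- rownames(S)
  fa <- .prof_freq(A, alf); fb <- .prof_freq(B, alf)
  M <- t(fa) %*% S %*% fb  # (la x lb) expected column scores
  D <- matrix(0, la + 1L, lb + 1L)
  D[1, ] <- -gap * (0:lb)
  D[, 1] <- -gap * (0:la)
  P <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    diagv <- D[i, 1:lb] + M[i, ]
    row <- numeric(lb + 1L)
    row[1] <- D[i + 1L, 1]
    for (j in seq_len(lb)) {
      up <- D[i, j + 1L] - gap
      left <- row[j] - gap
      dg <- diagv[j]
      best <- max(dg, up, left)
      row[j + 1L] <- best
      P[i + 1L, j + 1L] <- if (best == dg) 1L else if (best == up) 2L else 3L
    }
    D[i + 1L, ] <- row
  }
  # traceback
  i <- la; j <- lb
  colsA <- integer(0); colsB <- integer(0)
  while (i > 0L || j > 0L) {
    move <- if (i == 0L) 3L else if (j == 0L) 2L else P[i + 1L, j + 1L]
    if (move == 1L) {
      colsA <- c(i, colsA); colsB <- c(j, colsB); i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      colsA <- c(i, colsA); colsB <- c(0L, colsB); i <- i - 1L
    } else {
      colsA <- c(0L, colsA); colsB <- c(j, colsB); j <- j - 1L
    }
  }
  take <- function(Pm, cols) {
    out <- matrix("-", nrow(Pm), length(cols))
    nz <- cols > 0L
    out[, nz] <- Pm[, cols[nz], drop = FALSE]
    out
  }
  res <- rbind(take(A, colsA), take(B, colsB))
  rownames(res) <- c(rownames(A), rownames(B))
  res
}

.prof_freq <- function(P, alphabet) {
  f <- matrix(0, length(alphabet), ncol(P), dimnames = list(alphabet, NULL))
  for (j in seq_len(ncol(P))) {
    col <- P[, j]
    col <- col[col != "-"]
    if (length(col)) {
      t <- table(factor(col, levels = alphabet))
      f[, j] <- as.numeric(t) / length(col)
    }
  }
  f
}

# ---- distances ----

#' Kimura two-parameter distance between aligned nucleotide sequences
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` the transition
#' and `Q` the transversion proportion over aligned columns; columns with a
#' gap or N in either sequence are excluded. Saturated pairs (either log
#' argument non-positive) return `NA` with a warning.
#'
#' @param nt_a,nt_b Equal-length aligned nucleotide strings.
#' @return The K2P distance (substitutions/site), or `NA` on saturation.
#' @examples
#' k2p_distance(strrep("A", 100), strrep("A", 100)) # 0
#' @export
k2p_distance <- function(nt_a, nt_b) {
  a <- .chars(toupper(as.character(nt_a)))
  b <- .chars(toupper(as.character(nt_b)))
  stopifnot(length(a) == length(b))
  ok <- a %in% .BASES & b %in% .BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable (gap/N-free) aligned columns")
  purine <- c("A", "G")
  ts <- sum(a != b & (a %in% purine) == (b %in% purine))
  tv <- sum(a != b & (a %in% purine) != (b %in% purine))
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    warning("K2P distance undefined (saturated pair)")
    return(NA_real_)
  }
  -0.5 * log(arg1 * sqrt(arg2))
}

#' K2P distance matrix over aligned nucleotide sequences
#'
#' @param nt_seqs Named character vector / `DNAStringSet` of equal-length
#'   aligned sequences.
#' @return Symmetric matrix of K2P distances (NA where saturated).
#' @export
k2p_matrix <- function(nt_seqs) {
  s <- as.character(nt_seqs)
  n <- length(s)
  labs <- names(s)
  if (is.null(labs)) labs <- sprintf("s%03d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- suppressWarnings(k2p_distance(s[i], s[j]))
      D[i, j] <- D[j, i] <- k
    }
  }
  D
}

# ---- trees ----

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]); negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' edge so pairwise path lengths through the parent are preserved.
#'
#' @param d Symmetric distance matrix (labels as dimnames) or `dist`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) >= 3L)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  tr <- ape::nj(stats::as.dist(d))
  .clamp_negative_edges(tr)
}

.clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sisters)) {
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# p-distance matrix over an aligned AAStringSet (pairwise-deletion of gaps).
.aa_pdist <- function(msa) {
  chr <- lapply(as.character(msa), .chars)
  n <- length(chr)
  labs <- names(msa)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chr[[i]]; b <- chr[[j]]
      ok <- a != "-" & b != "-" & a != "X" & b != "X"
      D[i, j] <- D[j, i] <- if (any(ok)) mean(a[ok] != b[ok]) else 0
    }
  }
  D
}

#' Neighbor-joining tree with bootstrap supports from an alignment
#'
#' Builds the point-estimate NJ tree from p-distances over the alignment,
#' then resamples alignment columns with replacement `n_replicates` times,
#' rebuilding distances and the NJ tree each time. The support of each
#' internal edge of the point tree is the percentage of replicates whose
#' tree contains the same bipartition (stored in `node.label`). The
#' customary "show only supports > 50" rule is a display decision left to
#' the caller.
#'
#' @param msa Aligned sequences (`AAStringSet` / named character), >= 4.
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @param dist_fun Function from aligned character matrix rows to a distance
#'   matrix; defaults to amino-acid p-distance.
#' @return `phylo` tree with bootstrap percentages in `node.label`.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L,
                              dist_fun = NULL) {
  if (is.character(msa)) msa <- Biostrings::AAStringSet(msa)
  stopifnot(length(msa) >= 4L)
  chr <- do.call(rbind, lapply(as.character(msa), .chars))
  rownames(chr) <- names(msa)
  if (is.null(dist_fun)) {
    dist_fun <- function(m) {
      sets <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
      names(sets) <- rownames(m)
      .aa_pdist(sets)
    }
  }
  point <- nj_tree(dist_fun(chr))
  L <- ncol(chr)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      nj_tree(dist_fun(chr[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / n_replicates, 1)
  point
}

# ---- dating ----

#' Molecular-clock date from a K2P distance
#'
#' `T = K / (2 r)`, reported in millions of years, with `r` in
#' substitutions/site/year. The default rate 6.5e-8 is the value commonly
#' applied to grass retrotransposons.
#'
#' @param K K2P distance (substitutions/site).
#' @param rate Substitution rate per site per year (default 6.5e-8).
#' @return Time in millions of years.
#' @examples
#' date_split(0.13) # 1 mya
#' @export
date_split <- function(K, rate = 6.5e-8) {
  stopifnot(all(K >= 0, na.rm = TRUE), rate > 0)
  K / (2 * rate) / 1e6
}

#' Date the split between two paralog subclades
#'
#' Aligns every subclade-A tract against every subclade-B tract at the
#' nucleotide level (global alignment; gap columns excluded), computes the
#' K2P distance per pair and converts each to a split time `T = K / (2 r)`.
#' Saturated pairs are excluded and counted.
#'
#' @param tracts_a,tracts_b Nucleotide tracts (named character vectors,
#'   `DNAStringSet`s, or `paralog_tracts` — the `nt` column is used).
#' @param rate Substitution rate per site per year (default 6.5e-8).
#' @return Object of class `clade_dating`: `pairs` (data.frame `a`, `b`,
#'   `K`, `T_mya`), `n_pairs`, `n_saturated`, `min_mya`, `max_mya`,
#'   `mean_mya`.
#' @export
subclade_split_times <- function(tracts_a, tracts_b, rate = 6.5e-8) {
  a <- .tracts_to_nt(tracts_a)
  b <- .tracts_to_nt(tracts_b)
  stopifnot(length(a) > 0L, length(b) > 0L)
  sm <- .nuc_matrix(1, -1)
  rows <- list()
  n_sat <- 0L
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a[i]), Biostrings::DNAString(b[j]),
        type = "global", substitutionMatrix = sm,
        gapOpening = 5, gapExtension = 2)
      K <- suppressWarnings(k2p_distance(
        as.character(Biostrings::alignedPattern(pa)),
        as.character(Biostrings::alignedSubject(pa))))
      if (is.na(K)) {
        n_sat <- n_sat + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        a = names(a)[i], b = names(b)[j], K = K,
        T_mya = date_split(K, rate))
    }
  }
  if (!length(rows)) {
    stop("all ", n_sat, " subclade pairs are saturated; no dates estimable")
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, n_pairs = nrow(pairs), n_saturated = n_sat,
                 min_mya = min(pairs$T_mya), max_mya = max(pairs$T_mya),
                 mean_mya = mean(pairs$T_mya), rate = rate),
            class = "clade_dating")
}

.tracts_to_nt <- function(x) {
  if (inherits(x, "paralog_tracts")) {
    out <- stats::setNames(x$nt, x$id)
  } else {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- sprintf("t%03d", seq_along(out))
  }
  out
}

#' @export
print.clade_dating <- function(x, ...) {
  cat("Subclade split times over", x$n_pairs, "pairs (",
      x$n_saturated, "saturated excluded): ",
      round(x$min_mya, 1), "-", round(x$max_mya, 1),
      "mya (mean", round(x$mean_mya, 1), ")\n")
  invisible(x)
}
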