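# Synthetic genome simulator: plants dispersed repeat families and tandem
# satellite arrays into a random background at specified genome fractions,
# records exact ground-truth intervals, and shears the genome into low-pass
# read sets. Every downstream stage of the package is testable against the
# planted truth without any external data.

.CLASS_LABELS <- c("Ty1-copia", "Ty3-gypsy", "unclassified-LTR", "non-LTR",
                   "SINE", "DNA-TE", "satellite", "other")

#' Describe a repeat family to plant
#'
#' @param name Family identifier.
#' @param class_label Repeat class, one of `"Ty1-copia"`, `"Ty3-gypsy"`,
#'   `"unclassified-LTR"`, `"non-LTR"`, `"SINE"`, `"DNA-TE"`, `"satellite"`,
#'   `"other"`.
#' @param unit_length Element length in nt (monomer length for satellites).
#' @param target_fraction Percent of the genome this family should occupy.
#' @param divergence Expected per-site substitution fraction per copy,
#'   in `[0, 0.5)`.
#' @param arrangement `"dispersed"` or `"tandem"`; defaults to `"tandem"` for
#'   satellites and `"dispersed"` otherwise.
#' @param domain_cassette Optional amino-acid sequence back-translated (fixed
#'   codon per residue) and embedded at the centre of each copy's consensus;
#'   used to exercise translated-search paralog mining.
#' @param n_loci For tandem families, number of array loci the copies are
#'   spread across (default 10).
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, class_label, unit_length, target_fraction,
                        divergence = 0, arrangement = NULL,
                        domain_cassette = NULL, n_loci = 10L) {
  class_label <- match.arg(class_label, .CLASS_LABELS)
  if (is.null(arrangement)) {
    arrangement <- if (class_label == "satellite") "tandem" else "dispersed"
  }
  arrangement <- match.arg(arrangement, c("dispersed", "tandem"))
  stopifnot(unit_length >= 1, target_fraction >= 0,
            divergence >= 0, divergence < 0.5, n_loci >= 1)
  structure(list(name = name, class_label = class_label,
                 unit_length = as.integer(unit_length),
                 target_fraction = target_fraction,
                 divergence = divergence, arrangement = arrangement,
                 domain_cassette = domain_cassette,
                 n_loci = as.integer(n_loci)),
            class = "family_spec")
}

#' Describe a synthetic genome
#'
#' @param genome_length Genome length in nt (>= 1000).
#' @param families List of [family_spec()] objects; their `target_fraction`s
#'   must sum to at most 100.
#' @param gc_background Background GC fraction in (0, 1).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(genome_length, families = list(),
                        gc_background = 0.44, seed = 1L) {
  stopifnot(genome_length >= 1000, gc_background > 0, gc_background < 1)
  frac <- sum(vapply(families, function(f) f$target_fraction, numeric(1)))
  if (frac > 100) {
    stop("family target fractions sum to ", round(frac, 2),
         "% which exceeds 100% of the genome")
  }
  for (f in families) {
    if (f$unit_length > genome_length) {
      stop("family '", f$name, "' unit length ", f$unit_length,
           " exceeds the genome length ", genome_length)
    }
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_background = gc_background, families = families,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Default repeat family set emulating a repeat-rich plant genome at desk scale
#'
#' A family set whose planted fractions total 27.46% of the genome:
#' LTR retrotransposon families totalling 14.96% (Ty1-copia 2.67%, Ty3-gypsy
#' 11.40% split over two families, unclassified LTR 0.89%), DNA transposons
#' 2.33%, dispersed families totalling 5.63% standing in for the
#' uncharacterized fraction (minor classes below a 0.5% floor are folded
#' in), and a 169 bp-monomer tandem satellite at 4.54%. Unit lengths are
#' scaled down so that per-family copy numbers on megabase-scale test
#' genomes stay in the medium/high-copy regime that read-based discovery
#' targets. Per-copy divergence defaults to 8% (10% for the degraded
#' uncharacterized families).
#'
#' @param divergence Per-copy divergence for the main families.
#' @return List of [family_spec()] objects.
#' @seealso [ltr_family_set()] for full-length LTR element emulation.
#' @export
default_repeat_families <- function(divergence = 0.08) {
  list(
    family_spec("copia_1", "Ty1-copia", 1000, 2.67, divergence),
    family_spec("gypsy_1", "Ty3-gypsy", 1500, 6.00, divergence),
    family_spec("gypsy_2", "Ty3-gypsy", 1200, 5.40, divergence),
    family_spec("ltrx_1", "unclassified-LTR", 800, 0.89, divergence),
    family_spec("dnate_1", "DNA-TE", 600, 2.33, divergence),
    family_spec("misc_1", "other", 400, 1.19, divergence),
    family_spec("unchar_1", "other", 500, 4.44, 0.10),
    family_spec("sat169_1", "satellite", 169, 4.54, divergence)
  )
}

#' LTR retrotransposon family set with full-length elements
#'
#' Dispersed LTR retroelement families at realistic element lengths
#' (1-8 kb) whose fractions sum to 14.96% of the genome: Ty1-copia 2.67%
#' (4.5 kb), Ty3-gypsy 11.40% split over a 7 kb and a 5 kb family, and an
#' unclassified LTR family 0.89% (2 kb). Intended for exemplar-based
#' masking experiments where copy number per family may be low.
#'
#' @param divergence Per-copy divergence (default 8%).
#' @return List of [family_spec()] objects.
#' @export
ltr_family_set <- function(divergence = 0.08) {
  list(
    family_spec("copia_1", "Ty1-copia", 4500, 2.67, divergence),
    family_spec("gypsy_1", "Ty3-gypsy", 7000, 6.00, divergence),
    family_spec("gypsy_2", "Ty3-gypsy", 5000, 5.40, divergence),
    family_spec("ltrx_1", "unclassified-LTR", 2000, 0.89, divergence)
  )
}

#' Back-translate an amino-acid sequence with a fixed codon table
#'
#' Uses one fixed codon per amino acid, so the mapping is deterministic and
#' translated-search tests are reproducible.
#'
#' @param aa Amino-acid sequence (character or `AAString`).
#' @return Nucleotide character string of length `3 * nchar(aa)`.
#' @export
back_translate <- function(aa) {
  codons <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
              "*" = "TAA")
  ch <- .chars(toupper(as.character(aa)))
  bad <- !(ch %in% names(codons))
  if (any(bad)) stop("unknown amino acid(s): ", paste(unique(ch[bad]), collapse = ","))
  paste(codons[ch], collapse = "")
}

#' Mutate a sequence copy by independent substitutions
#'
#' Each site is substituted independently with probability `divergence`,
#' uniformly over the three alternative bases, so the expected identity to
#' the input is `1 - divergence`.
#'
#' @param consensus Sequence (character or `DNAString`).
#' @param divergence Substitution probability per site, in `[0, 0.5)`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Mutated character string.
#' @export
mutate_copy <- function(consensus, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence < 0.5)
  run <- function() .mutate_chars(.chars(.as_seq_string(consensus)), divergence)
  ch <- if (is.null(seed)) run() else with_seed(seed, run())
  paste(ch, collapse = "")
}

.mutate_chars <- function(ch, divergence) {
  if (divergence == 0) return(ch)
  hit <- which(stats::runif(length(ch)) < divergence)
  if (length(hit)) {
    cur <- match(ch[hit], .BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  ch
}

#' Evolve a sequence under a continuous-time Jukes-Cantor clock
#'
#' Applies the Jukes-Cantor substitution process for a branch accumulating
#' `subs_per_site` expected substitutions per site: each site changes to each
#' alternative base with probability `(1 - exp(-4 d / 3)) / 4`. Used to
#' simulate molecular-clock divergence for dating tests.
#'
#' @param sequence Input sequence.
#' @param subs_per_site Expected substitutions per site on the branch (d).
#' @param seed Optional seed.
#' @return Evolved character string.
#' @export
evolve_sequence <- function(sequence, subs_per_site, seed = NULL) {
  stopifnot(subs_per_site >= 0)
  p_change <- 0.75 * (1 - exp(-4 * subs_per_site / 3))
  run <- function() {
    ch <- .chars(.as_seq_string(sequence))
    hit <- which(stats::runif(length(ch)) < p_change)
    if (length(hit)) {
      cur <- match(ch[hit], .BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      ch[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Random background sequence at a given GC (character vector of bases).
.random_bases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a genome with planted repeats and ground truth
#'
#' Builds a random background genome at the requested GC, plants each repeat
#' family at its target fraction (whole-copy rounding), mutating every copy
#' independently at the family divergence, and records exact truth intervals.
#' Dispersed copies are placed uniformly without overlap on a random strand;
#' tandem families are planted as head-to-tail arrays spread over `n_loci`
#' loci.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `planted_genome`: a list with `genome`
#'   (`DNAString`), `truth` (data.frame: `start`, `end` 0-based half-open,
#'   `family`, `class`, `strand`, `copy_id`, `divergence` realized per copy),
#'   `consensi` (`DNAStringSet` of the true family consensus sequences) and
#'   `spec`.
#' @examples
#' gs <- genome_spec(50000, list(family_spec("sat", "satellite", 169, 4.54, 0.08)))
#' pg <- plant_genome(gs)
#' @export
plant_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  G <- spec$genome_length
  with_seed(spec$seed, {
    genome <- .random_bases(G, spec$gc_background)
    consensi <- list()
    truth <- list()
    occupied <- IRanges::IRanges()
    # largest blocks first to ease non-overlap packing
    fams <- spec$families
    blocks <- list()
    for (f in fams) {
      cons <- .random_bases(f$unit_length, spec$gc_background)
      if (!is.null(f$domain_cassette)) {
        cass <- .chars(back_translate(f$domain_cassette))
        if (length(cass) > f$unit_length) {
          stop("domain cassette longer than unit for family '", f$name, "'")
        }
        at <- max(1L, (f$unit_length - length(cass)) %/% 2L)
        cons[at:(at + length(cass) - 1L)] <- cass
      }
      consensi[[f$name]] <- paste(cons, collapse = "")
      n_copies <- round(f$target_fraction / 100 * G / f$unit_length)
      if (n_copies == 0) next
      if (f$arrangement == "tandem") {
        n_loci <- min(f$n_loci, max(1L, n_copies %/% 2L))
        alloc <- as.vector(stats::rmultinom(1, n_copies, rep(1, n_loci)))
        alloc <- alloc[alloc > 0]
        for (a in alloc) {
          blocks[[length(blocks) + 1L]] <- list(
            family = f, len = a * f$unit_length, units = a, cons = cons)
        }
      } else {
        for (k in seq_len(n_copies)) {
          blocks[[length(blocks) + 1L]] <- list(
            family = f, len = f$unit_length, units = 1L, cons = cons)
        }
      }
    }
    if (length(blocks)) {
      ord <- order(vapply(blocks, function(b) b$len, numeric(1)),
                   decreasing = TRUE)
      copy_counter <- integer(0)
      for (b in blocks[ord]) {
        len <- b$len
        placed <- FALSE
        for (try in seq_len(2000L)) {
          st <- sample.int(G - len + 1L, 1L)
          cand <- IRanges::IRanges(st, st + len - 1L)
          if (length(occupied) == 0L ||
              sum(IRanges::countOverlaps(cand, occupied)) == 0L) {
            occupied <- c(occupied, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place a ", len, " nt block for family '",
               b$family$name, "'; genome too crowded")
        }
        f <- b$family
        strand <- sample(c("+", "-"), 1L)
        for (u in seq_len(b$units)) {
          cid <- (copy_counter[f$name] <- sum(copy_counter[f$name], 1L,
                                              na.rm = TRUE))
          mut <- .mutate_chars(b$cons, f$divergence)
          realized <- mean(mut != b$cons)
          if (strand == "-") {
            mut <- .chars(.revcomp_chr(paste(mut, collapse = "")))
          }
          at <- st + (u - 1L) * f$unit_length
          genome[at:(at + f$unit_length - 1L)] <- mut
          truth[[length(truth) + 1L]] <- data.frame(
            start = at - 1L, end = at - 1L + f$unit_length,
            family = f$name, class = f$class_label, strand = strand,
            copy_id = cid, divergence = realized)
        }
      }
    }
    truth_df <- if (length(truth)) {
      df <- do.call(rbind, truth)
      df[order(df$start), , drop = FALSE]
    } else {
      data.frame(start = integer(0), end = integer(0), family = character(0),
                 class = character(0), strand = character(0),
                 copy_id = integer(0), divergence = numeric(0))
    }
    rownames(truth_df) <- NULL
    cons_set <- Biostrings::DNAStringSet(unlist(consensi))
    if (length(cons_set)) {
      cls <- vapply(spec$families, function(f) f$class_label, character(1))
      tnd <- vapply(spec$families, function(f) f$arrangement == "tandem",
                    logical(1))
      S4Vectors::mcols(cons_set) <- S4Vectors::DataFrame(
        class = cls, tandem = tnd,
        period = ifelse(tnd, vapply(spec$families,
                                    function(f) f$unit_length, integer(1)), NA))
    }
    structure(list(genome = Biostrings::DNAString(paste(genome, collapse = "")),
                   truth = truth_df, consensi = cons_set, spec = spec),
              class = "planted_genome")
  })
}

#' @export
print.planted_genome <- function(x, ...) {
  cat("Planted genome:", length(x$genome), "nt,",
      length(x$spec$families), "families,", nrow(x$truth), "planted copies\n")
  if (nrow(x$truth)) {
    ab <- truth_abundance(x$truth, length(x$genome))
    print(ab)
  }
  invisible(x)
}

#' Planted genome fraction per family from truth intervals
#'
#' @param truth Truth data.frame from [plant_genome()].
#' @param genome_length Genome length in nt.
#' @return Data.frame with `family`, `class`, `copies`, `percent` (of the
#'   genome covered by merged truth intervals).
#' @export
truth_abundance <- function(truth, genome_length) {
  if (nrow(truth) == 0L) {
    return(data.frame(family = character(0), class = character(0),
                      copies = integer(0), percent = numeric(0)))
  }
  fams <- unique(truth$family)
  do.call(rbind, lapply(fams, function(fm) {
    sub <- truth[truth$family == fm, , drop = FALSE]
    data.frame(family = fm, class = sub$class[1], copies = nrow(sub),
               percent = 100 * .interval_coverage(sub) / genome_length)
  }))
}

#' Shear a genome into a low-pass read set
#'
#' Emulates random shearing: `round(coverage * genome_length / mean_len)`
#' reads with uniform start positions and strands; lengths are drawn from a
#' normal distribution truncated at `min_len` and clipped at the genome end.
#'
#' @param genome `DNAString`, character string, or `planted_genome`.
#' @param coverage Fold coverage (>= 0); the low-pass regime of interest is
#'   around 0.25.
#' @param mean_len Mean read length in nt (default 367).
#' @param sd_len Read-length standard deviation (default 37).
#' @param seed Integer seed.
#' @param min_len Minimum read length (default 50).
#' @return A named `DNAStringSet`; `S4Vectors::mcols()` carries the
#'   provenance (`start` 0-based, `end`, `strand`).
#' @export
shear_reads <- function(genome, coverage, mean_len = 367, sd_len = 37,
                        seed = 1L, min_len = 50L) {
  if (inherits(genome, "planted_genome")) genome <- genome$genome
  gs <- .as_seq_string(genome)
  G <- nchar(gs)
  stopifnot(coverage >= 0, mean_len >= 50)
  n <- round(coverage * G / mean_len)
  if (n == 0L) {
    rs <- Biostrings::DNAStringSet()
    return(rs)
  }
  with_seed(seed, {
    starts <- sample.int(G, n, replace = TRUE)
    lens <- pmax(min_len, round(stats::rnorm(n, mean_len, sd_len)))
    ends <- pmin(G, starts + lens - 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(gs, starts, ends)
    rs <- Biostrings::DNAStringSet(seqs)
    neg <- strand == "-"
    if (any(neg)) rs[neg] <- Biostrings::reverseComplement(rs[neg])
    names(rs) <- sprintf("read_%06d", seq_len(n))
    S4Vectors::mcols(rs) <- S4Vectors::DataFrame(
      start = starts - 1L, end = ends, strand = strand)
    rs
  })
}

#' Write truth annotations as a BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), family, strand, copy_id,
#' divergence.
#'
#' @param truth Truth data.frame from [plant_genome()].
#' @param path Output path.
#' @param chrom Chromosome name to record (default `"genome"`).
#' @export
write_truth_bed <- function(truth, path, chrom = "genome") {
  df <- data.frame(chrom = chrom, start = truth$start, end = truth$end,
                   family = truth$family, strand = truth$strand,
                   copy_id = truth$copy_id, divergence = truth$divergence)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read truth annotations written by [write_truth_bed()]
#'
#' @param path Input path.
#' @return Data.frame with the BED-like columns.
#' @export
read_truth_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "family",
                                        "strand", "copy_id", "divergence"))
  df
}
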