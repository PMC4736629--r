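# De novo repeat discovery: l-mer counting, seed extension, filters,
# overlap assembly and identity clustering.

test_that("count_lmers counts canonical l-mers like a brute-force oracle", {
  reads <- c("ACGTACGTA", "GGGGTTTAC")
  l <- 4
  got <- count_lmers(reads, l)
  # oracle: enumerate windows, canonicalize by string reverse complement
  canon <- character(0)
  for (s in reads) {
    for (i in 1:(nchar(s) - l + 1)) {
      w <- substr(s, i, i + l - 1)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
      canon <- c(canon, min(w, rc))
    }
  }
  exp <- table(canon)
  expect_equal(sum(got), length(canon))
  expect_setequal(names(got), names(exp))
  expect_equal(as.integer(got[names(exp)]), as.integer(exp))
  # sorted by decreasing count
  expect_true(all(diff(as.integer(got)) <= 0))
})

test_that("count_lmers merges a window with its reverse complement", {
  got <- count_lmers("ACGTACGT", 4)
  # windows: ACGT CGTA GTAC ACGT CGTA; canonical(CGTA)=CGTA? rc(CGTA)=TACG,
  # min("CGTA","TACG")="CGTA"; canonical(GTAC)=GTAC (rc = GTAC, palindrome)
  expect_equal(unname(got["ACGT"]), 2L)
  expect_equal(unname(got["CGTA"]), 2L)
  expect_equal(unname(got["GTAC"]), 1L)
  expect_equal(length(got), 3L)
})

test_that("extend_seed recovers a planted element from reads", {
  set.seed(31)
  element <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mkread <- function() {
    left <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    paste0(left, mutate_copy(element, 0.05), right)
  }
  reads <- vapply(1:12, function(i) mkread(), "")
  seed <- substr(element, 140, 151)
  cand <- extend_seed(seed, reads)
  expect_gte(cand$length, 250)
  expect_lte(cand$length, 350)
  h <- local_align(cand$consensus, element)
  expect_gt(h$identity, 0.9)
  expect_gt((h$subject_end - h$subject_start) / 300, 0.8)
})

test_that("extension stops at the element boundary into random background", {
  set.seed(32)
  element <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  reads <- vapply(1:10, function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
           element,
           paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""))
  }, "")
  cand <- extend_seed(substr(element, 95, 106), reads)
  # must not grow far into the 150 nt random flanks
  expect_lte(cand$length, 260)
  expect_gte(cand$length, 160)
})

test_that("filter_candidates applies the length, copy and entropy rules", {
  cands <- data.frame(
    id = c("short", "fewcopies", "lowcomp", "good", "boundary"),
    consensus = c(strrep("ACGT", 20),          # 80 nt < 100
                  strrep("ACGTT", 30),         # 150 nt, 5 copies
                  strrep("AT", 75),            # 150 nt dinucleotide repeat
                  paste(rep(c("ACGTA", "GTCCA", "TTAGC"), 10), collapse = ""),
                  strrep("ACGGT", 30)),        # exactly 10 copies
    length = c(80L, 150L, 150L, 150L, 150L),
    n_occ = c(50L, 5L, 50L, 50L, 10L),
    stringsAsFactors = FALSE)
  kept <- filter_candidates(cands)
  expect_equal(kept$id, "good")
  # strictly more than 10 copies required: 11 passes
  cands$n_occ[5] <- 11L
  kept2 <- filter_candidates(cands)
  expect_setequal(kept2$id, c("good", "boundary"))
})

test_that("assemble_candidates merges overlapping fragments of one element", {
  set.seed(33)
  element <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  a <- substr(element, 1, 550)
  b <- substr(element, 251, 800) # 300 nt identical overlap, score 600 >= 500
  cands <- data.frame(id = c("a", "b"), consensus = c(a, b),
                      length = c(550L, 550L), n_occ = c(20L, 20L),
                      stringsAsFactors = FALSE)
  merged <- assemble_candidates(cands)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$consensus, element)
  # fragments without an admissible overlap stay separate
  c2 <- data.frame(id = c("a", "b"),
                   consensus = c(substr(element, 1, 300),
                                 substr(element, 401, 800)),
                   length = c(300L, 400L), n_occ = c(20L, 20L),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(assemble_candidates(c2)), 2)
})

test_that("cluster_library keeps one representative per 80% identity group", {
  set.seed(34)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  variant <- mutate_copy(base, 0.1) # ~90% identity to base
  cands <- data.frame(id = c("base", "variant", "other"),
                      consensus = c(base, variant, other),
                      length = c(400L, 400L, 400L),
                      n_occ = c(30L, 20L, 10L), stringsAsFactors = FALSE)
  cl <- cluster_library(cands)
  expect_equal(nrow(cl$representatives), 2)
  expect_setequal(cl$representatives$id, c("base", "other"))
  expect_equal(
    cl$membership$representative[cl$membership$member == "variant"], "base")
  # a minus-strand variant clusters too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(base)))
  cands$consensus[3] <- rc
  cl2 <- cluster_library(cands)
  expect_equal(nrow(cl2$representatives), 1)
})

test_that("discover_repeats recovers planted families from low-pass reads", {
  fams <- list(
    family_spec("eleA", "Ty1-copia", 600, 8, divergence = 0.05),
    family_spec("eleB", "DNA-TE", 400, 6, divergence = 0.05))
  gs <- genome_spec(3e5, fams, seed = 51)
  pg <- plant_genome(gs)
  reads <- shear_reads(pg$genome, 0.6, seed = 52)
  lib <- discover_repeats(reads)
  expect_s3_class(lib, "repeat_library")
  expect_gte(nrow(lib$library), 1)
  expect_true(all(lib$library$length > 100))
  expect_true(all(lib$library$n_occ > 10))
  # every planted family is covered >=60% by some library entry
  for (fam in c("eleA", "eleB")) {
    cons <- as.character(pg$consensi[[fam]])
    best_cov <- 0
    for (s in as.character(lib$sequences)) {
      h <- local_align(s, cons)
      best_cov <- max(best_cov, (h$subject_end - h$subject_start) / nchar(cons))
    }
    expect_gt(best_cov, 0.6)
  }
})

test_that("discovery reports no library entries for repeat-free reads", {
  gs <- genome_spec(2e5, list(), seed = 53)
  pg <- plant_genome(gs)
  reads <- shear_reads(pg$genome, 0.4, seed = 54)
  lib <- discover_repeats(reads)
  expect_equal(nrow(lib$library), 0)
})
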