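# Paralog phylogenetics: translated mining, progressive alignment, K2P
# distances, neighbor joining, bootstrap supports and clock dating.

domain_reads <- function(divs, seed = 101, aa_len = 100) {
  set.seed(seed)
  aa <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                       "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                     aa_len, TRUE), collapse = "")
  nt <- back_translate(aa)
  rs <- Biostrings::DNAStringSet(vapply(divs, function(d) {
    core <- evolve_sequence(nt, d)
    paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
           core,
           paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""))
  }, ""))
  names(rs) <- paste0("r", seq_along(divs))
  list(aa = aa, nt = nt, reads = rs)
}

test_that("mine_paralogs finds in-frame tracts across all six frames", {
  fx <- domain_reads(rep(0.02, 3))
  # shift each read by 0..2 nt and reverse-complement one to hit other frames
  reads <- fx$reads
  shifted <- Biostrings::DNAStringSet(c(
    as.character(reads[[1]]),
    paste0("G", as.character(reads[[2]])),
    as.character(Biostrings::reverseComplement(reads[[3]]))))
  names(shifted) <- c("plain", "shift1", "revcomp")
  tr <- mine_paralogs(shifted, fx$aa)
  expect_s3_class(tr, "paralog_tracts")
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$coverage >= 80))
  expect_true(all(tr$evalue < 1e-5))
  expect_lt(tr$frame[tr$read == "revcomp"], 0)
  # nt tract translates back to the aa tract (in-frame extraction)
  for (i in seq_len(nrow(tr))) {
    taa <- as.character(Biostrings::translate(
      Biostrings::DNAString(tr$nt[i]), if.fuzzy.codon = "X"))
    expect_equal(taa, tr$aa[i])
  }
})

test_that("mine_paralogs rejects unrelated reads and low coverage", {
  fx <- domain_reads(c(0.02, 0.02))
  set.seed(102)
  junk <- paste(sample(c("A", "C", "G", "T"), 380, TRUE), collapse = "")
  reads <- c(fx$reads, Biostrings::DNAStringSet(c(junk = junk)))
  tr <- mine_paralogs(reads, fx$aa)
  expect_false("junk" %in% tr$read)
  # a read carrying only 40 residues of the domain misses the 80 aa floor
  short <- paste0(substr(fx$nt, 1, 120),
                  paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  tr2 <- mine_paralogs(Biostrings::DNAStringSet(c(s = short)), fx$aa)
  expect_equal(nrow(tr2), 0)
})

test_that("align_tracts on two sequences equals the optimal pairwise DP", {
  a <- "MKWVTFISLL"
  b <- "MKWTFISLL" # one deletion
  msa <- align_tracts(c(x = a, y = b), gap = 4)
  expect_equal(length(msa), 2)
  expect_equal(Biostrings::width(msa)[1], Biostrings::width(msa)[2])
  # removing gaps restores the inputs
  expect_equal(gsub("-", "", as.character(msa[["x"]])), a)
  expect_equal(gsub("-", "", as.character(msa[["y"]])), b)
  # score of the produced alignment equals pairwiseAlignment's optimum
  data("BLOSUM62", package = "Biostrings", envir = environment())
  cols <- cbind(strsplit(as.character(msa[["x"]]), "")[[1]],
                strsplit(as.character(msa[["y"]]), "")[[1]])
  sc <- sum(apply(cols, 1, function(cc) {
    if (any(cc == "-")) -4 else BLOSUM62[cc[1], cc[2]]
  }))
  opt <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 0, gapExtension = 4))
  expect_equal(sc, opt)
})

test_that("progressive alignment preserves sequences and input order", {
  fx <- domain_reads(c(0.01, 0.05, 0.1, 0.15, 0.2), seed = 103)
  tr <- mine_paralogs(fx$reads, fx$aa)
  msa <- align_tracts(tr)
  expect_equal(names(msa), tr$id)
  expect_equal(length(unique(Biostrings::width(msa))), 1)
  for (i in seq_along(msa)) {
    expect_equal(gsub("-", "", as.character(msa[[i]])), tr$aa[i])
  }
})

test_that("k2p_distance matches the closed form on hand-built cases", {
  # 100 sites: 10 transitions, 5 transversions -> P=0.10, Q=0.05
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  K <- k2p_distance(a, b)
  expect_equal(K, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)),
               tolerance = 1e-12)
  expect_equal(round(K, 4), 0.1702)
  # transversions only: P=0, Q=0.05
  b2 <- paste0(strrep("C", 5), strrep("A", 95))
  expect_equal(k2p_distance(a, b2),
               -0.5 * log(0.95 * sqrt(0.90)), tolerance = 1e-12)
  expect_equal(round(k2p_distance(a, b2), 4), 0.0520)
  expect_equal(k2p_distance(a, a), 0)
  # gap and N columns are excluded
  expect_equal(k2p_distance("AC-GN", "ACTGA"), 0)
  expect_error(k2p_distance("---", "---"), "no comparable")
  # saturation returns NA with a warning
  expect_warning(ks <- k2p_distance(strrep("A", 10), strrep("C", 10)))
  expect_true(is.na(ks))
})

test_that("k2p_distance agrees with ape::dist.dna K80", {
  set.seed(104)
  for (rep in 1:5) {
    s1 <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    s2 <- mutate_copy(s1, 0.12)
    m <- rbind(strsplit(tolower(s1), "")[[1]], strsplit(tolower(s2), "")[[1]])
    rownames(m) <- c("a", "b")
    expect_equal(k2p_distance(s1, s2),
                 as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80")),
                 tolerance = 1e-12)
  }
})

test_that("nj_tree matches brute-force least-squares topology selection", {
  # additive distances on ((A,B),(C,D)): internal edge 1, tips 1,2,3,4
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- 3; dm["A", "C"] <- 5; dm["A", "D"] <- 6
  dm["B", "C"] <- 6; dm["B", "D"] <- 7; dm["C", "D"] <- 7
  dm <- dm + t(dm)
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
  # oracle: evaluate all three 4-taxon topologies by least-squares edge
  # fitting (phangorn::nnls.tree); an additive matrix is fit exactly only
  # by the true topology
  fit <- vapply(list(
    ape::read.tree(text = "((A,B),(C,D));"),
    ape::read.tree(text = "((A,C),(B,D));"),
    ape::read.tree(text = "((A,D),(B,C));")), function(t0) {
      f <- phangorn::nnls.tree(as.dist(dm), ape::unroot(t0),
                               method = "unrooted")
      sum((as.matrix(ape::cophenetic.phylo(f))[LETTERS[1:4], LETTERS[1:4]] -
             dm)^2)
    }, numeric(1))
  best <- which.min(fit)
  expect_equal(best, 1L)
  # nj recovered the oracle's best topology
  expect_equal(ape::dist.topo(
    ape::unroot(ape::read.tree(text = "((A,B),(C,D));")),
    ape::unroot(tr))[[1]], 0)
  # and recovers the additive path lengths exactly
  co <- as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, dm, tolerance = 1e-9)
})

test_that("nj_tree recovers random additive 6-taxon trees", {
  set.seed(105)
  for (rep in 1:5) {
    t0 <- ape::rtree(6, rooted = FALSE)
    t0$edge.length <- runif(nrow(t0$edge), 0.1, 1)
    dm <- as.matrix(ape::cophenetic.phylo(t0))
    tr <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(t0),
                                           ape::unroot(tr))), 0)
  }
})

test_that("negative NJ branch lengths are clamped without breaking paths", {
  # a non-additive matrix known to induce a negative NJ edge
  dm <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 2,
                 9, 10, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 0.5 # force distortion
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic and bounded", {
  fx <- domain_reads(c(0.01, 0.03, 0.1, 0.3, 0.32, 0.6), seed = 106)
  tr <- mine_paralogs(fx$reads, fx$aa)
  msa <- align_tracts(tr)
  b1 <- bootstrap_support(msa, n_replicates = 100, seed = 9)
  b2 <- bootstrap_support(msa, n_replicates = 100, seed = 9)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 100))
  expect_equal(length(b1$node.label), b1$Nnode)
})

test_that("date_split is linear in K and reproduces hand values", {
  expect_equal(date_split(0.13), 1)
  expect_equal(date_split(1.17), 9)
  expect_equal(date_split(0.26), 2 * date_split(0.13))
  expect_equal(date_split(0.13, rate = 1.3e-8), 5)
  expect_error(date_split(-1))
})

test_that("a planted 10-mya clock is recovered within 15 percent", {
  # two subclades diverged 10 mya at r = 6.5e-8: each branch accumulates
  # d = r * 1e7 = 0.65 substitutions/site... scaled down: use 10 mya total
  # K = 2 * r * T = 1.3 per site is saturated; instead plant T such that
  # K = 0.13 (T = 1 mya equivalent scaled x10 via rate) — here we check the
  # estimator: evolve both lineages d = K/2 each and date with the same rate.
  set.seed(107)
  anc <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  r <- 6.5e-9 # slower clock keeps a 10-mya split unsaturated
  T_true <- 10e6
  d <- r * T_true # per-lineage substitutions/site = 0.065
  a <- evolve_sequence(anc, d)
  b <- evolve_sequence(anc, d)
  K <- k2p_distance(a, b)
  T_hat <- date_split(K, rate = r)
  expect_equal(T_hat, 10, tolerance = 0.15)
})

test_that("subclade_split_times dates all pairs and excludes saturation", {
  set.seed(108)
  anc <- back_translate(paste(sample(c("A", "R", "N", "D", "G", "H", "I", "L",
                                       "K", "M", "F", "P", "S", "T", "V"),
                                     100, TRUE), collapse = ""))
  cla <- vapply(1:3, function(i) evolve_sequence(anc, 0.02), "")
  clb <- vapply(1:2, function(i) evolve_sequence(anc, 0.08), "")
  names(cla) <- paste0("a", 1:3); names(clb) <- paste0("b", 1:2)
  cd <- subclade_split_times(cla, clb)
  expect_s3_class(cd, "clade_dating")
  expect_equal(cd$n_pairs + cd$n_saturated, 6)
  expect_equal(nrow(cd$pairs), cd$n_pairs)
  expect_true(all(cd$pairs$T_mya >= 0))
  expect_equal(cd$mean_mya, mean(cd$pairs$T_mya))
  # expected K around 0.02 + 0.08 = 0.10 -> ~0.77 mya at the default rate
  expect_equal(cd$mean_mya, date_split(0.1), tolerance = 0.35)
})
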