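# Satellite characterization: monomer extraction, pairwise statistics,
# conservation profiles, monomer inference and digest ladders.

sat_fixture <- function(seed = 91, genome_length = 3e5, coverage = 1) {
  fam <- family_spec("sat", "satellite", 169, 4.54, divergence = 0.08)
  gs <- genome_spec(genome_length, list(fam), seed = seed)
  pg <- plant_genome(gs)
  list(pg = pg,
       mono = as.character(pg$consensi[["sat"]]),
       reads = shear_reads(pg$genome, coverage, seed = seed + 1))
}

test_that("extract_monomers harvests full-length phased copies", {
  fx <- sat_fixture()
  ms <- extract_monomers(fx$reads, fx$mono)
  expect_s3_class(ms, "monomer_set")
  expect_gt(length(ms$copies), 20)
  w <- Biostrings::width(ms$copies)
  expect_true(all(w >= 0.9 * 169 & w <= 1.1 * 169))
  # copies resemble the planted consensus at the planted divergence
  ids <- vapply(as.character(ms$copies), function(s) {
    if (nchar(s) != 169) return(NA_real_)
    mean(strsplit(s, "")[[1]] == strsplit(fx$mono, "")[[1]])
  }, numeric(1))
  expect_equal(mean(ids, na.rm = TRUE), 0.92, tolerance = 0.03)
})

test_that("max_copies subsampling is seeded and bounded", {
  fx <- sat_fixture()
  a <- extract_monomers(fx$reads, fx$mono, max_copies = 10, seed = 3)
  b <- extract_monomers(fx$reads, fx$mono, max_copies = 10, seed = 3)
  expect_equal(length(a$copies), 10)
  expect_identical(as.character(a$copies), as.character(b$copies))
})

test_that("monomer_stats reports identity, lengths, GC and partners", {
  fx <- sat_fixture()
  ms <- extract_monomers(fx$reads, fx$mono)
  st <- monomer_stats(ms)
  expect_equal(st$consensus_length, 169)
  expect_true(st$length_range[1] >= 150 && st$length_range[2] <= 190)
  # two copies at 8% divergence from a shared consensus are ~85% identical
  expect_equal(st$mean_pairwise_identity, 85, tolerance = 3)
  expect_gt(st$identity_to_consensus, st$mean_pairwise_identity)
  expect_true(st$partner_count >= 0 && st$partner_count <= st$n)
  expect_equal(dim(st$identity_matrix), c(st$n, st$n))
})

test_that("partner counting uses a strict threshold against an oracle", {
  copies <- Biostrings::DNAStringSet(c(
    a = strrep("ACGGT", 20),          # identical pair: identity 1
    b = strrep("ACGGT", 20),
    c = paste0(strrep("ACGGT", 19), "ACGTT"),  # 98% to a/b
    d = strrep("TTACG", 20)))         # unrelated
  st <- monomer_stats(copies, partner_identity = 0.94)
  # brute-force oracle over equal-length ungapped identity
  chr <- lapply(as.character(copies), function(s) strsplit(s, "")[[1]])
  n <- 4
  idm <- diag(1, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    idm[i, j] <- idm[j, i] <- mean(chr[[i]] == chr[[j]])
  }
  oracle <- sum(apply(idm + diag(-Inf, n), 1, max) > 0.94)
  expect_equal(st$partner_count, oracle)
  # exactly at the threshold does not count (strict >)
  two <- Biostrings::DNAStringSet(c(
    x = strrep("A", 100), y = paste0(strrep("A", 94), strrep("C", 6))))
  expect_equal(monomer_stats(two, partner_identity = 0.94)$partner_count, 0)
})

test_that("conservation_profile matches per-column frequency arithmetic", {
  copies <- Biostrings::DNAStringSet(c(
    strrep("ACGT", 30), strrep("ACGT", 30),
    paste0("T", substr(strrep("ACGT", 30), 2, 120))))
  cp <- conservation_profile(copies)
  expect_equal(dim(cp$freq), c(4L, 120L))
  expect_true(all(abs(colSums(cp$freq) - 1) < 1e-12))
  # column 1: A,A,T -> p = (2/3, 1/3); info = 2 - H
  h1 <- -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3))
  expect_equal(cp$information[1], 2 - h1, tolerance = 1e-12)
  # fully conserved column carries 2 bits
  expect_equal(cp$information[2], 2)
  # perfectly conserved set: all columns 2 bits
  same <- Biostrings::DNAStringSet(rep(strrep("ACGT", 30), 5))
  expect_true(all(conservation_profile(same)$information == 2))
})

test_that("infer_monomer recovers the planted period and consensus de novo", {
  fx <- sat_fixture()
  inf <- infer_monomer(fx$reads)
  expect_equal(inf$period, 169)
  # best rotation of the inferred consensus matches the planted monomer
  rot <- repeatome:::.best_rotation(inf$consensus, fx$mono)
  id <- mean(strsplit(rot, "")[[1]] == strsplit(fx$mono, "")[[1]])
  expect_gt(id, 0.95)
})

test_that("digest ladders conserve length and show the monomer-period rungs", {
  set.seed(92)
  site <- "GAATTC"
  base <- paste(sample(c("A", "C", "G", "T"), 169, TRUE), collapse = "")
  base <- gsub(site, "GAATTA", base, fixed = TRUE) # no accidental sites
  # plant exactly one site per monomer, none elsewhere
  mono <- paste0(substr(base, 1, 80), site, substr(base, 87, 169))
  fl <- strrep("CT", 32)  # 64 nt, site-free
  fr <- strrep("GA", 67)  # 134 nt, site-free
  frags <- digest_ladder(mono, 10, flank_left = fl, flank_right = fr,
                         site = site)
  expect_equal(sum(frags), 64 + 10 * 169 + 134)
  # interior rungs all equal the monomer length: {flank+offset, 169 x 9, rest}
  expect_equal(sort(table(frags), decreasing = TRUE)[[1]], 9)
  expect_equal(as.integer(names(which.max(table(frags)))), 169)
  # blocking all sites yields a single fragment
  whole <- digest_ladder(mono, 10, flank_left = fl, flank_right = fr,
                         site = site, blocked_fraction = 1)
  expect_equal(whole, sum(frags))
  # blocking is seeded
  p1 <- digest_ladder(mono, 30, site = site, blocked_fraction = 0.5, seed = 7)
  p2 <- digest_ladder(mono, 30, site = site, blocked_fraction = 0.5, seed = 7)
  expect_identical(p1, p2)
})

test_that("non-palindromic sites are cut on both strands", {
  # site GACGTG is non-palindromic; its reverse complement CACGTC on the
  # forward strand marks a minus-strand site
  s <- paste0(strrep("T", 50), "GACGTG", strrep("T", 50), "CACGTC",
              strrep("T", 50))
  frags <- digest_ladder(s, 1, site = "GACGTG")
  expect_equal(length(frags), 3)
  expect_equal(sum(frags), nchar(s))
})
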