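# Synthetic genome simulator: planted fractions, truth bookkeeping,
# mutation models and read shearing.

test_that("family and genome specs validate their inputs", {
  expect_error(family_spec("x", "nonsense", 100, 1))
  expect_error(family_spec("x", "satellite", 100, 1, divergence = 0.6))
  f <- family_spec("sat", "satellite", 169, 4.54, 0.08)
  expect_equal(f$arrangement, "tandem")
  g <- family_spec("g", "Ty3-gypsy", 1500, 6)
  expect_equal(g$arrangement, "dispersed")
  expect_error(genome_spec(1e5, list(family_spec("a", "other", 100, 60),
                                     family_spec("b", "other", 100, 50))),
               "exceeds 100")
  expect_error(genome_spec(1000, list(family_spec("a", "other", 5000, 1))))
})

test_that("planted truth matches the genome sequence exactly", {
  gs <- genome_spec(60000, list(
    family_spec("ele", "Ty1-copia", 400, 4, divergence = 0),
    family_spec("sat", "satellite", 169, 3, divergence = 0)), seed = 3)
  pg <- plant_genome(gs)
  gchr <- as.character(pg$genome)
  for (i in seq_len(nrow(pg$truth))) {
    tr <- pg$truth[i, ]
    planted <- substr(gchr, tr$start + 1, tr$end)
    cons <- as.character(pg$consensi[[tr$family]])
    if (tr$strand == "-") {
      cons <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cons)))
    }
    # zero divergence: the planted copy equals the (oriented) consensus
    expect_equal(planted, cons)
  }
})

test_that("planted fractions hit their targets within rounding", {
  gs <- genome_spec(2e5, list(
    family_spec("ele", "Ty1-copia", 500, 5, divergence = 0.08),
    family_spec("sat", "satellite", 169, 4.54, divergence = 0.08)), seed = 8)
  pg <- plant_genome(gs)
  ab <- truth_abundance(pg$truth, 2e5)
  expect_equal(ab$percent[ab$family == "ele"], 5, tolerance = 0.05)
  expect_equal(ab$percent[ab$family == "sat"], 4.54, tolerance = 0.05)
  # truth intervals never overlap
  o <- merge_intervals(pg$truth[, c("start", "end")])
  expect_equal(sum(o$end - o$start), sum(pg$truth$end - pg$truth$start))
})

test_that("plant_genome is deterministic in the spec seed", {
  gs <- genome_spec(30000, list(family_spec("s", "satellite", 169, 4, 0.08)),
                    seed = 21)
  a <- plant_genome(gs)
  b <- plant_genome(gs)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
})

test_that("mutate_copy realizes the requested divergence in expectation", {
  set.seed(10)
  cons <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  mut <- mutate_copy(cons, 0.08)
  d <- mean(strsplit(cons, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(d - 0.08), 0.01)
  expect_identical(mutate_copy(cons, 0), cons)
  expect_identical(mutate_copy(cons, 0.1, seed = 4),
                   mutate_copy(cons, 0.1, seed = 4))
})

test_that("evolve_sequence follows the Jukes-Cantor expectation", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  d <- 0.3
  e <- evolve_sequence(s, d)
  p_obs <- mean(strsplit(s, "")[[1]] != strsplit(e, "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_equal(p_obs, p_exp, tolerance = 0.02)
})

test_that("back_translate uses one fixed codon per residue", {
  expect_equal(back_translate("MK"), "ATGAAA")
  expect_equal(nchar(back_translate("ACDEFGHIKLMNPQRSTVWY")), 60)
  tr <- as.character(Biostrings::translate(
    Biostrings::DNAString(back_translate("ACDEFGHIKLMNPQRSTVWY"))))
  expect_equal(tr, "ACDEFGHIKLMNPQRSTVWY")
  expect_error(back_translate("MKZ"), "unknown amino acid")
})

test_that("shear_reads draws the expected number and length of reads", {
  gs <- genome_spec(1e6, list(), seed = 2)
  pg <- plant_genome(gs)
  reads <- shear_reads(pg$genome, 2, mean_len = 367, sd_len = 37, seed = 5)
  expect_equal(length(reads), round(2 * 1e6 / 367)) # 5450
  expect_equal(mean(Biostrings::width(reads)), 367, tolerance = 0.02)
  expect_true(all(Biostrings::width(reads) >= 50))
  # provenance maps each read back onto the genome
  mc <- S4Vectors::mcols(reads)
  gchr <- as.character(pg$genome)
  for (i in sample(length(reads), 25)) {
    seg <- substr(gchr, mc$start[i] + 1, mc$end[i])
    r <- as.character(reads[[i]])
    if (mc$strand[i] == "-") {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    }
    expect_equal(r, seg)
  }
})

test_that("realized coverage approximates the requested coverage", {
  gs <- genome_spec(5e5, list(), seed = 9)
  pg <- plant_genome(gs)
  reads <- shear_reads(pg$genome, 0.25, seed = 14)
  cov <- sum(Biostrings::width(reads)) / 5e5
  expect_equal(cov, 0.25, tolerance = 0.05)
})

test_that("truth BED round-trips through disk", {
  gs <- genome_spec(30000, list(family_spec("s", "satellite", 169, 4, 0.08)),
                    seed = 21)
  pg <- plant_genome(gs)
  path <- tempfile(fileext = ".bed")
  write_truth_bed(pg$truth, path)
  back <- read_truth_bed(path)
  expect_equal(back$start, pg$truth$start)
  expect_equal(back$end, pg$truth$end)
  expect_equal(back$family, pg$truth$family)
  expect_equal(back$strand, pg$truth$strand)
  unlink(path)
})

test_that("the default family sets sum to their documented totals", {
  fams <- default_repeat_families()
  tot <- sum(vapply(fams, function(f) f$target_fraction, numeric(1)))
  expect_equal(tot, 27.46)
  ltr <- ltr_family_set()
  expect_equal(sum(vapply(ltr, function(f) f$target_fraction, numeric(1))),
               14.96)
  expect_true(all(vapply(ltr, function(f) f$unit_length, integer(1)) >= 1000))
  expect_true(all(vapply(ltr, function(f) f$unit_length, integer(1)) <= 8000))
})
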