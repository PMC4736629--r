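---
title: "Methods: low-pass repeatome characterization with repeatome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-pass repeatome characterization with repeatome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`repeatome` characterizes the repetitive fraction of a plant genome from a
shallow random shotgun sample of unassembled reads (around 0.25× coverage).
The statistical premise is simple: if read start positions are uniform over
the genome, the fraction of sampled nucleotides belonging to a repeat family
is an unbiased estimator of that family's genomic fraction. Everything in
the package either builds a repeat library from the reads, or measures what
fraction of the reads the library masks.

The pipeline has five stages:

1. **Discovery** (`discover_repeats()`): frequent l-mer seeding and greedy
   consensus extension recover family consensi directly from reads.
2. **Filtering and library construction** (`filter_candidates()`,
   `assemble_candidates()`, `cluster_library()`): length, copy-number and
   complexity filters; overlap assembly of fragmented candidates;
   greedy identity clustering into representatives.
3. **Annotation** (`classify_repeat()`, `detect_tandem()`,
   `annotate_library()`): similarity classification against labelled
   exemplars, with translated search as a fallback, plus tandem-structure
   detection.
4. **Abundance** (`mask_reads()`, `abundance()`, `copy_number()`,
   `completeness()`): masking-based genome-fraction estimation.
5. **Specialized analyses**: satellite monomer work
   (`extract_monomers()`, `monomer_stats()`, `conservation_profile()`,
   `infer_monomer()`, `digest_ladder()`) and paralog phylogenetics
   (`mine_paralogs()`, `align_tracts()`, `k2p_distance()`, `nj_tree()`,
   `bootstrap_support()`, `date_split()`, `subclade_split_times()`).

A synthetic-genome simulator (`plant_genome()`, `shear_reads()`) with exact
planted truth is a first-class part of the package: every stage is validated
against genomes whose repeat content is known by construction.

## The synthetic generator and its realism limits

`plant_genome()` builds a uniform-random background at a configurable GC
(default 0.44), then plants each `family_spec()` at its target genome
fraction using whole-copy rounding. Dispersed families are placed uniformly
at random without overlap (rejection sampling), on a random strand per
copy. Tandem (satellite) families are planted as head-to-tail arrays whose
copies are multinomially allocated over `n_loci` loci. Each copy is
independently mutated at the family divergence — substitutions only, uniform
over the three alternative bases — so the expected identity of a copy to its
consensus is `1 - divergence`, and the expected identity between two copies
is about `(1 - divergence)^2`.

Deliberate simplifications, and what they mean for interpretation:

* **No indels within copies.** Planted copies differ from their consensus
  by substitutions only. Alignment-based stages all tolerate gaps, but the
  simulator does not exercise indel-rich degradation, nested insertions, or
  truncated elements.
* **Uniform background.** Real intergenic sequence has compositional
  structure (isochores, low-complexity runs) that can seed spurious
  candidates; a uniform background makes the discovery false-positive test
  cleaner but easier than reality.
* **Uniform shearing.** `shear_reads()` draws read starts uniformly and
  lengths from a truncated normal (mean 367, sd 37, minimum 50), matching
  the read-length regime of classic shotgun sanger libraries. No cloning or
  GC bias is simulated.
* **Scaled unit lengths.** `default_repeat_families()` uses element lengths
  of 0.4–1.5 kb rather than full-length 5–10 kb retroelements so that, on
  the megabase-scale genomes used in examples and tests, each family's copy
  number stays in the medium/high-copy regime (tens of copies) that
  read-based discovery targets; with full-length elements at the same
  genome fractions, per-family copy numbers would fall below the strict
  copy-number filter for any desk-scale genome. `ltr_family_set()` keeps
  realistic 2–7 kb lengths for exemplar-based masking experiments, where
  low copy number is not a problem. Minor repeat classes below roughly half
  a percent are folded into the two `"other"` families rather than planted
  individually.

## Discovery: seeds, extension, filters

Reads are indexed by canonical l-mers (the lexicographic minimum of each
window and its reverse complement), encoded 2 bits per base into doubles.
The seed length defaults to `ceil(log4(total read nt)) + 1`, clamped to
10–14 — the usual scaling that makes a random l-mer expected to occur about
once. Seeds are visited in decreasing frequency order (minimum count 4 by
default; at 0.25× coverage even a high-copy family yields only a handful of
exact l-mer matches, which is why the threshold is low). Read positions
consumed by earlier candidates are not re-seeded.

Extension is greedy and fit-preferred, one column at a time on each side of
the seed: the consensus base is the majority over occurrences still
aligned; an occurrence is dropped once its running agreement score (+1
match, −1 mismatch) falls more than `c_penalty` below its own maximum, so a
subfamily that diverges from the majority stops contributing rather than
degrading the consensus. A side stops extending by an X-drop rule on the
cumulative, cost-adjusted gain (each column's net agreement minus
`col_cost`), and the consensus is trimmed back to the cumulative maximum —
the boundary where overall agreement peaked. The per-column cost makes
extension into sequence whose agreement is at chance level run downhill,
which pins consensus ends at element boundaries; extension also stops
outright when fewer than two occurrences survive, since a lone occurrence
is no longer evidence of repetition.

Candidates then pass three filters: length at least 100 nt, copy number
strictly greater than 10, and a dinucleotide Shannon-entropy floor that
removes microsatellite and low-complexity artifacts. Because exact seed
occurrences undercount diverged copies, a candidate that passes the length
and entropy predicates but falls at or below the copy threshold on its
exact seed-match count is given a second chance: its support is recounted
as the number of reads carrying an admissible local hit (identity ≥ 0.7
over ≥ 30 nt) — the same notion of a copy that the masking stage uses.
Candidate–read pairs for the recount are prefiltered by two distinct
shared 11-mers (the BLAST two-hit seeding rule) and counting stops once
the threshold is exceeded, which is the only question the filter asks.

Fragmented candidates are merged by ends-free overlap alignment under an
assembly-style scoring (match +2, mismatch −5, gap −6/−1) requiring at
least 30 overlap columns at 80% identity and an overlap score of 500; the
library is finally clustered greedily at 80% identity over the shorter
sequence (length-sorted, both strands), cd-hit style, keeping one
representative per cluster. The clustering identity is computed from the
best local alignment, which approximates (from below) the global-overlap
identity the threshold notionally refers to; at the 80% level the two
rarely disagree for near-full-length variants.

## Masking and abundance

`mask_reads()` collects every admissible local hit (identity ≥ 0.7,
length ≥ 30 nt, both strands) of every library entry against every read,
re-searching the unmasked flanks of each read so multiple family copies per
read are found. Entries flagged as tandem are tiled head-to-tail beyond the
longest read length first, so a single local hit can span an entire
in-read satellite array instead of fragmenting at monomer boundaries.
Overlapping hits are resolved exclusively: hits are processed per read in
decreasing score order (ties to the longer hit, then entry name) and each
claims only not-yet-covered bases. Abundance per class is the percent of
sampled read nucleotides masked; `copy_number()` converts a genomic
percent to a copy count as `floor(percent/100 × G / L)`;
`completeness()` masks one library's candidates with another and counts a
candidate as masked at ≥ 80% length coverage.

A read-vs-entry pair is only aligned at all if the two share at least two
distinct canonical 11-mers whose entry positions fall within one read
length of each other — the BLAST two-hit seeding rule — and the alignment
is seed-anchored: the read is aligned only against the entry window
spanned by that word cluster, padded by one read length on each side (for
tandem-tiled entries this window is effectively the whole tiled entry).
This keeps the alignment work proportional to the number of true hits
rather than to library size times read count. `mask_reads_truth()` produces the
same report from planted-truth provenance with no alignment, giving the
ground-truth upper bound that the unit tests compare against.

## Satellite analyses

`detect_tandem()` scans lags `p ≥ min_period` (default 100) and calls a
tandem when the mean identity between the sequence and itself shifted by
`p` reaches 0.7; because every multiple of the true period scores
near-identical self-identity, the call takes the smallest lag within 0.02
of the maximum rather than the raw argmax. The monomer is the
column-majority over phased units. `infer_monomer()` applies this per read,
takes the modal period over tandem-positive reads, phases every read's
monomer to the best-supported one by cyclic rotation (both strands), and
returns the column-majority consensus. `extract_monomers()` harvests
complete, phased monomer copies from reads by aligning each read against
the tiled consensus and cutting the alignment at unit boundaries; copies
shorter than 90% of the unit (truncated by read ends or deletions) are
discarded. `monomer_stats()` reports copy-length range, pooled GC, the
all-pairs identity distribution, and how many copies have a partner above
94% identity (strict inequality). `conservation_profile()` stacks phased
copies into a position-frequency matrix and reports per-column information
content `2 − H` bits, with no small-sample correction.
`digest_ladder()` cuts `flank + monomer×n + flank` at every recognition
site (both strands for non-palindromic sites) and returns fragment
lengths — with one site per monomer the interior fragments all equal the
monomer length, the classic satellite ladder; a `blocked_fraction`
randomly protects that fraction of sites, a minimal model of
methylation-blocked digestion.

## Paralog phylogenetics

`mine_paralogs()` translates each read in six frames and aligns every frame
locally against an amino-acid query (BLOSUM62, gap open 11 / extend 1).
Significance uses the Karlin–Altschul expectation
`E = K m n e^{−λS}` with BLAST's gapped BLOSUM62 constants λ = 0.267,
K = 0.041; hits need `E < 1e-5` and at least 80 aligned query residues.
The best hit per read wins and the in-frame nucleotide tract under the
aligned segment is extracted, so the amino-acid and nucleotide tracts stay
codon-synchronized. For nucleotide alignments the expectation uses an
ungapped λ solved from the match/mismatch scores with a conservative
K = 0.1 — adequate for thresholding, not for exact BLAST reproduction.

`align_tracts()` is a progressive profile–profile aligner: pairwise global
identities build a UPGMA guide tree, and profiles are merged by dynamic
programming over expected BLOSUM62 column scores with a linear gap penalty
(equivalent to `gapOpening = 0` in `Biostrings::pairwiseAlignment`, against
which the two-sequence case is exact). Distances between nucleotide tracts
use the Kimura two-parameter closed form
`K = −½ ln[(1 − 2P − Q)√(1 − 2Q)]`, excluding gap/N columns
(pairwise deletion) and returning `NA` with a warning when a log argument
is non-positive (saturation). The implementation is cross-checked against
`ape::dist.dna(model = "K80")` in the unit tests.

Trees come from Saitou–Nei neighbor joining (`ape::nj()`); negative branch
lengths are clamped to zero with the deficit moved to a sister edge so
path lengths through the parent are preserved. Bootstrap supports resample
alignment columns with replacement, rebuild the NJ tree per replicate, and
count bipartition recovery with `ape::prop.clades()`. Dating converts a
distance to time as `T = K/(2r)` with the grass-retrotransposon rate
`r = 6.5e-8` substitutions/site/year by default;
`subclade_split_times()` applies this to every between-subclade tract
pair, excluding saturated pairs. The quantity dated is a subclade *split*
(divergence) time — sequence divergence between paralog lineages — not a
per-element LTR–LTR insertion age.

## Numerical and design choices worth knowing

* **Coordinates** are 0-based half-open (BED-like) everywhere in returned
  data frames; `IRanges` 1-based closed coordinates are converted at the
  boundary.
* **N never matches**: nucleotide scoring uses an explicit 5×5 matrix in
  which N scores as a mismatch against everything, including N, so
  ambiguity cannot inflate identity.
* **Canonical l-mers** are numeric (2-bit rolling encoding into doubles,
  exact up to l = 15), and all k-mer joins are integer-valued merges, not
  string operations.
* **Determinism**: every stochastic function takes a seed and restores the
  caller's RNG state (`with_seed` internally), so pipelines are
  reproducible end to end from a single master seed.
* **Exclusive attribution** makes class percentages sum to the overall
  masked percent; without it, overlapping family hits would double-count.
* **Strictness conventions** follow the filters they model: copy-number
  filter strictly `> 10`; satellite partner rule strictly `> 94%`
  identity.

## Limitations

Beyond the generator simplifications above: discovery assumes repeats are
sampled by many independent reads, so it degrades below roughly ten copies
per family at 0.25× coverage (by design — that is the filter); the
progressive aligner has no iterative refinement; the Karlin–Altschul
E-values are approximations suitable for thresholding; `nj_tree()` is
distance-based only (no likelihood or Bayesian alternative); and dating
inherits the strong assumptions of a strict molecular clock with a single
substitution rate.
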