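make_test_query <- function() {
  query_precursor("q", paste0(strrep("A", 10), "YGGFLRRIRPKLKWDNQ",
                              strrep("S", 5)), c(11L, 27L))
}

test_that("search retains exactly the planted precursors on a clean fixture", {
  tpl <- make_precursor_set(seed = 21, n_species = 5, mutation_rate = 0)
  fx <- embed_in_contigs(tpl, seed = 22, n_decoys = 10,
                         contig_length = c(700, 1000))
  q <- make_query_precursor()
  sel <- select_candidates(fx$contigs)
  hits <- search_hits(q, sel)
  expect_equal(sort(hits$contig_id), sort(fx$manifest$contig_id))
  expect_true(all(hits$evalue <= 1e-6))
  expect_true(all(hits$mature_sequence == "YGGFLRRIRPKLKWDNQ"))
  expect_true(!is.unsorted(hits$evalue))
  # E is strictly positive, so a zero threshold retains nothing
  expect_equal(nrow(search_hits(q, sel, evalue_threshold = 0)), 0L)
  # requiring more aligned dyn A residues than exist excludes everything
  expect_equal(nrow(search_hits(q, sel, min_overlap = 18L)), 0L)
})

test_that("strand and frame of each hit match the planting manifest", {
  tpl <- make_precursor_set(seed = 23, n_species = 6, mutation_rate = 0)
  fx <- embed_in_contigs(tpl, seed = 24, n_decoys = 0,
                         contig_length = c(700, 1000))
  hits <- search_hits(make_query_precursor(), select_candidates(fx$contigs))
  mf <- fx$manifest[match(hits$contig_id, fx$manifest$contig_id), ]
  expect_identical(hits$strand, mf$strand)
  expect_identical(hits$frame_offset, mf$frame)
})

test_that("mature extraction maps subject residues onto dyn A columns", {
  q <- make_test_query()
  # identity alignment over the full precursor
  full <- align_local(q$sequence, q$sequence)
  expect_identical(extract_mature(full, q), "YGGFLRRIRPKLKWDNQ")
  # alignment covering only dyn A columns 1-8, blenniorphin-like subject
  aln <- structure(list(score = 30, query_interval = c(11L, 18L),
                        subject_interval = c(1L, 8L),
                        aligned_query = "YGGFLRRI",
                        aligned_subject = "YGGFMRRV"),
                   class = "sw_alignment")
  expect_identical(extract_mature(aln, q), "YGGFMRRV---------")
  # subject insertions inside the interval are dropped
  aln$aligned_query <- "YGGF-LRRI"
  aln$aligned_subject <- "YGGFWMRRV"
  expect_identical(extract_mature(aln, q), "YGGFMRRV---------")
  # zero overlap violates the precondition
  aln$query_interval <- c(1L, 9L)
  aln$aligned_query <- aln$aligned_subject <- "AAAAAAAAA"
  expect_error(extract_mature(aln, q), "overlap")
})

test_that("unique hits count distinct (sequence, species) pairs", {
  hits <- data.frame(
    mature_sequence = c(rep("YGGFMRRVGRPEWLVDS", 3), "YGGFMRRVGRPEWLVDS",
                        paste0("YGGFLRRIRPKLKWDN", c("A","C","D","E","F"))),
    species = c("sp1", "sp2", "sp3", "sp1", rep("sp9", 5)),
    taxon = c(rep("Blenniiformes", 4), rep("Perciformes", 5)),
    contig_id = sprintf("c%02d", 1:9),
    stringsAsFactors = FALSE)
  dd <- dedup_hits(hits)
  # same sequence in 3 species -> 3 unique hits in one record;
  # a repeat in a known species adds nothing; 5 novel sequences -> 5
  expect_equal(dd$n_unique, 8L)
  rec <- dd$unique_hits[dd$unique_hits$mature_sequence ==
                          "YGGFMRRVGRPEWLVDS", ]
  expect_equal(rec$n_species, 3L)
  expect_match(rec$taxon_counts, "Blenniiformes:3")
  # idempotence: dedup of the flattened pairs changes nothing
  dd2 <- dedup_hits(dd$pairs)
  expect_identical(dd2$pairs, dd$pairs)
  expect_lte(dd$n_unique, nrow(hits))
  # missing species metadata is an input error naming the contig
  hits$species[2] <- NA
  expect_error(dedup_hits(hits), "c02")
})

test_that("taxonomic profile reproduces per-taxon and overall fractions", {
  taxa <- rep(c("Cypriniformes", "Salmoniformes", "Perciformes",
                "Blenniiformes"), each = 50)
  taxonomy <- data.frame(species = sprintf("sp%03d", 1:200), taxon = taxa,
                         stringsAsFactors = FALSE)
  tr <- data.frame(taxon = unique(taxa), n_transcriptomes = c(90, 80, 60, 40))
  # 146 of 200 species have one hit each
  pairs <- data.frame(mature_sequence = "YGGFLRRIRPKLKWDNQ",
                      species = taxonomy$species[1:146],
                      stringsAsFactors = FALSE)
  prof <- taxonomic_profile(pairs, taxonomy, tr)
  expect_equal(prof$totals$species_with_hits_fraction, 0.73)
  expect_equal(prof$totals$n_unique_hits, 146L)
  expect_equal(sum(prof$per_taxon$n_unique_hits), prof$totals$n_unique_hits)
  expect_equal(prof$totals$taxa_with_hits_fraction, 3 / 4)
  # empty hit set: all counts zero
  prof0 <- taxonomic_profile(pairs[0, ], taxonomy, tr)
  expect_equal(prof0$totals$n_unique_hits, 0L)
  expect_true(all(prof0$per_taxon$n_unique_hits == 0L))
  # unmapped species is an input error
  expect_error(
    taxonomic_profile(data.frame(mature_sequence = "X", species = "nope"),
                      taxonomy, tr), "nope")
})

test_that("logo information content matches direct entropy computation", {
  # single residue: zero entropy, R = log2(20)
  lm1 <- logo_matrix("Y")
  expect_equal(lm1$information, log2(20))
  # uniform 20-residue column: maximum entropy, R = 0
  lm2 <- logo_matrix(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                       "Q","R","S","T","V","W","Y"))
  expect_equal(lm2$information, 0)
  # 50/50 two-residue column: H = 1 bit
  lm3 <- logo_matrix(c("Y", "Y", "F", "F"))
  expect_equal(lm3$information, log2(20) - 1)
  # small-sample correction subtracts 19 / (2 ln2 n) ...
  lm4 <- logo_matrix(rep(c("Y", "F"), 20), small_sample_correction = TRUE)
  expect_equal(lm4$information, log2(20) - 1 - 19 / (2 * log(2) * 40))
  # ... and information is clamped at zero when n is tiny
  lm3c <- logo_matrix(c("Y", "Y", "F", "F"), small_sample_correction = TRUE)
  expect_equal(lm3c$information, 0)
})

test_that("logo frequencies sum to one and ignore input order and gaps", {
  set.seed(55)
  peps <- vapply(1:30, function(i) random_protein(17), character(1))
  peps[1] <- paste0(substr(peps[1], 1, 8), strrep("-", 9))
  lm <- logo_matrix(peps)
  sums <- rowSums(lm$frequencies)
  expect_true(all(abs(sums[lm$n_nongap > 0] - 1) < 1e-9))
  expect_true(all(lm$information >= 0 & lm$information <= log2(20)))
  expect_equal(lm$n_nongap[17], 29L)
  shuffled <- logo_matrix(sample(peps))
  expect_equal(shuffled$information, lm$information)
  expect_error(logo_matrix(c("YGGF", "YG")), "ragged")
})
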