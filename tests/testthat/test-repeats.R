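test_that("random sequence without planted repeats yields no pairs", {
  g <- make_repeat_genome(10000L, families = list(), seed = 1L)
  expect_equal(nrow(g$truth), 0L)
  pairs <- find_repeat_pairs(g$genome)
  expect_equal(nrow(pairs), 0L)
  expect_equal(nrow(oracle_repeat_pairs(g$genome)), 0L)
})

test_that("one exact 1000 bp copy gives one pair at full identity", {
  g <- make_repeat_genome(10000L,
                          families = list(list(copies = 2L, length = 1000L,
                                               mut_rate = 0)),
                          seed = 1L)
  pairs <- find_repeat_pairs(g$genome)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$identity, 1.0)
  # detected length may exceed the planted 1000 bp only by chance matches
  # directly flanking the copies; it can never undershoot
  expect_gte(pairs$aln_length, 1000L)
  expect_lte(pairs$aln_length, 1050L)
  # loci must cover the planted intervals
  tr <- g$truth[order(g$truth$start), ]
  expect_lte(pairs$a_start, tr$start[1])
  expect_gte(pairs$a_end, tr$end[1])
  expect_lte(pairs$b_start, tr$start[2])
  expect_gte(pairs$b_end, tr$end[2])
})

test_that("three exact 600 bp copies give C(3,2) = 3 pairs", {
  g <- make_repeat_genome(20000L,
                          families = list(list(copies = 3L, length = 600L,
                                               mut_rate = 0)),
                          seed = 3L)
  pairs <- find_repeat_pairs(g$genome)
  expect_equal(nrow(pairs), 3L)
  expect_true(all(pairs$identity == 1.0))
})

test_that("diverged copies are found with the planted identity", {
  g <- make_repeat_genome(20000L,
                          families = list(list(copies = 3L, length = 600L,
                                               mut_rate = 0.02)),
                          seed = 7L)
  pairs <- find_repeat_pairs(g$genome)
  expect_equal(nrow(pairs), 3L)
  # fixed-count mutation: each non-first copy differs from the template at
  # exactly round(0.02 * 600) = 12 sites, so pairwise identity >= 1 - 2*0.02
  expect_true(all(pairs$identity >= 0.96 - 1e-9))
  expect_true(all(abs(pairs$aln_length - 600L) <= 0.05 * 600))
})

test_that("k-mer seeded detection agrees with the brute-force oracle", {
  specs <- list(
    list(len = 6000L, fam = list(list(copies = 2L, length = 700L,
                                      mut_rate = 0.01)), seed = 11L),
    list(len = 8000L, fam = list(list(copies = 3L, length = 550L,
                                      mut_rate = 0.03)), seed = 12L),
    list(len = 8000L, fam = list(list(copies = 2L, length = 1200L,
                                      mut_rate = 0),
                                 list(copies = 2L, length = 600L,
                                      mut_rate = 0.02)), seed = 13L))
  for (sp in specs) {
    g <- make_repeat_genome(sp$len, families = sp$fam, seed = sp$seed)
    got <- find_repeat_pairs(g$genome)
    want <- oracle_repeat_pairs(g$genome)
    expect_equal(got[, c("a_start", "a_end", "b_start", "b_end",
                         "orientation", "aln_length", "identity")],
                 want, ignore_attr = TRUE)
  }
})

test_that("reverse-complement repeats are detected with mapped coordinates", {
  set.seed(42)
  seg <- random_dna_str(800)
  genome <- c(chr = paste0(random_dna_str(3000), seg, random_dna_str(3000),
                           revcomp(seg), random_dna_str(3000)))
  pairs <- find_repeat_pairs(genome)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$orientation, "reverse_complement")
  # chance single-base matches flanking the planted copies may extend the
  # alignment by a few bp; the planted loci must be covered near-exactly
  expect_lte(abs(pairs$a_start - 3000L), 5L)
  expect_lte(abs(pairs$a_end - 3800L), 5L)
  expect_lte(abs(pairs$b_start - 6800L), 5L)
  expect_lte(abs(pairs$b_end - 7600L), 5L)
  expect_equal(pairs[, c("a_start", "a_end", "b_start", "b_end",
                         "orientation", "aln_length", "identity")],
               oracle_repeat_pairs(genome), ignore_attr = TRUE)
})

test_that("results are invariant under reverse-complementing the genome", {
  g <- make_repeat_genome(15000L,
                          families = list(list(copies = 2L, length = 900L,
                                               mut_rate = 0.01)),
                          seed = 21L)
  fwd <- find_repeat_pairs(g$genome)
  rc <- find_repeat_pairs(c(chr = revcomp(g$genome[[1]])))
  expect_equal(nrow(fwd), nrow(rc))
  expect_equal(sort(fwd$aln_length), sort(rc$aln_length))
  expect_equal(sort(fwd$identity), sort(rc$identity))
})

test_that("raising thresholds never adds pairs", {
  g <- make_repeat_genome(20000L,
                          families = list(list(copies = 3L, length = 700L,
                                               mut_rate = 0.03)),
                          seed = 31L)
  base <- find_repeat_pairs(g$genome, min_length = 500L, min_identity = 0.95)
  longer <- find_repeat_pairs(g$genome, min_length = 650L,
                              min_identity = 0.95)
  stricter <- find_repeat_pairs(g$genome, min_length = 500L,
                                min_identity = 0.99)
  expect_lte(nrow(longer), nrow(base))
  expect_lte(nrow(stricter), nrow(base))
})

test_that("alignments break at N runs and Ns never match", {
  set.seed(5)
  half <- random_dna_str(400)
  seg <- paste0(half, strrep("N", 20), half)
  genome <- c(chr = paste0(random_dna_str(2000), seg, random_dna_str(2000),
                           seg, random_dna_str(2000)))
  pairs <- find_repeat_pairs(genome, min_length = 300L)
  # each 400 bp half pairs with its counterpart (plus at most a few chance
  # flanking matches); no pair spans the N run
  expect_true(all(pairs$aln_length <= 410L))
  expect_true(all(pairs$identity >= 0.97))
  spans_ns <- pairs$a_start < 2400L & pairs$a_end > 2420L
  expect_false(any(spans_ns))
})

test_that("combined scope finds repeats shared between replicons", {
  set.seed(9)
  seg <- random_dna_str(700)
  genome <- c(chrA = paste0(random_dna_str(2000), seg, random_dna_str(2000)),
              chrB = paste0(random_dna_str(1500), seg, random_dna_str(2500)))
  per <- find_repeat_pairs(genome, scope = "per_replicon")
  comb <- find_repeat_pairs(genome, scope = "combined")
  expect_equal(nrow(per), 0L)
  expect_equal(nrow(comb), 1L)
  expect_equal(comb$replicon_a, "chrA")
  expect_equal(comb$replicon_b, "chrB")
  expect_equal(comb$a_start, 2000L)
  expect_equal(comb$b_start, 1500L)
})

test_that("rotate catches repeats spanning the origin", {
  set.seed(10)
  seg <- random_dna_str(600)
  # second copy wraps around the origin: 300 bp at the end + 300 bp start
  genome <- c(chr = paste0(substr(seg, 301, 600), random_dna_str(3000), seg,
                           random_dna_str(3000), substr(seg, 1, 300)))
  plain <- find_repeat_pairs(genome)
  rotated <- find_repeat_pairs(genome, rotate = TRUE)
  expect_equal(nrow(plain), 0L)
  expect_equal(nrow(rotated), 1L)
  expect_equal(rotated$aln_length, 600L)
})

test_that("invalid genomes are rejected", {
  expect_error(find_repeat_pairs(character(0)), "no sequences")
  expect_error(find_repeat_pairs(c(chr = "ACGTX")), "non-ACGTN")
})

test_that("classify_complexity reproduces the stated thresholds", {
  expect_equal(classify_complexity(0, 0), "I")
  expect_equal(classify_complexity(5, 7001), "III")
  expect_equal(classify_complexity(101, 7000), "II")
  expect_equal(classify_complexity(100, 7000), "I")
  expect_equal(classify_complexity(c(0, 101, 5), c(0, 7000, 7001)),
               c("I", "II", "III"))
  expect_error(classify_complexity(-1, 100), "non-negative")
})

test_that("summarize_repeats profiles a pair table", {
  empty <- summarize_repeats(NULL, "G0")
  expect_equal(empty$n_pairs, 0L)
  expect_equal(empty$max_len, 0L)
  expect_equal(empty$complexity_class, "I")

  pairs <- data.frame(aln_length = c(rep(550L, 195), 600L, 5466L, 800L))
  prof <- summarize_repeats(pairs, "FAM8627")
  expect_equal(prof$n_pairs, 198L)
  expect_equal(prof$max_len, 5466L)
  expect_equal(prof$complexity_class, "II")

  big <- data.frame(aln_length = c(500L, 30000L, 700L, 600L, 900L))
  expect_equal(summarize_repeats(big, "H10")$complexity_class, "III")
})

test_that("species summary averages pairs and drops singleton species", {
  profiles <- data.frame(
    genome_id = c("a1", "a2", "b1", "c1", "c2", "c3"),
    n_pairs = c(100L, 200L, 7L, 10L, 20L, 30L),
    complexity_class = c("II", "II", "I", "I", "I", "I"),
    stringsAsFactors = FALSE)
  species_of <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", c2 = "C", c3 = "C")
  s <- species_repeat_summary(profiles, species_of)
  expect_setequal(s$species$species, c("A", "C"))
  expect_equal(s$species$mean_n_pairs[s$species$species == "A"], 150)
  expect_equal(unname(s$class_percentages["II"]), 100 * 2 / 5)
  # all class I -> 100%
  all_one <- profiles[4:6, ]
  s1 <- species_repeat_summary(all_one, species_of)
  expect_equal(unname(s1$class_percentages["I"]), 100)
  expect_error(species_repeat_summary(profiles, species_of[-1]),
               "no species")
})

test_that("repeat pair tables round-trip through TSV", {
  g <- make_repeat_genome(10000L,
                          families = list(list(copies = 2L, length = 1000L,
                                               mut_rate = 0)),
                          seed = 1L)
  pairs <- find_repeat_pairs(g$genome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repeat_pairs(pairs, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(back, pairs, ignore_attr = TRUE)
})
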