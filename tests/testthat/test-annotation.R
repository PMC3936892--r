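test_that("hamming distance counts substitutions and rejects indels", {
  expect_equal(hamming("ACGT", "ACGT"), 0)
  expect_equal(hamming("ACGT", "ACGA"), 1)
  expect_equal(hamming("AAAA", "TTTT"), 4)
  expect_error(hamming("ACG", "ACGT"), "unequal")
})

test_that("known-miRNA matching is exact full-length identity", {
  known <- c("bra-miR164a" = "CACGTGCTCCACTCCTCCAAC",
             "bra-miR164a-dup" = "CACGTGCTCCACTCCTCCAAC")
  reads <- srna_reads(c("a", "b"),
                      c("CACGTGCTCCACTCCTCCAAC",
                        "CACGTGCTCCACTCCTCCAAT"))  # 1 mismatch
  m <- match_known(reads, known)
  expect_equal(sort(m$known_name), c("bra-miR164a", "bra-miR164a-dup"))
  expect_true(all(m$sequence == "CACGTGCTCCACTCCTCCAAC"))
  expect_equal(nrow(match_known(reads, character(0))), 0)
})

test_that("genome mapping reports all exact hits on both strands", {
  mir <- "TGACCGAGTAGACCGATAGTC"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mir)))
  set.seed(99)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  chr <- paste0(bg(100), mir, bg(50), mir, bg(80), rc, bg(60))
  genome <- Biostrings::DNAStringSet(chr); names(genome) <- "chr1"
  hits <- map_to_genome(mir, genome)
  expect_equal(nrow(hits), 3)
  expect_equal(sum(hits$strand == "+"), 2)     # two planted loci
  expect_equal(sum(hits$strand == "-"), 1)     # reverse-complement hit
  expect_equal(hits$start[hits$strand == "+"], c(100, 171))
  expect_equal(hits$end - hits$start, rep(nchar(mir), 3))
  # genome substring at a + hit equals the read
  expect_equal(substr(chr, hits$start[1] + 1, hits$end[1]), mir)
  un <- map_to_genome("GGGGGGGGGGGGGGGGGGGGG", genome)
  expect_equal(nrow(un), 0)
  expect_equal(attr(un, "unmapped"), "GGGGGGGGGGGGGGGGGGGGG")
})

test_that("repetitive reads beyond the hit threshold are dropped", {
  unit <- "ACGTACGTACGTACGTACGT"
  genome <- Biostrings::DNAStringSet(strrep(unit, 40))
  names(genome) <- "chr1"
  hits <- map_to_genome("ACGTACGTACGTACGTACGT", genome, max_hits = 20)
  expect_equal(nrow(hits), 0)
  expect_true("ACGTACGTACGTACGTACGT" %in% attr(hits, "repetitive"))
})

test_that("conserved scan agrees with a brute-force all-pairs search", {
  set.seed(42)
  refs <- setNames(vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""), ""),
    sprintf("ath-miR%03da", 1:12))
  mutate <- function(s, k) {
    x <- strsplit(s, "")[[1]]
    for (p in sample(seq_along(x), k))
      x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    paste(x, collapse = "")
  }
  qry <- c(mutate(refs[1], 2), mutate(refs[5], 3), mutate(refs[8], 4),
           vapply(1:3, function(i)
             paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""),
             ""))
  got <- find_conserved_candidates(qry, refs, max_mm = 3)
  for (i in seq_along(qry)) {
    d <- vapply(refs, function(r) hamming(qry[i], r), 0L)
    expect_equal(got$class[got$sequence == qry[i]],
                 if (min(d) <= 3) "conserved" else "novel")
    if (min(d) <= 3)
      expect_equal(got$mismatches[got$sequence == qry[i]], min(d))
  }
})

test_that("equal-score family ties resolve to the smallest family name", {
  base <- "ACGTACGTACGTACGTACGTA"
  refs <- c("ath-miR500a" = base, "osa-miR200b" = base)
  qry <- sub("^A", "T", base)
  expect_message(
    got <- find_conserved_candidates(qry, refs, max_mm = 3), "tie")
  expect_equal(got$family, "miR200")
})

test_that("mir_family strips species, arm, letter and sub-member parts", {
  expect_equal(mir_family("ath-miR156a-5p"), "miR156")
  expect_equal(mir_family("bra-miR168a-1-p5"), "miR168")
  expect_equal(mir_family("P-bra-miR319b-p3"), "miR319")
})

test_that("naming assigns arms, sub-member indices and P- prefixes", {
  cand <- data.frame(
    sequence = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
                 "TTGACCGAGTAGACCGATAGT"),
    chrom = "chr1", start = c(100, 900, 2000),
    end = c(121, 921, 2021), strand = "+",
    arm = c("5p", "5p", "3p"),
    family = NA_character_,
    star_sequence = c("TACGTACGTACGTACGTAC", "TACGTACGTACGTACGTAC",
                      "CTATCGGTCTACTCGGTCA"),
    star_observed = c(TRUE, TRUE, FALSE),
    hairpin_id = c("h1", "h2", "h3"),
    stringsAsFactors = FALSE)
  named <- assign_names(cand, prefix = "bra")
  # identical mature from two loci -> sub-members -1 and -2
  subm <- named[named$sequence == "ACGTACGTACGTACGTACGTA", ]
  expect_setequal(subm$name, c("bra-miRn1-1-5p", "bra-miRn1-2-5p"))
  # unsequenced partner arm reported with a P- prefix
  p <- named[named$predicted_only_flag, ]
  expect_equal(nrow(p), 1)
  expect_match(p$name, "^P-bra-miRn2-5p$")
  expect_equal(p$arm, "5p")
  # candidate without a precursor errors
  cand$hairpin_id[1] <- NA
  expect_error(assign_names(cand), "precursor")
})
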