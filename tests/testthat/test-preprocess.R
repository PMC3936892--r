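ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("3' adapter trimming recovers inserts and flags adapterless reads", {
  insert <- "TGACCGAGTAGACCGATAGTC"
  reads <- srna_reads(
    read_id = c("full", "partial", "none", "adapter_only"),
    sequence = c(paste0(insert, ADAPTER),
                 paste0(insert, substr(ADAPTER, 1, 8)),
                 "ACGTACGTACGTACGTACGTACGTACGTAC",
                 ADAPTER))
  out <- trim_3p_adapter(reads, ADAPTER)
  expect_equal(out$sequence[1], insert)
  expect_equal(out$sequence[2], insert)   # 8-base prefix suffices
  expect_false(out$kept[3])
  expect_equal(out$removal_reason[3], "no_3adt")
  # read equal to the adapter alone: empty insert, removed downstream
  expect_true(out$kept[4])
  expect_equal(out$sequence[4], "")
  out2 <- filter_by_length(out)
  expect_equal(out2$removal_reason[4], "too_short")
})

test_that("adapter trimming takes the leftmost qualifying match", {
  # insert whose tail equals the adapter start: the earlier (5'-most)
  # occurrence of the adapter prefix wins
  ins <- "ACGTACGT"
  read <- paste0(ins, substr(ADAPTER, 1, 7), ADAPTER)
  out <- trim_3p_adapter(srna_reads("x", read), ADAPTER, min_overlap = 6)
  expect_equal(nchar(out$sequence), nchar(ins) + 7)  # leftmost full-suffix match
  expect_true(out$kept)
})

test_that("invalid read characters are rejected with a diagnostic", {
  expect_error(trim_3p_adapter(srna_reads("bad", "ACGTXACGT"), ADAPTER),
               "non-ACGTN")
})

test_that("length filter bounds are inclusive", {
  reads <- srna_reads(paste0("r", 1:4),
                      c(strrep("ACGTT", 3)[1],              # 15 nt
                        substr(strrep("ACGT", 8), 1, 30),   # 30 nt
                        substr(strrep("ACGT", 8), 1, 14),   # 14 nt
                        substr(strrep("ACGT", 8), 1, 31)))  # 31 nt
  out <- filter_by_length(reads)
  expect_equal(out$kept, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$removal_reason[3:4], c("too_short", "too_long"))
  expect_error(filter_by_length(reads, 20, 10), "min_len")
})

test_that("junk screen removes low-complexity and N-rich reads", {
  reads <- srna_reads(paste0("r", 1:4),
                      c(strrep("A", 17),
                        paste0("ACGTACGTACGTACGTAN", "NN"),
                        "TGACCGAGTAGACCGATAGTC",
                        strrep("AC", 10)))
  out <- remove_junk(reads)
  expect_equal(out$removal_reason[1], "junk")   # 1 distinct base
  expect_equal(out$removal_reason[2], "junk")   # 3 N of 20 -> 0.15 > 0.1
  expect_true(out$kept[3])                      # a real mature survives
  expect_equal(out$removal_reason[4], "junk")   # dimer repeat
})

test_that("contaminant matching is exact substring with fixed precedence", {
  rrna <- strrep("GATTACAGATTACAGGCGCGT", 4)
  rep1 <- "TTTTGGGGCCCCAAAATTTTGGGG"
  reads <- srna_reads(paste0("r", 1:3),
                      c(substr(rrna, 10, 30),    # window of the rRNA
                        substr(rep1, 1, 20),
                        "TGACCGAGTAGACCGATAGTC"))
  out <- remove_contaminants(reads, rfam_set = c(rrna, substr(rep1, 1, 20)),
                             repbase_set = rep1)
  expect_equal(out$removal_reason[1], "rfam")
  expect_equal(out$removal_reason[2], "rfam")   # matches both: rfam wins
  expect_true(out$kept[3])
  expect_warning(remove_contaminants(reads, NULL, NULL), "no-op")
})

test_that("contaminants are found on the reverse strand too", {
  rrna <- "GATTACAGATTACAGGCGCGTACGATCGATT"
  rc_window <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(rrna, 5, 25))))
  out <- remove_contaminants(srna_reads("r", rc_window), rfam_set = rrna)
  expect_equal(out$removal_reason, "rfam")
})

test_that("ledger arithmetic reproduces the published accounting totals", {
  acc <- study_read_accounting()
  for (i in 1:2) {
    rep <- filter_report(acc$raw[i],
                         c(no_3adt = acc$no_3adt[i],
                           too_short = acc$too_short[i],
                           junk = acc$junk[i],
                           rfam = acc$rfam[i],
                           repbase = acc$repbase[i]))
    expect_equal(rep$surviving_15_30,
                 c(5098547, 5309119)[i])
  }
})

test_that("accounting over real reads satisfies the conservation invariant", {
  rrna <- strrep("GATTACAGATTACAGGCGCGT", 4)
  mk <- function(ins) paste0(ins, ADAPTER)
  reads <- srna_reads(paste0("r", 1:6),
                      c(mk("TGACCGAGTAGACCGATAGTC"),
                        mk("TGACCGAGTAGACCGATAGTC"),
                        mk(substr(rrna, 10, 30)),
                        mk(strrep("A", 20)),
                        mk("ACGT"),
                        strrep("ACGTG", 6)),
                      count = c(5L, 2L, 3L, 1L, 4L, 2L))
  out <- preprocess_reads(reads, ADAPTER, rfam_set = rrna)
  rep <- out$report
  expect_equal(rep$raw_total, 17)
  expect_equal(rep$raw_total, rep$mappable_total + sum(rep$removed))
  expect_equal(rep$surviving_15_30,
               rep$mappable_total + rep$removed[["rfam"]] +
                 rep$removed[["repbase"]])
  # every read carries exactly one reason, kept xor removed
  expect_true(all(xor(out$reads$kept, out$reads$removal_reason != "none")))
  # zero input gives an all-zero report
  z <- build_accounting(srna_reads(character(0), character(0),
                                   integer(0)))
  expect_equal(z$raw_total, 0)
  expect_equal(sum(z$removed), 0)
})

test_that("the filter chain is idempotent on its own kept output", {
  rrna <- strrep("GATTACAGATTACAGGCGCGT", 4)
  reads <- srna_reads(paste0("r", 1:4),
                      c(paste0("TGACCGAGTAGACCGATAGTC", ADAPTER),
                        paste0(substr(rrna, 3, 26), ADAPTER),
                        paste0(strrep("AG", 11), ADAPTER),
                        "ACGTACGTACGTACGTACGTACGTACGTACGT"))
  once <- preprocess_reads(reads, ADAPTER, rfam_set = rrna)
  kept <- once$reads[once$reads$kept, , drop = FALSE]
  # kept inserts no longer carry the adapter; re-running only the
  # length/junk/contaminant stages must change nothing
  again <- remove_contaminants(remove_junk(filter_by_length(kept)),
                               rfam_set = rrna)
  expect_equal(again$sequence, kept$sequence)
  expect_true(all(again$kept))
})

test_that("collapsed FASTA counts survive a write/read round trip", {
  reads <- srna_reads(c("a", "b", "c"),
                      c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA",
                        "TTTTGCGTTTCAACTCGGTCC"),
                      count = c(3L, 2L, 7L))
  tmp <- tempfile(fileext = ".fa")
  write_collapsed_fasta(reads, tmp)
  back <- read_small_rna(tmp)
  expect_setequal(back$count, c(5L, 7L))
  expect_setequal(back$sequence, unique(reads$sequence))
})
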