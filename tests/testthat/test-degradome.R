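test_that("degradome reads map by 5' end with exact anchors", {
  set.seed(8)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  shared <- bg(25)
  tx1 <- paste0(bg(553), shared, bg(300))
  tx2 <- paste0(bg(100), shared, bg(500))
  txs <- Biostrings::DNAStringSet(c(TX1 = tx1, TX2 = tx2))
  reads <- srna_reads(
    c("hit", "multi", "mm"),
    c(substr(tx1, 300, 320),
      substr(shared, 1, 21),
      paste0("A", substr(tx1, 301, 320))),   # 1 mismatch at the 5' end
    count = c(3L, 2L, 1L))
  prof <- map_degradome_reads(reads, txs)
  expect_equal(prof$TX1[300], 3)
  expect_equal(prof$TX1[554], 2)             # multi-mapped, counted twice
  expect_equal(prof$TX2[101], 2)
  expect_equal(substr(as.character(txs[["TX1"]]), 554, 554 + 24),
               shared)
  expect_equal(sum(prof$TX1), 5)             # the mismatch read is unmapped
  expect_true(substr(shared, 1, 20) %in% attr(prof, "multimapped"))
})

test_that("category assignment follows the max/median conventions", {
  prof <- integer(700)
  prof[554] <- 5; prof[600] <- 1; prof[601] <- 1
  expect_equal(assign_category(prof, 554), 0L)
  prof2 <- integer(700); prof2[554] <- 5; prof2[600] <- 5
  expect_equal(assign_category(prof2, 554), 1L)
  expect_equal(assign_category(prof, 600), 4L)   # single read
  prof3 <- integer(100)
  prof3[c(10, 20, 30, 40)] <- c(10, 6, 2, 2)
  expect_equal(assign_category(prof3, 20), 2L)   # above median (4)
  expect_equal(assign_category(prof3, 30), 3L)   # at/below median, > 1
  expect_error(assign_category(prof, 100), "evidence")
})

test_that("category assignment agrees with the explicit oracle", {
  set.seed(33)
  for (i in 1:200) {
    prof <- integer(sample(50:200, 1))
    k <- sample(3:12, 1)
    prof[sample(length(prof), k)] <- sample(1:20, k, TRUE)
    site <- sample(which(prof > 0), 1)
    expect_equal(assign_category(prof, site),
                 oracle_category(prof, site),
                 info = paste(c(site, prof[prof > 0]), collapse = ","))
  }
})

test_that("target alignment scoring uses plant-standard penalties", {
  mir <- "TGACCGAGTAGACCGATAGTC"          # 21 nt
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mir)))
  set.seed(4)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  tx <- paste0(bg(99), rc, bg(80))
  al <- align_mir_target(mir, tx)
  expect_equal(nrow(al), 1)
  expect_equal(al$binding_start, 100)
  expect_equal(al$binding_end, 120)
  expect_equal(al$score, 0)
  expect_equal(al$cleavage_site, 111)     # opposite miRNA position 10
  expect_equal(al$labels, strrep("|", 21))

  # one G:U inside the core region scores 0.5 x 2: miRNA position 2 is a
  # G and faces transcript position b2 - 2 + 1 = 119; G pairs U(T)
  x <- strsplit(tx, "")[[1]]
  stopifnot(substr(mir, 2, 2) == "G")
  x[119] <- "T"
  al_gu <- align_mir_target(mir, paste(x, collapse = ""))
  expect_equal(al_gu$score[al_gu$binding_start == 100], 1.0)

  # one mismatch outside the core (position 20) scores 1 x 1
  y <- strsplit(tx, "")[[1]]
  y[101] <- "A"  # faces miRNA position 20; mir[20] = T pairs A -> mutate
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m20 <- substr(mir, 20, 20)
  y[101] <- setdiff(c("A", "C", "G", "T"),
                    c(comp[[m20]], if (m20 == "G") "T",
                      if (m20 == "T") "G"))[1]
  al_mm <- align_mir_target(mir, paste(y, collapse = ""))
  expect_equal(al_mm$score[al_mm$binding_start == 100], 1.0)
})

test_that("cleavage position rule counts 9th/10th from the miRNA-5' end", {
  al <- list(binding_start = 100, binding_end = 120)
  expect_true(check_cleavage_position(al, 111))    # opposite miR nt 10
  expect_true(check_cleavage_position(al, 112))    # opposite miR nt 9
  expect_false(check_cleavage_position(al, 108))
  expect_false(check_cleavage_position(al, 130))   # outside binding region
  # the alternative convention counts from the target 5' end
  expect_true(check_cleavage_position(al, 108, count_from = "target5"))
  expect_true(check_cleavage_position(al, 109, count_from = "target5"))
  expect_false(check_cleavage_position(al, 115, count_from = "target5"))
})

test_that("target calling needs the peak at the admissible site", {
  mir <- "TGACCGAGTAGACCGATAGTC"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mir)))
  set.seed(9)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  tx <- paste0(bg(499), rc, bg(480))      # binding 500-520, site 511
  txs <- Biostrings::DNAStringSet(c(T1 = tx))
  reads_good <- srna_reads(paste0("r", 1:3),
                           rep(substr(tx, 511, 530), 3))
  prof <- map_degradome_reads(reads_good, txs)
  al <- align_mir_target(mir, txs)
  al$mir_name <- "bra-miR9001-5p"
  hom <- data.frame(transcript_id = "T1", at_gene_id = "AT1G11111",
                    known_target_of = "miR9001",
                    stringsAsFactors = FALSE)
  calls <- call_targets(al, prof, hom)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cleavage_site, 511)
  expect_equal(calls$category, 0L)
  expect_true(calls$conserved_flag)
  # evidence away from the 9th/10th positions is not called
  reads_bad <- srna_reads("r", substr(tx, 505, 524))
  prof_bad <- map_degradome_reads(reads_bad, txs)
  expect_equal(nrow(call_targets(al, prof_bad, hom)), 0)
  # transcript absent from the map: called but unannotated, with warning
  expect_warning(c2 <- call_targets(al, prof,
                                    hom[hom$transcript_id == "zz", ]),
                 "absent")
  expect_equal(nrow(c2), 1)
  expect_true(is.na(c2$homolog))
  # t-plot table flags the site
  tp <- emit_tplot(prof$T1, 511)
  expect_equal(sum(tp$is_site), 1)
  expect_equal(tp$reads[tp$is_site], 3)
})
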