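#' Run the full miRNA discovery pipeline on two small RNA libraries
#'
#' Preprocesses both libraries (adapter, length, junk, contaminants) with
#' exact accounting, anchors surviving reads to the genome by exact
#' matching, classifies them as known / conserved / novel, screens every
#' candidate locus through the precursor window ladder and the
#' five-criterion duplex evaluation, names the validated matures, and
#' calls differential expression on reads-per-million abundances.
#'
#' @param reads_A,reads_B read data frames (see [read_small_rna()]), or
#'   an `srna_sim` object as `reads_A` to run directly on a simulation.
#' @param genome a `DNAStringSet` or FASTA path.
#' @param adapter 3' adapter sequence.
#' @param rfam_set,repbase_set contaminant sets.
#' @param known_set named character vector of known matures (target
#'   species).
#' @param plant_mirs named character vector of all-species matures for
#'   the conserved scan.
#' @param flank_steps precursor window ladder.
#' @param max_mm conserved-match mismatch bound.
#' @param max_genome_hits repetitive-read threshold.
#' @param prefix,arm_style naming conventions (see [assign_names()]).
#' @param pseudo_rpm zero-cell replacement for fold changes.
#' @param fold_fun folding backend.
#' @param ... further thresholds for [classify_candidate()].
#' @return an object of class `mir_discovery`.
#' @export
discover_mirnas <- function(reads_A, reads_B = NULL, genome = NULL,
                            adapter = NULL, rfam_set = NULL,
                            repbase_set = NULL, known_set = character(),
                            plant_mirs = character(),
                            flank_steps = c(20, 50, 100, 150),
                            max_mm = 3L, max_genome_hits = 20L,
                            prefix = "bra", arm_style = "5p",
                            pseudo_rpm = 0.01, fold_fun = fold_hairpin,
                            ...) {
  if (inherits(reads_A, "srna_sim")) {
    sim <- reads_A
    reads_A <- sim$reads_A; reads_B <- sim$reads_B
    genome <- sim$genome; adapter <- sim$adapter
    rfam_set <- sim$rfam; repbase_set <- sim$repbase
    known_set <- sim$known_set; plant_mirs <- sim$plant_mirs
    prefix <- "syn"
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)

  pre_A <- preprocess_reads(collapse_reads(reads_A), adapter,
                            rfam_set, repbase_set)
  pre_B <- preprocess_reads(collapse_reads(reads_B), adapter,
                            rfam_set, repbase_set)
  kept_A <- pre_A$reads[pre_A$reads$kept, c("sequence", "count")]
  kept_B <- pre_B$reads[pre_B$reads$kept, c("sequence", "count")]
  counts <- merge(kept_A, kept_B, by = "sequence", all = TRUE,
                  suffixes = c("_A", "_B"))
  counts$count_A[is.na(counts$count_A)] <- 0L
  counts$count_B[is.na(counts$count_B)] <- 0L
  lib_sizes <- c(A = pre_A$report$mappable_total,
                 B = pre_B$report$mappable_total)

  known <- match_known(data.frame(sequence = counts$sequence,
                                  kept = TRUE), known_set)
  hits <- map_to_genome(counts$sequence, genome, max_genome_hits)
  cand_seqs <- setdiff(unique(hits$sequence), known$sequence)
  classes <- find_conserved_candidates(cand_seqs, plant_mirs, max_mm)

  # observed star spans come from the genome hits of all mappable reads
  make_star_finder <- function(self_seq) {
    function(w) {
      h <- hits[hits$chrom == w$chrom & hits$strand == w$strand &
                  hits$start >= w$start & hits$end <= w$end &
                  hits$sequence != self_seq, , drop = FALSE]
      lapply(seq_len(nrow(h)), function(i) {
        if (w$strand == "+") c(h$start[i] - w$start, h$end[i] - w$start)
        else c(w$end - h$end[i], w$end - h$start[i])
      })
    }
  }

  screens <- list()
  for (s in cand_seqs) {
    loci <- hits[hits$sequence == s, , drop = FALSE]
    for (li in seq_len(nrow(loci))) {
      locus <- as.list(loci[li, ])
      scr <- screen_hairpin(genome, locus,
                            star_finder = make_star_finder(s),
                            flank_steps = flank_steps,
                            fold_fun = fold_fun, ...)
      if (is.null(scr)) next
      screens[[length(screens) + 1L]] <- c(
        list(sequence = s, locus = locus), scr)
    }
  }
  screen_df <- do.call(rbind, lapply(screens, function(x)
    data.frame(sequence = x$sequence, chrom = x$locus$chrom,
               start = x$locus$start, end = x$locus$end,
               strand = x$locus$strand, pass = x$pass,
               failed = paste(x$verdict$failed, collapse = ","),
               window_start = x$window$start, window_end = x$window$end,
               mfei = x$metrics$mfei, mfe = x$metrics$mfe,
               gc_percent = x$metrics$gc_percent,
               stringsAsFactors = FALSE)))
  if (is.null(screen_df)) screen_df <- data.frame()

  # validated matures: passing screens, grouped into hairpin loci by
  # overlapping precursor windows
  mirnas <- data.frame()
  de <- data.frame()
  pass_idx <- which(vapply(screens, `[[`, TRUE, "pass"))
  if (length(pass_idx)) {
    pd <- do.call(rbind, lapply(pass_idx, function(i) {
      x <- screens[[i]]
      w <- x$window
      star_span <- x$duplex$star_span
      arm <- if (w$mir_span[1] < star_span[1]) "5p" else "3p"
      data.frame(sequence = x$sequence, chrom = x$locus$chrom,
                 start = x$locus$start, end = x$locus$end,
                 strand = x$locus$strand, arm = arm,
                 star_sequence = substr(w$sequence, star_span[1] + 1,
                                        star_span[2]),
                 star_observed = x$star_observed,
                 wstart = w$start, wend = w$end,
                 precursor_length = nchar(w$sequence),
                 mfe = x$metrics$mfe, mfei = x$metrics$mfei,
                 gc_percent = x$metrics$gc_percent,
                 stringsAsFactors = FALSE)
    }))
    pd <- pd[order(pd$chrom, pd$strand, pd$wstart), , drop = FALSE]
    grp <- integer(nrow(pd))
    gid <- 0L; last_end <- -1L; last_key <- ""
    for (i in seq_len(nrow(pd))) {
      key <- paste(pd$chrom[i], pd$strand[i])
      if (key != last_key || pd$wstart[i] > last_end) {
        gid <- gid + 1L
        last_end <- pd$wend[i]
      } else last_end <- max(last_end, pd$wend[i])
      last_key <- key
      grp[i] <- gid
    }
    pd$hairpin_id <- sprintf("hp%03d", grp)
    pd$family <- classes$family[match(pd$sequence, classes$sequence)]
    # both arms of one hairpin share a family: a conserved arm names its
    # (usually novel-looking) star arm too
    for (g in unique(pd$hairpin_id)) {
      sel <- pd$hairpin_id == g
      fams <- pd$family[sel]
      if (any(!is.na(fams)) && any(is.na(fams)))
        pd$family[sel] <- fams[!is.na(fams)][1]
    }
    named <- assign_names(pd, prefix = prefix, arm_style = arm_style)
    named$class <- classes$class[match(named$sequence, classes$sequence)]
    named$class[is.na(named$class)] <- "novel"
    keyed <- paste(pd$chrom, pd$start, pd$sequence)
    named_key <- paste(named$chrom, named$start, named$sequence)
    named$precursor_length <- pd$precursor_length[match(named_key, keyed)]
    named$mfe <- pd$mfe[match(named_key, keyed)]
    named$mfei <- pd$mfei[match(named_key, keyed)]
    named$gc_percent <- pd$gc_percent[match(named_key, keyed)]
    mirnas <- named
  }

  # expression table over identified matures plus known miRNAs
  expr_rows <- rbind(
    if (nrow(mirnas))
      data.frame(mir_name = mirnas$name, sequence = mirnas$sequence,
                 stringsAsFactors = FALSE),
    if (nrow(known))
      data.frame(mir_name = known$known_name, sequence = known$sequence,
                 stringsAsFactors = FALSE))
  if (!is.null(expr_rows) && nrow(expr_rows)) {
    expr_rows <- expr_rows[!duplicated(expr_rows$mir_name), , drop = FALSE]
    m <- match(expr_rows$sequence, counts$sequence)
    ct <- data.frame(mir_name = expr_rows$mir_name,
                     sequence = expr_rows$sequence,
                     reads_A = counts$count_A[m],
                     reads_B = counts$count_B[m],
                     stringsAsFactors = FALSE)
    de <- fold_change(normalize_rpm(ct, lib_sizes),
                      pseudo_rpm = pseudo_rpm)
  }

  res <- list(report_A = pre_A$report, report_B = pre_B$report,
              lib_sizes = lib_sizes, known = known, classes = classes,
              screens = screens, screen_table = screen_df,
              mirnas = mirnas, de = de)
  class(res) <- "mir_discovery"
  res
}

#' @export
print.mir_discovery <- function(x, ...) {
  cat("miRNA discovery result\n")
  cat(sprintf("  mappable reads: A %d / B %d\n",
              x$report_A$mappable_total, x$report_B$mappable_total))
  cat(sprintf("  known matures matched: %d\n",
              length(unique(x$known$known_name))))
  cat(sprintf("  candidate loci screened: %d\n", length(x$screens)))
  cat(sprintf("  validated matures: %d (%d hairpin loci)\n",
              nrow(x$mirnas),
              if (nrow(x$mirnas)) length(unique(x$mirnas$hairpin_id))
              else 0L))
  if (nrow(x$de))
    cat(sprintf("  differentially expressed (fold > 2): %d\n",
                sum(x$de$is_de)))
  invisible(x)
}

#' @export
summary.mir_discovery <- function(object, ...) {
  print(object)
  if (nrow(object$mirnas)) {
    cat("\nValidated matures (table style: name, LM, LP, CG%, dG, MFEI):\n")
    t3 <- object$mirnas
    df <- data.frame(name = t3$name, LM = t3$mature_length,
                     LP = t3$precursor_length,
                     CG = round(t3$gc_percent, 1),
                     dG = round(t3$mfe, 1), MFEI = round(t3$mfei, 1))
    print(df, row.names = FALSE)
  }
  invisible(object)
}

#' Score a discovery result against simulation truth
#'
#' Joins the pipeline output back onto the planted truth: which true
#' hairpins were recovered (either arm validated at the planted locus),
#' which decoys passed (none should), and the failed-criterion sets
#' reported for each decoy's mature candidate.
#'
#' @param result a `mir_discovery`.
#' @param sim the `srna_sim` that produced its input.
#' @return list with `recovery` (fraction of true hairpins recovered),
#'   `hairpins` (per-hairpin data frame with `recovered`,
#'   `decoy_passed`, `reported_failed`), and `de` (abundance truth
#'   joined with the pipeline's DE calls).
#' @export
score_discovery <- function(result, sim) {
  hp <- sim$truth$hairpins
  scr <- result$screen_table
  per <- lapply(seq_len(nrow(hp)), function(i) {
    at_mat <- scr[scr$sequence == hp$mature[i] &
                    scr$start == hp$mat_start[i] &
                    scr$strand == hp$strand[i], , drop = FALSE]
    at_star <- scr[scr$sequence == hp$star[i] &
                     scr$start == hp$star_start[i] &
                     scr$strand == hp$strand[i], , drop = FALSE]
    any_pass <- any(at_mat$pass) || any(at_star$pass)
    data.frame(hairpin_id = hp$hairpin_id[i], type = hp$type[i],
               violated = hp$violated[i],
               recovered = hp$type[i] == "true" && any_pass,
               decoy_passed = hp$type[i] != "true" && any_pass,
               reported_failed = if (nrow(at_mat))
                 at_mat$failed[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  truth_true <- per$type == "true"
  de_join <- merge(sim$truth$abundance, result$de,
                   by = "sequence", all.x = TRUE)
  list(recovery = mean(per$recovered[truth_true]),
       hairpins = per, de = de_join)
}
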