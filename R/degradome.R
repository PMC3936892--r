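#' Map degradome reads onto transcripts by their 5' ends
#'
#' A read contributes its count to the position of its 5'-most base on
#' every transcript where its first `anchor_len` nt match exactly, sense
#' strand only.  Reads matching several transcripts are counted on all of
#' them and flagged multi-mapped.
#'
#' @param reads a read data frame (or character vector of sequences with
#'   counts 1); reads shorter than `min_len` are ignored.
#' @param transcripts a `DNAStringSet` (or FASTA path).
#' @param anchor_len number of leading bases that must match exactly
#'   (reads shorter than this use their full length).
#' @param min_len minimum read length.
#' @return a list of class `degradome_profile_set`: per transcript an
#'   integer vector of per-position 5'-end counts (1-based positions);
#'   attribute `multimapped` lists multi-mapping anchor sequences.
#' @export
map_degradome_reads <- function(reads, transcripts, anchor_len = 20L,
                                min_len = 18L) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts))
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  if (!is.data.frame(reads))
    reads <- srna_reads(read_id = seq_along(reads), sequence = reads)
  reads <- reads[reads$kept & nchar(reads$sequence) >= min_len, ,
                 drop = FALSE]
  anchors <- substr(reads$sequence, 1L, anchor_len)
  cnt <- rowsum(reads$count, anchors)
  uniq <- rownames(cnt)
  profiles <- lapply(Biostrings::width(transcripts), integer)
  names(profiles) <- names(transcripts)
  n_tx_hit <- setNames(integer(length(uniq)), uniq)
  for (ti in seq_along(transcripts)) {
    subject <- transcripts[[ti]]
    for (ai in seq_along(uniq)) {
      m <- Biostrings::matchPattern(uniq[ai], subject)
      if (!length(m)) next
      n_tx_hit[ai] <- n_tx_hit[ai] + 1L
      pos <- Biostrings::start(m)
      profiles[[ti]][pos] <- profiles[[ti]][pos] + cnt[ai, 1]
    }
  }
  attr(profiles, "multimapped") <- names(n_tx_hit)[n_tx_hit > 1]
  class(profiles) <- "degradome_profile_set"
  profiles
}

#' Assign a t-plot abundance category to a cleavage evidence site
#'
#' CleaveLand-style conventions: category 0, more than one read at the
#' site, equal to the transcript maximum and the maximum is unique;
#' category 1, equal to a shared maximum; category 2, below the maximum
#' but above the median of the nonzero positions; category 3, at or below
#' that median but more than one read; category 4, exactly one read.
#'
#' @param profile integer vector of per-position counts for one
#'   transcript.
#' @param site 1-based transcript position with at least one read.
#' @return integer category 0-4.
#' @export
assign_category <- function(profile, site) {
  x <- profile[site]
  if (is.na(x) || x < 1) stop("no degradome evidence at site ", site)
  if (x == 1) return(4L)
  mx <- max(profile)
  if (x == mx) {
    return(if (sum(profile == mx) == 1L) 0L else 1L)
  }
  med <- median(profile[profile > 0])
  if (x > med) 2L else 3L
}

#' Align a miRNA against a transcript with plant-standard penalties
#'
#' Ungapped scanning of every window of miRNA length on the sense strand
#' of the transcript, the miRNA 5' end facing the window's 3' end.
#' Penalty: mismatch 1, G:U wobble 0.5, doubled at miRNA positions 2-13;
#' windows scoring at most `cutoff` are retained.  The predicted cleavage
#' site is the transcript position opposite miRNA position 10 counted from
#' the miRNA 5' end.
#'
#' @param mir_sequence mature miRNA (DNA alphabet).
#' @param transcript_sequence transcript (DNA alphabet); or a
#'   `DNAStringSet` scanned transcript by transcript.
#' @param cutoff maximum retained penalty score.
#' @param core miRNA positions with doubled penalties.
#' @return data frame with one row per retained window: `binding_start`,
#'   `binding_end` (1-based inclusive), `score`, `cleavage_site`,
#'   `labels` (per-position `|` match, `o` G:U, `x` mismatch, 5'->3' of
#'   the miRNA); plus `transcript_id` when a set is given.
#' @export
align_mir_target <- function(mir_sequence, transcript_sequence,
                             cutoff = 4.5, core = 2:13) {
  if (is(transcript_sequence, "XStringSet") ||
      (is.character(transcript_sequence) &&
         !is.null(names(transcript_sequence)) &&
         length(transcript_sequence) > 1)) {
    txs <- if (is(transcript_sequence, "XStringSet"))
      setNames(as.character(transcript_sequence),
               names(transcript_sequence)) else transcript_sequence
    out <- lapply(names(txs), function(id) {
      r <- align_mir_target(mir_sequence, txs[[id]], cutoff, core)
      if (nrow(r)) r$transcript_id <- id
      r
    })
    out <- out[vapply(out, nrow, 0L) > 0]
    if (!length(out))
      return(data.frame(binding_start = integer(), binding_end = integer(),
                        score = numeric(), cleavage_site = integer(),
                        labels = character(), transcript_id = character(),
                        stringsAsFactors = FALSE))
    return(do.call(rbind, out))
  }
  mir <- toupper(as.character(mir_sequence))
  tx <- toupper(as.character(transcript_sequence))
  m <- nchar(mir)
  L <- nchar(tx)
  empty <- data.frame(binding_start = integer(), binding_end = integer(),
                      score = numeric(), cleavage_site = integer(),
                      labels = character(), stringsAsFactors = FALSE)
  if (L < m) return(empty)
  mchars <- strsplit(mir, "")[[1]]
  tchars <- strsplit(tx, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "@")
  wobble <- c(G = "T", T = "G")  # miR G:U(T), miR U(T):G
  nwin <- L - m + 1L
  weight <- ifelse(seq_len(m) %in% core, 2, 1)
  # miRNA position k faces transcript position b2 - k + 1 (b2 = b1 + m - 1)
  pen <- matrix(0, nrow = m, ncol = nwin)
  lab <- matrix("|", nrow = m, ncol = nwin)
  for (k in seq_len(m)) {
    tpos <- (seq_len(nwin) + m - 1L) - k + 1L
    tb <- tchars[tpos]
    is_match <- tb == comp[[mchars[k]]]
    is_gu <- !is_match & !is.na(wobble[mchars[k]]) &
      tb == unname(wobble[mchars[k]])
    pen[k, ] <- weight[k] * ifelse(is_match, 0, ifelse(is_gu, 0.5, 1))
    lab[k, ] <- ifelse(is_match, "|", ifelse(is_gu, "o", "x"))
  }
  score <- colSums(pen)
  keep <- which(score <= cutoff)
  if (!length(keep)) return(empty)
  data.frame(
    binding_start = keep,
    binding_end = keep + m - 1L,
    score = score[keep],
    cleavage_site = keep + m - 1L - 9L,
    labels = apply(lab[, keep, drop = FALSE], 2, paste, collapse = ""),
    stringsAsFactors = FALSE)
}

#' Check a cleavage site against the 9th/10th-nucleotide rule
#'
#' The accepted cleavage evidence must fall on the 9th or 10th nucleotide
#' of the target binding region.  Counting from the binding-region end
#' adjacent to the miRNA 5' end (`count_from = "mir5"`, the default), the
#' 9th and 10th nucleotides are the positions opposite miRNA nucleotides 9
#' and 10, which brackets the canonical cleavage between positions 10 and
#' 11.  `count_from = "target5"` counts from the 5' end of the binding
#' region on the target instead.  Sites outside the binding region are
#' always `FALSE`.
#'
#' @param alignment one row (list or data frame) with `binding_start`,
#'   `binding_end`.
#' @param observed_site 1-based transcript position of the degradome
#'   evidence.
#' @param count_from counting convention, see Details.
#' @return logical.
#' @export
check_cleavage_position <- function(alignment, observed_site,
                                    count_from = c("mir5", "target5")) {
  count_from <- match.arg(count_from)
  b1 <- alignment$binding_start
  b2 <- alignment$binding_end
  if (observed_site < b1 || observed_site > b2) return(FALSE)
  pos <- if (count_from == "mir5") b2 - observed_site + 1L
  else observed_site - b1 + 1L
  pos %in% c(9L, 10L)
}

#' Call miRNA targets from alignments and degradome profiles
#'
#' A call is emitted when an alignment is retained, the degradome evidence
#' at the cleavage site passes the 9th/10th-nucleotide rule, and the site
#' holds at least one read.  The evidence site is the better-supported of
#' the two admissible positions (opposite miRNA nucleotides 9 and 10).
#' The abundance category is attached, the Arabidopsis homolog looked up
#' from the user-supplied map (a missing map downgrades the homology
#' criterion to a warning), and calls are sorted by family, category and
#' decreasing reads.
#'
#' @param alignments data frame from [align_mir_target()] with
#'   `transcript_id` plus a `mir_name` column added by the caller.
#' @param profiles a `degradome_profile_set`.
#' @param homology_map data frame from [read_homology_map()], or `NULL`.
#' @param count_from cleavage counting convention, see
#'   [check_cleavage_position()].
#' @return data frame of target calls: `mir_name`, `mir_family`,
#'   `transcript_id`, `cleavage_site`, `reads_at_site`, `category`,
#'   `score`, `homolog`, `conserved_flag`.
#' @export
call_targets <- function(alignments, profiles, homology_map = NULL,
                         count_from = c("mir5", "target5")) {
  count_from <- match.arg(count_from)
  if (is.null(homology_map))
    warning("no homology map supplied; homology criterion is advisory")
  calls <- list()
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    prof <- profiles[[al$transcript_id]]
    if (is.null(prof)) next
    # admissible evidence sites: opposite miRNA nt 10 and nt 9
    sites <- c(al$binding_end - 9L, al$binding_end - 8L)
    sites <- sites[sites >= 1 & sites <= length(prof)]
    sites <- sites[order(-prof[sites])]
    if (!length(sites) || prof[sites[1]] < 1) next
    site <- sites[1]
    if (!check_cleavage_position(al, site, count_from)) next
    homolog <- NA_character_
    conserved <- FALSE
    fam <- mir_family(al$mir_name)
    if (!is.null(homology_map)) {
      j <- match(al$transcript_id, homology_map$transcript_id)
      if (is.na(j)) {
        warning("transcript ", al$transcript_id,
                " absent from homology map; call emitted unannotated")
      } else {
        homolog <- homology_map$at_gene_id[j]
        conserved <- identical(homology_map$known_target_of[j], fam)
      }
    }
    calls[[length(calls) + 1L]] <- data.frame(
      mir_name = al$mir_name, mir_family = fam,
      transcript_id = al$transcript_id,
      cleavage_site = site, reads_at_site = prof[site],
      category = assign_category(prof, site), score = al$score,
      homolog = homolog, conserved_flag = conserved,
      stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(mir_name = character(), mir_family = character(),
                      transcript_id = character(),
                      cleavage_site = integer(), reads_at_site = integer(),
                      category = integer(), score = numeric(),
                      homolog = character(), conserved_flag = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$mir_family, out$category, -out$reads_at_site), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit a t-plot table for one transcript
#'
#' Per-position degradome read counts with the cleavage site flagged,
#' suitable for any plotting tool.
#'
#' @param profile integer vector of per-position counts.
#' @param site 1-based cleavage site.
#' @return data frame with `position`, `reads`, `is_site`.
#' @export
emit_tplot <- function(profile, site) {
  data.frame(position = seq_along(profile), reads = as.integer(profile),
             is_site = seq_along(profile) == site)
}

#' Plot a degradome t-plot
#'
#' @param x a t-plot table from [emit_tplot()].
#' @param ... further arguments to [plot()].
#' @export
plot_tplot <- function(x, ...) {
  plot(x$position, x$reads, type = "h", xlab = "transcript position (nt)",
       ylab = "degradome reads", ...)
  s <- x[x$is_site, , drop = FALSE]
  if (nrow(s))
    arrows(s$position, s$reads + max(x$reads) * 0.12, s$position,
           s$reads + max(x$reads) * 0.02, length = 0.08, col = "red")
  invisible(x)
}
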