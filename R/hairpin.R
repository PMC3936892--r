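#' Extract precursor candidate windows around a genome locus
#'
#' For each flank size in the ladder, one window centred on the mature
#' locus is extracted (truncated at contig ends).  Downstream screening
#' retains the smallest window whose structure passes all criteria.
#' Windows are returned in the read's orientation: minus-strand loci are
#' reverse-complemented and the mature span re-expressed in window
#' coordinates (0-based half-open).
#'
#' @param genome a `DNAStringSet`.
#' @param locus list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param flank_steps flank sizes (nt each side), smallest first.
#' @return list of windows, each a list with `chrom`, `start`, `end`,
#'   `strand`, `flank`, `sequence`, `mir_span` (c(start, end), 0-based
#'   half-open window coordinates).  Empty list (with a message) when the
#'   locus admits no flanking sequence at all.
#' @export
extract_precursor_windows <- function(genome, locus,
                                      flank_steps = c(20, 50, 100, 150)) {
  chrom_len <- Biostrings::width(genome)[match(locus$chrom, names(genome))]
  if (is.na(chrom_len)) stop("unknown chrom: ", locus$chrom)
  out <- list()
  for (flank in flank_steps) {
    ws <- max(0L, locus$start - flank)
    we <- min(chrom_len, locus$end + flank)
    if (ws == locus$start && we == locus$end) next  # zero extractable flank
    seq <- as.character(Biostrings::subseq(genome[[locus$chrom]],
                                           ws + 1L, we))
    if (locus$strand == "-") {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      mir_span <- c(we - locus$end, we - locus$start)
    } else {
      mir_span <- c(locus$start - ws, locus$end - ws)
    }
    out[[length(out) + 1L]] <- list(
      chrom = locus$chrom, start = ws, end = we, strand = locus$strand,
      flank = flank, sequence = seq, mir_span = mir_span)
  }
  if (!length(out))
    message("locus ", locus$chrom, ":", locus$start, "-", locus$end,
            " has no extractable flank; candidate skipped")
  out
}

#' Fold a sequence into a hairpin secondary structure
#'
#' The built-in backend is a weighted maximum base-pairing dynamic program
#' (Watson-Crick plus G:U wobble, minimum hairpin loop of 3) with an
#' explicit energy proxy of -2.0 kcal/mol per GC pair and -1.0 per AU or
#' GU pair.  It is a screening-grade stand-in, not a nearest-neighbour
#' thermodynamic model; externally computed Vienna dot-bracket structures
#' can be supplied instead and are parsed verbatim.
#'
#' @param sequence DNA or RNA string; `N` is treated as unpairable.
#' @param backend `"nussinov"` (built-in) or `"vienna_file"`.
#' @param structure_file for `"vienna_file"`, a dot-bracket file whose
#'   first record matching `sequence` (or the first record) is used.
#' @return list with `structure` (dot-bracket) and `mfe` (kcal/mol, <= 0).
#' @export
fold_hairpin <- function(sequence, backend = c("nussinov", "vienna_file"),
                         structure_file = NULL) {
  backend <- match.arg(backend)
  sequence <- toupper(sequence)
  if (grepl("[^ACGUTN]", sequence))
    stop("fold_hairpin: sequence contains non-ACGU(T)N characters")
  if (backend == "vienna_file") {
    recs <- read_vienna(structure_file)
    seq_t <- chartr("U", "T", sequence)
    hit <- which(vapply(recs, function(r)
      chartr("U", "T", r$sequence) == seq_t, TRUE))
    r <- recs[[if (length(hit)) hit[1] else 1L]]
    return(list(structure = r$structure, mfe = r$mfe))
  }
  .nussinov_fold(sequence, 3L)
}

#' Pairing partners from a dot-bracket string
#'
#' @param structure dot-bracket string (round brackets).
#' @return integer vector, `partner[i]` = 1-based partner of position i or
#'   0 when unpaired.
#' @export
pairing_partners <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  partner <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets")
  partner
}

#' Evaluate the miRNA/miRNA* duplex of a precursor candidate
#'
#' Works directly on the dot-bracket structure.  A mismatch is a mature
#' position that is unpaired or paired outside the star span; the longest
#' consecutive run of such positions is tracked separately.  An asymmetric
#' bulge is a maximal run of unpaired positions on one strand of the
#' duplex with no opposing unpaired run.  `overhang_3p_ok` requires both
#' strands' 3' ends to extend exactly 2 nt beyond the partner's pairing
#' region; `opposite_arms_ok` requires the two spans to flank the hairpin
#' terminal loop (a span overlapping the loop fails the flag rather than
#' erroring).
#'
#' When the star span is not observed from reads it is inferred as the
#' positions paired to the mature span extended by the 2-nt 3' overhang.
#'
#' @param structure dot-bracket string of the precursor window.
#' @param mir_span mature span, c(start, end), 0-based half-open.
#' @param star_span observed star span (same convention) or `NULL` to
#'   infer it from the structure.
#' @return a list (`duplex_report`): `mismatch_count`,
#'   `max_consecutive_mismatches`, `asymmetric_bulge_count`,
#'   `max_asymmetric_bulge_size`, `overhang_3p_ok`, `opposite_arms_ok`,
#'   `star_span` (used), `star_inferred`.
#' @export
evaluate_duplex <- function(structure, mir_span, star_span = NULL) {
  partner <- pairing_partners(structure)
  n <- length(partner)
  mir_idx <- (mir_span[1] + 1L):mir_span[2]   # 1-based positions
  star_inferred <- is.null(star_span)
  if (star_inferred) {
    p <- partner[mir_idx]
    p <- p[p > 0]
    if (!length(p)) {
      res <- list(
        mismatch_count = length(mir_idx),
        max_consecutive_mismatches = length(mir_idx),
        asymmetric_bulge_count = 0L, max_asymmetric_bulge_size = 0L,
        overhang_3p_ok = FALSE, opposite_arms_ok = FALSE,
        star_span = NULL, star_inferred = TRUE)
      class(res) <- "duplex_report"
      return(res)
    }
    star_span <- c(min(p) - 1L, min(n, max(p) + 2L))
  }
  star_idx <- (star_span[1] + 1L):star_span[2]
  in_star <- function(x) x >= star_span[1] + 1L & x <= star_span[2]
  in_mir <- function(x) x >= mir_span[1] + 1L & x <= mir_span[2]

  mm <- !(partner[mir_idx] > 0 & in_star(partner[mir_idx]))
  anchors <- mir_idx[!mm]
  # up to 2 trailing unpaired bases at the mature 3' end are the expected
  # duplex overhang, not mismatches
  mm_eff <- mm
  if (length(anchors)) {
    trailing <- mir_span[2] - max(anchors)
    drop <- min(trailing, 2L)
    if (drop > 0) mm_eff <- mm_eff[seq_len(length(mm_eff) - drop)]
  }
  mismatch_count <- sum(mm_eff)
  runs <- rle(mm_eff)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  bulge_sizes <- integer(0)
  if (length(anchors) >= 2) {
    for (k in seq_len(length(anchors) - 1L)) {
      i <- anchors[k]; j <- anchors[k + 1L]
      gm <- j - i - 1L
      gs <- abs(partner[i] - partner[j]) - 1L
      if (gm > 0L && gs == 0L) bulge_sizes <- c(bulge_sizes, gm)
      if (gs > 0L && gm == 0L) bulge_sizes <- c(bulge_sizes, gs)
    }
  }
  # unpaired star bases beyond the outermost mature anchors fall under the
  # overhang check rather than the bulge ledger
  star_paired <- star_idx[partner[star_idx] > 0 & in_mir(partner[star_idx])]
  overhang_ok <- length(anchors) > 0 && length(star_paired) > 0 &&
    (mir_span[2] - max(anchors)) == 2L &&
    (star_span[2] - max(star_paired)) == 2L

  # opposite arms: spans disjoint and ordered, the duplex pairs across the
  # apex (no base of either span pairs within its own span or with the
  # region between the spans -- a span crossing the terminal loop does one
  # of those), and at least one mature base anchors into the star span
  opposite <- FALSE
  if (star_span[1] >= mir_span[2] || mir_span[1] >= star_span[2]) {
    up <- if (mir_span[1] < star_span[1]) mir_span else star_span
    dn <- if (mir_span[1] < star_span[1]) star_span else mir_span
    gap <- if (dn[1] > up[2]) (up[2] + 1L):dn[1] else integer(0)
    span_pos <- c(mir_idx, star_idx)
    pp <- partner[span_pos]
    self_or_gap <- pp > 0 &
      ((pp %in% span_pos &
          ((span_pos <= up[2] & pp <= up[2]) |
             (span_pos > up[2] & pp > up[2]))) |
         pp %in% gap)
    opposite <- length(anchors) > 0 && !any(self_or_gap)
  }

  res <- list(
    mismatch_count = as.integer(mismatch_count),
    max_consecutive_mismatches = as.integer(max_run),
    asymmetric_bulge_count = length(bulge_sizes),
    max_asymmetric_bulge_size = if (length(bulge_sizes))
      max(bulge_sizes) else 0L,
    overhang_3p_ok = overhang_ok,
    opposite_arms_ok = opposite,
    star_span = star_span,
    star_inferred = star_inferred)
  class(res) <- "duplex_report"
  res
}

#' Precursor thermodynamic metrics: GC%, MFE, AMFE and MFEI
#'
#' AMFE is the absolute folding energy per 100 nt of precursor; MFEI is
#' AMFE divided by the GC percentage.  Values are kept at full precision;
#' table-style reports round to one decimal.  Either a sequence or an
#' explicit (`length`, `gc_percent`) pair may be given, the latter for
#' recomputing published table rows.
#'
#' @param sequence precursor sequence (optional when `length` and
#'   `gc_percent` are given).
#' @param mfe minimum folding energy, kcal/mol (<= 0).
#' @param length precursor length, nt.
#' @param gc_percent GC percentage of the precursor (0-100].
#' @return list with `gc_percent`, `mfe`, `amfe`, `mfei`.
#' @export
compute_metrics <- function(sequence = NULL, mfe, length = NULL,
                            gc_percent = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (is.null(length)) length <- nchar(sequence)
    if (is.null(gc_percent)) {
      gc <- nchar(gsub("[^GC]", "", sequence))
      gc_percent <- 100 * gc / nchar(sequence)
    }
  }
  if (is.null(length) || length == 0) stop("zero-length precursor")
  if (is.null(gc_percent) || gc_percent <= 0)
    stop("gc_percent must be > 0")
  amfe <- abs(mfe) / length * 100
  list(gc_percent = gc_percent, mfe = mfe, amfe = amfe,
       mfei = amfe / gc_percent)
}

#' Apply the five-criterion screen to a candidate hairpin
#'
#' PASS requires: (1) the star sequence observed in the sequencing data;
#' (2) fewer than 4 duplex mismatches and no run of 4 consecutive
#' mismatches; (3) at most one asymmetric bulge of at most 2 nt; (4) the
#' two matures on opposite stem arms forming a duplex with 2-nt 3'
#' overhangs; (5) MFEI strictly greater than `mfei_min`.  Every failure
#' lists the violated criteria.
#'
#' @param duplex a `duplex_report` from [evaluate_duplex()].
#' @param metrics a metrics list from [compute_metrics()].
#' @param star_observed was the star sequenced?
#' @param max_mismatches,max_mismatch_run,max_bulges,max_bulge_size,mfei_min
#'   screen thresholds (defaults follow the published criteria; the bulge
#'   size bound of 2 nt is configurable).
#' @return list with `pass`, `criteria` (named logical over the five
#'   criteria), `flags` (granular sub-checks), `failed` (names of failed
#'   criteria).
#' @export
classify_candidate <- function(duplex, metrics, star_observed,
                               max_mismatches = 3L, max_mismatch_run = 3L,
                               max_bulges = 1L, max_bulge_size = 2L,
                               mfei_min = 0.8) {
  flags <- c(
    star_detected = isTRUE(star_observed),
    mismatch_total_ok = duplex$mismatch_count <= max_mismatches,
    mismatch_run_ok = duplex$max_consecutive_mismatches <= max_mismatch_run,
    bulge_count_ok = duplex$asymmetric_bulge_count <= max_bulges,
    bulge_size_ok = duplex$max_asymmetric_bulge_size <= max_bulge_size,
    overhang_ok = isTRUE(duplex$overhang_3p_ok),
    opposite_arms_ok = isTRUE(duplex$opposite_arms_ok),
    mfei_ok = metrics$mfei > mfei_min)
  criteria <- c(
    star = flags[["star_detected"]],
    mismatches = flags[["mismatch_total_ok"]] && flags[["mismatch_run_ok"]],
    bulges = flags[["bulge_count_ok"]] && flags[["bulge_size_ok"]],
    duplex_geometry = flags[["overhang_ok"]] && flags[["opposite_arms_ok"]],
    mfei = flags[["mfei_ok"]])
  list(pass = all(criteria), criteria = criteria, flags = flags,
       failed = names(criteria)[!criteria])
}

#' Screen one candidate locus through the precursor window ladder
#'
#' Extracts the flank ladder, folds each window, evaluates the duplex and
#' the thermodynamic metrics, and retains the smallest window passing all
#' criteria.  When no window passes, the window with the fewest failed
#' criteria (smallest first on ties) is reported so the rejection reason
#' is well defined.
#'
#' @param genome a `DNAStringSet`.
#' @param locus candidate locus (list with `chrom`, `start`, `end`,
#'   `strand`).
#' @param star_finder function(window) returning a list of candidate
#'   observed star spans (each c(start, end), 0-based half-open window
#'   coordinates, e.g. from mapped read hits inside the window), or
#'   `NULL` when star evidence is not available.  The candidate span
#'   closest to the structure-inferred star span (both ends within
#'   `star_tol` nt) is taken as the observed star.
#' @param flank_steps flank ladder.
#' @param star_tol per-end tolerance when matching an observed star span
#'   against the inferred one.
#' @param fold_fun folding backend, defaults to [fold_hairpin()].
#' @param ... thresholds passed to [classify_candidate()].
#' @return list with `pass`, `verdict` (classification of the reported
#'   window), `window`, `structure`, `duplex`, `metrics`,
#'   `star_observed`.  `NULL` when no window is extractable.
#' @export
screen_hairpin <- function(genome, locus, star_finder = NULL,
                           flank_steps = c(20, 50, 100, 150),
                           star_tol = 3L, fold_fun = fold_hairpin, ...) {
  windows <- extract_precursor_windows(genome, locus, flank_steps)
  if (!length(windows)) return(NULL)
  best <- NULL
  for (w in windows) {
    fold <- fold_fun(w$sequence)
    duplex <- evaluate_duplex(fold$structure, w$mir_span, NULL)
    star_observed <- FALSE
    if (!is.null(star_finder) && !is.null(duplex$star_span)) {
      wlen <- nchar(w$sequence)
      inferred <- duplex$star_span
      cands <- star_finder(w)
      cands <- Filter(function(s)
        s[1] >= 0 && s[2] <= wlen && s[1] < s[2] &&
          abs(s[1] - inferred[1]) <= star_tol &&
          abs(s[2] - inferred[2]) <= star_tol, cands)
      if (length(cands)) {
        dev <- vapply(cands, function(s)
          abs(s[1] - inferred[1]) + abs(s[2] - inferred[2]), 0)
        obs <- cands[[which.min(dev)]]
        duplex <- evaluate_duplex(fold$structure, w$mir_span, obs)
        star_observed <- TRUE
      }
    }
    metrics <- compute_metrics(w$sequence, fold$mfe)
    verdict <- classify_candidate(duplex, metrics,
                                  star_observed = star_observed, ...)
    res <- list(pass = verdict$pass, verdict = verdict, window = w,
                structure = fold$structure, duplex = duplex,
                metrics = metrics, star_observed = star_observed)
    if (verdict$pass) return(res)
    if (is.null(best) ||
        length(verdict$failed) < length(best$verdict$failed))
      best <- res
  }
  best
}
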