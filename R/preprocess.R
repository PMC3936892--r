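#' Trim the 3' sequencing adapter from small RNA reads
#'
#' A prefix of the adapter of at least `min_overlap` bases must align to the
#' 3' end of the read (the match extends to the last base of the read)
#' within the allowed mismatch rate.  The leftmost (5'-most) qualifying
#' match wins and the insert upstream of it is kept.  Reads without a match
#' are flagged `no_3adt`.  A zero-length insert (read equal to the adapter)
#' is kept here and removed as `too_short` by the length filter.
#'
#' @param reads a read data frame (see [srna_reads()]).
#' @param adapter 3' adapter DNA sequence.
#' @param min_overlap minimum adapter prefix length, >= 6.
#' @param max_mismatch_rate allowed mismatches per overlap base; `N` never
#'   matches.
#' @return the read data frame with trimmed sequences and updated state.
#' @export
trim_3p_adapter <- function(reads, adapter, min_overlap = 6L,
                            max_mismatch_rate = 0.1) {
  adapter <- toupper(adapter)
  if (nchar(adapter) < min_overlap || min_overlap < 6)
    stop("adapter length >= min_overlap >= 6 required")
  bad <- grepl("[^ACGTN]", reads$sequence)
  if (any(bad))
    stop("non-ACGTN characters in read(s): ",
         paste(head(reads$read_id[bad], 5), collapse = ", "))
  idx <- which(reads$kept)
  if (!length(idx)) return(reads)
  seqs <- reads$sequence[idx]
  insert_len <- rep(NA_integer_, length(seqs))
  achars <- strsplit(adapter, "")[[1]]
  K <- length(achars)
  for (L in sort(unique(nchar(seqs)))) {
    sel <- which(nchar(seqs) == L)
    if (L < min_overlap) next  # cannot host a qualifying match
    M <- matrix(unlist(strsplit(seqs[sel], ""), use.names = FALSE),
                nrow = length(sel), ncol = L, byrow = TRUE)
    unresolved <- seq_along(sel)
    for (k in max(0L, L - K):(L - min_overlap)) {
      if (!length(unresolved)) break
      overlap <- L - k
      cmp <- M[unresolved, (k + 1):L, drop = FALSE] !=
        matrix(achars[1:overlap], nrow = length(unresolved),
               ncol = overlap, byrow = TRUE)
      mm <- rowSums(cmp)
      hit <- mm <= floor(max_mismatch_rate * overlap)
      if (any(hit)) {
        insert_len[sel[unresolved[hit]]] <- k
        unresolved <- unresolved[!hit]
      }
    }
  }
  found <- !is.na(insert_len)
  reads$sequence[idx[found]] <-
    substr(seqs[found], 1L, insert_len[found])
  reads$kept[idx[!found]] <- FALSE
  reads$removal_reason[idx[!found]] <- "no_3adt"
  reads
}

#' Filter reads by insert length
#'
#' Bounds are inclusive; shorter reads are flagged `too_short`, longer ones
#' `too_long`.
#'
#' @param reads a read data frame (adapter-trimmed).
#' @param min_len,max_len inclusive length bounds.
#' @return the updated read data frame.
#' @export
filter_by_length <- function(reads, min_len = 15L, max_len = 30L) {
  if (min_len > max_len) stop("min_len > max_len")
  idx <- which(reads$kept)
  len <- nchar(reads$sequence[idx])
  short <- len < min_len
  long <- len > max_len
  reads$kept[idx[short | long]] <- FALSE
  reads$removal_reason[idx[short]] <- "too_short"
  reads$removal_reason[idx[long]] <- "too_long"
  reads
}

#' Remove low-complexity and N-rich junk reads
#'
#' A read is junk when its fraction of `N` bases exceeds `max_n_fraction`
#' or it is composed of fewer than `min_distinct_bases` distinct
#' A/C/G/T bases (homopolymer and dimer artifacts).
#'
#' @param reads a read data frame.
#' @param max_n_fraction maximum tolerated N fraction.
#' @param min_distinct_bases minimum number of distinct bases.
#' @return the updated read data frame.
#' @export
remove_junk <- function(reads, max_n_fraction = 0.1,
                        min_distinct_bases = 3L) {
  idx <- which(reads$kept)
  s <- reads$sequence[idx]
  len <- nchar(s)
  n_frac <- (len - nchar(gsub("N", "", s, fixed = TRUE))) / pmax(len, 1L)
  distinct <- rowSums(cbind(grepl("A", s, fixed = TRUE),
                            grepl("C", s, fixed = TRUE),
                            grepl("G", s, fixed = TRUE),
                            grepl("T", s, fixed = TRUE)))
  junk <- n_frac > max_n_fraction | distinct < min_distinct_bases
  reads$kept[idx[junk]] <- FALSE
  reads$removal_reason[idx[junk]] <- "junk"
  reads
}

# one string per strand for exact substring containment tests
contaminant_haystack <- function(set) {
  if (is.null(set) || !length(set)) return(NULL)
  if (is(set, "XStringSet")) set <- as.character(set)
  set <- toupper(set)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(set)))
  paste(c(set, rc), collapse = "|")
}

#' Remove reads matching contaminant (Rfam/Repbase-style) sets
#'
#' A read matching any contaminant sequence exactly as a substring, on
#' either strand, is removed with the first matching category; the fixed
#' order rfam-then-repbase keeps the ledger categories disjoint.
#'
#' @param reads a read data frame.
#' @param rfam_set,repbase_set contaminant sequences (character vector,
#'   `DNAStringSet`, or `NULL`).
#' @return the updated read data frame.
#' @export
remove_contaminants <- function(reads, rfam_set = NULL, repbase_set = NULL) {
  hays <- list(rfam = contaminant_haystack(rfam_set),
               repbase = contaminant_haystack(repbase_set))
  if (all(vapply(hays, is.null, TRUE))) {
    warning("empty contaminant sets: contaminant filter is a no-op")
    return(reads)
  }
  idx <- which(reads$kept)
  seqs <- reads$sequence[idx]
  uniq <- unique(seqs)
  cat_of <- setNames(rep("", length(uniq)), uniq)
  for (category in names(hays)) {
    hay <- hays[[category]]
    if (is.null(hay)) next
    todo <- names(cat_of)[cat_of == ""]
    hit <- vapply(todo, function(s) grepl(s, hay, fixed = TRUE), TRUE)
    cat_of[todo[hit]] <- category
  }
  category <- cat_of[seqs]
  removed <- category != ""
  reads$kept[idx[removed]] <- FALSE
  reads$removal_reason[idx[removed]] <- category[removed]
  reads
}

#' Build the removal ledger for a filtered read set
#'
#' Totals are computed over read counts, unique totals over distinct
#' sequences.  Categories are disjoint because the filter chain applies
#' them in a fixed order (adapter, length, junk, rfam, repbase), so the raw
#' total always equals mappable plus the sum of removals.
#'
#' @param reads a fully filtered read data frame.
#' @return a `filter_report` object.
#' @export
build_accounting <- function(reads) {
  reasons <- c("no_3adt", "too_short", "too_long", "junk", "rfam", "repbase")
  removed <- setNames(integer(length(reasons)), reasons)
  removed_unique <- removed
  for (r in reasons) {
    sel <- reads$removal_reason == r
    removed[r] <- sum(reads$count[sel])
    removed_unique[r] <- length(unique(reads$sequence[sel]))
  }
  kept <- reads$kept
  report <- list(
    raw_total = sum(reads$count),
    raw_unique = length(unique(reads$sequence)),
    removed = removed,
    removed_unique = removed_unique,
    mappable_total = sum(reads$count[kept]),
    mappable_unique = length(unique(reads$sequence[kept])))
  report$surviving_15_30 <- report$raw_total - removed["no_3adt"] -
    removed["too_short"] - removed["too_long"] - removed["junk"]
  report$surviving_15_30 <- unname(report$surviving_15_30)
  class(report) <- "filter_report"
  report
}

#' Construct a removal ledger from category totals
#'
#' Pure ledger arithmetic over stated removal counts, as used when checking
#' a published accounting table: the surviving 15-30 nt total is the raw
#' total minus the adapter, length and junk removals; the mappable total
#' further subtracts the contaminant categories.
#'
#' @param raw_total total raw reads.
#' @param removed named vector with any of `no_3adt`, `too_short`,
#'   `too_long`, `junk`, `rfam`, `repbase`.
#' @param raw_unique,removed_unique,mappable_unique optional unique-sequence
#'   totals.
#' @return a `filter_report` object.
#' @export
filter_report <- function(raw_total, removed = integer(),
                          raw_unique = NA_integer_,
                          removed_unique = integer(),
                          mappable_unique = NA_integer_) {
  reasons <- c("no_3adt", "too_short", "too_long", "junk", "rfam", "repbase")
  rem <- setNames(numeric(length(reasons)), reasons)
  rem[names(removed)] <- removed
  remu <- setNames(rep(NA_real_, length(reasons)), reasons)
  remu[names(removed_unique)] <- removed_unique
  report <- list(
    raw_total = raw_total, raw_unique = raw_unique,
    removed = rem, removed_unique = remu,
    mappable_total = raw_total - sum(rem),
    mappable_unique = mappable_unique,
    surviving_15_30 = unname(raw_total - rem["no_3adt"] - rem["too_short"] -
                               rem["too_long"] - rem["junk"]))
  class(report) <- "filter_report"
  report
}

#' @export
print.filter_report <- function(x, ...) {
  rows <- c("Raw reads" = x$raw_total,
            "Removed: 3' adapter not found" = unname(x$removed["no_3adt"]),
            "Removed: too short" = unname(x$removed["too_short"]),
            "Removed: too long" = unname(x$removed["too_long"]),
            "Removed: junk reads" = unname(x$removed["junk"]),
            "Removed: Rfam" = unname(x$removed["rfam"]),
            "Removed: Repbase" = unname(x$removed["repbase"]),
            "Surviving 15-30 nt" = x$surviving_15_30,
            "Mappable sequences" = x$mappable_total)
  cat("Small RNA filter report\n")
  for (i in seq_along(rows))
    cat(sprintf("  %-32s %12.0f\n", names(rows)[i], rows[i]))
  invisible(x)
}

#' Write a filter report as a ledger-style TSV
#'
#' One row per category with read and unique-sequence totals.
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    category = c("raw", "no_3adt", "too_short", "too_long", "junk",
                 "rfam", "repbase", "surviving_15_30", "mappable"),
    sequences = c(report$raw_total, unname(report$removed),
                  report$surviving_15_30, report$mappable_total),
    unique_sequences = c(report$raw_unique, unname(report$removed_unique),
                         NA, report$mappable_unique))
  write_tsv(df, path)
}

#' Run the full preprocessing chain
#'
#' Applies adapter trimming, inclusive length bounds, the junk screen and
#' contaminant removal in the fixed ledger order, then builds the
#' accounting report.
#'
#' @param reads a read data frame.
#' @param adapter 3' adapter sequence.
#' @param rfam_set,repbase_set contaminant sequence sets (optional).
#' @param min_len,max_len length bounds.
#' @param min_overlap,max_mismatch_rate adapter-matching parameters.
#' @param max_n_fraction,min_distinct_bases junk-screen parameters.
#' @return a list with `reads` (filtered read table) and `report`.
#' @export
preprocess_reads <- function(reads, adapter, rfam_set = NULL,
                             repbase_set = NULL, min_len = 15L,
                             max_len = 30L, min_overlap = 6L,
                             max_mismatch_rate = 0.1,
                             max_n_fraction = 0.1,
                             min_distinct_bases = 3L) {
  reads <- trim_3p_adapter(reads, adapter, min_overlap, max_mismatch_rate)
  reads <- filter_by_length(reads, min_len, max_len)
  reads <- remove_junk(reads, max_n_fraction, min_distinct_bases)
  if (!is.null(rfam_set) || !is.null(repbase_set))
    reads <- remove_contaminants(reads, rfam_set, repbase_set)
  list(reads = reads, report = build_accounting(reads))
}
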