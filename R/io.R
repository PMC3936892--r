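#' Read a small RNA library (FASTQ or collapsed FASTA)
#'
#' Reads are returned as a data frame of records with one row per input read
#' (FASTQ) or per collapsed sequence (FASTA).  The collapsed-FASTA dialect
#' stores the read multiplicity after the last underscore of the header
#' (`id_count`); headers without a numeric suffix get count 1.  Qualities in
#' FASTQ input are ignored.
#'
#' @param path path to a `.fastq`/`.fq` or `.fasta`/`.fa` file.
#' @param format `"auto"` (by extension), `"fastq"` or `"fasta"`.
#' @return a data frame with columns `read_id`, `sequence`, `count`,
#'   `kept` (all `TRUE` on input) and `removal_reason` (`"none"`).
#' @export
read_small_rna <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(x)
  counts <- rep(1L, length(x))
  if (format == "fasta") {
    m <- regmatches(ids, regexpr("_[0-9]+$", ids))
    has <- lengths(regmatches(ids, gregexpr("_[0-9]+$", ids))) > 0
    counts[has] <- as.integer(sub("^_", "", m))
  }
  srna_reads(read_id = ids, sequence = toupper(as.character(x)),
             count = counts)
}

#' Construct a small RNA read table
#'
#' @param read_id,sequence,count parallel vectors describing the reads.
#' @param kept,removal_reason filter state; defaults describe unfiltered
#'   input.
#' @return a `data.frame` of read records.
#' @export
srna_reads <- function(read_id, sequence, count = 1L, kept = TRUE,
                       removal_reason = "none") {
  stopifnot(length(read_id) == length(sequence))
  n <- length(read_id)
  df <- data.frame(read_id = as.character(read_id),
                   sequence = toupper(as.character(sequence)),
                   count = rep_len(as.integer(count), n),
                   kept = rep_len(kept, n),
                   removal_reason = rep_len(removal_reason, n),
                   stringsAsFactors = FALSE)
  if (any(df$count < 1L)) stop("read counts must be >= 1")
  df
}

#' Collapse reads to unique sequences
#'
#' Sums counts over identical sequences among kept reads; removed reads are
#' passed through untouched.  Filter state must be homogeneous per sequence
#' (it is, after any pipeline stage).
#'
#' @param reads a read data frame.
#' @return a read data frame with one row per unique (sequence, state).
#' @export
collapse_reads <- function(reads) {
  key <- paste(reads$sequence, reads$kept, reads$removal_reason, sep = "\r")
  agg <- rowsum(reads$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$count <- as.integer(agg[match(key[first], rownames(agg)), 1])
  out$read_id <- paste0("seq", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Write kept reads as collapsed FASTA
#'
#' Headers follow the `id_count` dialect so the multiplicity survives a
#' round trip through [read_small_rna()].
#'
#' @param reads a read data frame; only kept reads are written.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  k <- collapse_reads(reads[reads$kept, , drop = FALSE])
  x <- Biostrings::DNAStringSet(k$sequence)
  names(x) <- sprintf("seq%06d_%d", seq_len(nrow(k)), k$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a mature miRNA FASTA (miRBase dialect)
#'
#' Sequences are normalized U to T and uppercased.  miRBase mature headers
#' start with a species prefix (`ath-miR156a-5p ...`); `species` keeps only
#' entries whose name starts with that prefix.
#'
#' @param path FASTA path.
#' @param species optional species prefix such as `"bra"`.
#' @return named character vector of DNA sequences.
#' @export
read_mature_fasta <- function(path, species = NULL) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  seqs <- toupper(chartr("Uu", "Tt", as.character(x)))
  names(seqs) <- nm
  if (!is.null(species))
    seqs <- seqs[startsWith(nm, paste0(species, "-"))]
  seqs
}

#' Read or write Vienna dot-bracket files
#'
#' The Vienna plain-text format: a `>name` header, the sequence, then the
#' dot-bracket structure followed by the energy, either as `(-12.30)` or as
#' an mfold-style `(dG = -12.30)` comment.
#'
#' @param path file path.
#' @return for `read_vienna`, a list of records, each a list with `name`,
#'   `sequence`, `structure`, `mfe`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' records in ", path)
  lapply(starts, function(i) {
    name <- sub("^>\\s*", "", lines[i])
    seqline <- lines[i + 1]
    strline <- lines[i + 2]
    mfe <- NA_real_
    m <- regmatches(strline, regexpr("\\(\\s*dG\\s*=\\s*(-?[0-9.]+)\\s*\\)",
                                     strline))
    if (!length(m))
      m <- regmatches(strline, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)$", strline))
    if (length(m))
      mfe <- as.numeric(regmatches(m, regexpr("-?[0-9]+\\.?[0-9]*", m)))
    structure <- sub("\\s*\\(\\s*(dG\\s*=)?\\s*-?[0-9.]+\\s*\\)\\s*$", "",
                     strline)
    if (nchar(structure) != nchar(seqline))
      stop("structure/sequence length mismatch for record ", name)
    list(name = name, sequence = toupper(seqline), structure = structure,
         mfe = mfe)
  })
}

#' @rdname read_vienna
#' @param records a list of records as returned by `read_vienna`, or a
#'   single record.
#' @export
write_vienna <- function(records, path) {
  if (!is.null(records$sequence)) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(c(paste0(">", r$name), r$sequence,
                 sprintf("%s (dG = %.2f)", r$structure, r$mfe)), con)
  }
  invisible(path)
}

#' Read a transcript-to-Arabidopsis homology map
#'
#' Tab-separated with columns `transcript_id`, `at_gene_id`,
#' `known_target_of` (miRNA family for which the Arabidopsis homolog is a
#' known target, empty otherwise).
#'
#' @param path TSV path.
#' @return a data frame.
#' @export
read_homology_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "at_gene_id", "known_target_of")
  if (!all(need %in% names(df)))
    stop("homology map needs columns: ", paste(need, collapse = ", "))
  df
}

# internal TSV writer with fixed conventions
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# write reads as FASTQ with uniform dummy qualities
write_fastq <- function(ids, sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  qual <- Biostrings::BStringSet(vapply(nchar(sequences), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
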