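#' Hamming distance between two equal-length DNA strings
#'
#' Conserved-miRNA matching tolerates substitutions only, so unequal
#' lengths are an error rather than an indel alignment.
#'
#' @param a,b DNA strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Match reads exactly against a known mature miRNA set
#'
#' Full-length identity only; near-matches are left for the conserved scan.
#' When duplicate sequences carry different names, all names are reported.
#'
#' @param reads a read data frame (kept reads are used).
#' @param known_set named character vector of mature sequences (U already
#'   normalized to T; see [read_mature_fasta()]).
#' @return data frame with `sequence`, `known_name`, one row per match.
#' @export
match_known <- function(reads, known_set) {
  if (!length(known_set))
    return(data.frame(sequence = character(), known_name = character(),
                      stringsAsFactors = FALSE))
  seqs <- unique(reads$sequence[reads$kept])
  hit <- known_set %in% seqs
  data.frame(sequence = unname(known_set[hit]),
             known_name = names(known_set)[hit],
             stringsAsFactors = FALSE)
}

#' Map reads to a genome by exact full-length matching
#'
#' All exact hits on both strands are reported with 0-based half-open
#' coordinates.  Reads with no hit are excluded from candidacy (returned in
#' the `unmapped` attribute); reads with more than `max_hits` hits are
#' dropped as repetitive.  Reads containing `N` cannot match exactly and
#' are treated as unmapped.
#'
#' @param reads a read data frame or character vector of sequences.
#' @param genome a `DNAStringSet` (or FASTA path).
#' @param max_hits repetitive-read threshold.
#' @return data frame with `sequence`, `chrom`, `start`, `end`, `strand`;
#'   attributes `unmapped` and `repetitive` list excluded sequences.
#' @export
map_to_genome <- function(reads, genome, max_hits = 20L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  seqs <- if (is.data.frame(reads))
    unique(reads$sequence[reads$kept]) else unique(reads)
  clean <- seqs[!grepl("N", seqs, fixed = TRUE) & nzchar(seqs)]
  hits <- vector("list", 2L * length(genome))
  hi <- 0L
  for (w in sort(unique(nchar(clean)))) {
    sub <- clean[nchar(clean) == w]
    fwd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    rev <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sub)))
    for (ci in seq_along(genome)) {
      chrom <- names(genome)[ci]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") fwd else rev
        m <- Biostrings::matchPDict(pd, genome[[ci]])
        starts <- Biostrings::startIndex(m)
        n_per <- lengths(starts)
        if (!sum(n_per)) next
        hi <- hi + 1L
        hits[[hi]] <- data.frame(
          sequence = rep(sub, n_per),
          chrom = chrom,
          start = unlist(starts) - 1L,
          end = unlist(starts) - 1L + w,
          strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (hi) do.call(rbind, hits[seq_len(hi)]) else
    data.frame(sequence = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  n_hits <- table(out$sequence)
  repetitive <- names(n_hits)[n_hits > max_hits]
  out <- out[!(out$sequence %in% repetitive), , drop = FALSE]
  out <- out[order(out$sequence, out$chrom, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- setdiff(seqs, unique(out$sequence))
  attr(out, "repetitive") <- repetitive
  out
}

#' Extract the miRNA family from a miRBase-style name
#'
#' `ath-miR156a-5p` and `bra-miR168a-1-p5` both yield `miR156` / `miR168`.
#'
#' @param name character vector of mature names.
#' @return character vector of family names.
#' @export
mir_family <- function(name) {
  x <- sub("^P-", "", name)
  x <- sub("^[a-z]{3,4}-", "", x)
  x <- sub("-(p[35]|[35]p)$", "", x)
  x <- sub("-[0-9]+$", "", x)              # sub-member index
  sub("^((miR|MIR)[0-9]+).*$", "\\1", x)
}

#' Classify genome-anchored reads as conserved or novel candidates
#'
#' A read is a conserved candidate when some known plant mature sequence of
#' equal length lies within `max_mm` Hamming mismatches; the best-scoring
#' known name is recorded and its family inherited.  Equal-score ties are
#' broken by the lexicographically smallest family name and logged.  Reads
#' matching nothing become novel candidates.
#'
#' @param sequences character vector of genome-anchored read sequences.
#' @param plant_mirs named character vector of known plant mature
#'   sequences (all species).
#' @param max_mm maximum Hamming mismatches.
#' @return data frame with `sequence`, `class` (`conserved`/`novel`),
#'   `best_name`, `family`, `mismatches`.
#' @export
find_conserved_candidates <- function(sequences, plant_mirs, max_mm = 3L) {
  sequences <- unique(sequences)
  out <- data.frame(sequence = sequences, class = "novel",
                    best_name = NA_character_, family = NA_character_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  if (!length(plant_mirs)) return(out)
  ref_len <- nchar(plant_mirs)
  seq_ints <- lapply(sequences, utf8ToInt)
  for (i in seq_along(sequences)) {
    cand <- which(ref_len == nchar(sequences[i]))
    if (!length(cand)) next
    d <- vapply(cand, function(j)
      sum(seq_ints[[i]] != utf8ToInt(plant_mirs[j])), 0L)
    best <- min(d)
    if (best > max_mm) next
    names_best <- names(plant_mirs)[cand[d == best]]
    fams <- mir_family(names_best)
    ord <- order(fams, names_best)
    if (length(unique(fams)) > 1)
      message("conserved-family tie for ", sequences[i], ": ",
              paste(sort(unique(fams)), collapse = ", "),
              "; keeping ", fams[ord[1]])
    out$class[i] <- "conserved"
    out$best_name[i] <- names_best[ord[1]]
    out$family[i] <- fams[ord[1]]
    out$mismatches[i] <- best
  }
  out
}

#' Assign mature miRNA names, arms and sub-member indices
#'
#' Candidates must each be tied to a validated precursor.  The arm suffix
#' comes from the stem side of the mature span; identical mature sequences
#' from distinct loci receive `-1`, `-2`, ... sub-member indices in genome
#' coordinate order; a mature whose partner arm was never sequenced keeps a
#' `P-` ("predicted") prefix on the partner's reported name.
#'
#' @param candidates data frame with one row per validated (mature, locus)
#'   pair: columns `sequence`, `chrom`, `start`, `end`, `strand`, `arm`
#'   (`"5p"`/`"3p"`), `family` (NA for novel), `star_sequence`,
#'   `star_observed` (logical), `hairpin_id` (one id per precursor locus).
#' @param prefix species prefix for names, e.g. `"bra"`.
#' @param arm_style `"5p"` for `-5p/-3p` suffixes, `"p5"` for `-p5/-p3`.
#' @return data frame of named matures, one row per reported arm.
#' @export
assign_names <- function(candidates, prefix = "bra",
                         arm_style = c("5p", "p5")) {
  arm_style <- match.arg(arm_style)
  if (!nrow(candidates)) return(candidates)
  if (any(is.na(candidates$hairpin_id)))
    stop("candidate without a validated precursor")
  # deterministic order: by genome coordinates
  candidates <- candidates[order(candidates$chrom, candidates$start,
                                 candidates$end, candidates$arm), ,
                           drop = FALSE]
  is_novel <- is.na(candidates$family)
  # novel families numbered by first-locus order over distinct mature seqs
  novel_key <- candidates$sequence[is_novel]
  fam_index <- integer(0)
  if (length(novel_key)) {
    first_seen <- !duplicated(novel_key)
    fam_ids <- cumsum(first_seen)
    fam_index <- setNames(fam_ids[first_seen], novel_key[first_seen])
    candidates$family[is_novel] <-
      paste0("miRn", fam_index[novel_key])
  }
  # sub-member indices: same family+sequence at distinct loci
  key <- paste(candidates$family, candidates$sequence)
  idx_within <- stats::ave(seq_along(key), key, FUN = seq_along)
  n_loci <- stats::ave(seq_along(key), key, FUN = length)
  sub_idx <- ifelse(n_loci > 1, paste0("-", idx_within), "")
  base <- paste0(prefix, "-", candidates$family, sub_idx)
  name <- paste0(base, arm_suffix(candidates$arm, arm_style))
  predicted <- !candidates$star_observed
  out <- data.frame(
    name = name,
    sequence = candidates$sequence,
    mature_length = nchar(candidates$sequence),
    arm = candidates$arm,
    family = candidates$family,
    submember_index = ifelse(n_loci > 1, idx_within, NA_integer_),
    predicted_only_flag = FALSE,
    chrom = candidates$chrom, start = candidates$start,
    end = candidates$end, strand = candidates$strand,
    hairpin_id = candidates$hairpin_id,
    stringsAsFactors = FALSE)
  # partner arm rows for unsequenced stars, marked predicted ("P-")
  star_rows <- which(predicted & !is.na(candidates$star_sequence))
  if (length(star_rows)) {
    cc <- candidates[star_rows, , drop = FALSE]
    other <- ifelse(cc$arm == "5p", "3p", "5p")
    extra <- data.frame(
      name = paste0("P-", base[star_rows], arm_suffix(other, arm_style)),
      sequence = cc$star_sequence,
      mature_length = nchar(cc$star_sequence),
      arm = other, family = cc$family,
      submember_index = out$submember_index[star_rows],
      predicted_only_flag = TRUE,
      chrom = cc$chrom, start = cc$start, end = cc$end,
      strand = cc$strand, hairpin_id = cc$hairpin_id,
      stringsAsFactors = FALSE)
    out <- rbind(out, extra)
  }
  rownames(out) <- NULL
  out
}

# arm suffix helper: "-5p"/"-3p" or the older "-p5"/"-p3" dialect
arm_suffix <- function(arm, style = c("5p", "p5")) {
  style <- match.arg(style)
  if (style == "5p") paste0("-", arm)
  else paste0("-p", substr(arm, 1, 1))
}
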