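#' Simulation configuration for the synthetic small RNA study
#'
#' Defaults describe the emulated study conditions: two libraries of
#' 2e5 reads, ten genuine hairpins plus one decoy per violable screening
#' criterion, miRNA* at roughly a tenth of the mature abundance, a
#' four-fold planted change for differentially expressed miRNAs and a
#' 1.5-fold "near" class that must never be called, contaminant and
#' low-complexity read admixtures, and degradome libraries with 80% of a
#' target's reads at the true cleavage site.
#'
#' @param seed RNG seed; the same seed reproduces every output byte.
#' @param n_true_hairpins number of genuine planted hairpins.
#' @param n_decoys_per_criterion decoys per violated-criterion type.
#' @param library_depth nominal reads per small RNA library.
#' @param mature_weight_range log-uniform range of relative mature
#'   abundances.
#' @param adapter 3' adapter ligated to every insert.
#' @param read_length sequencer read length; inserts plus adapter are
#'   truncated to it.
#' @param contaminant_fraction,junk_fraction,short_fraction,long_fraction,no_adapter_fraction,genomic_fraction
#'   read-budget fractions for the non-miRNA categories.
#' @param star_fraction miRNA* abundance relative to its mature.
#' @param de_ratio planted fold change for differentially expressed
#'   miRNAs.
#' @param near_ratio planted fold change for the not-DE "near" class.
#' @param mature_len_range mature length range, nt.
#' @param loop_len terminal loop length, nt.
#' @param ext_stem_len extra stem below the duplex, bp.
#' @param n_targets,n_decoy_targets degradome target/decoy transcript
#'   counts.
#' @param degradome_depth total degradome reads over all transcripts.
#' @param peak_fraction fraction of a target's degradome reads at the
#'   true cleavage site; must exceed 0.5 so planted sites are maxima
#'   (1 means zero background).
#' @param transcript_length target transcript length, nt.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_true_hairpins = 10L,
                       n_decoys_per_criterion = 1L,
                       library_depth = 2e5,
                       mature_weight_range = c(1, 4),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 48L,
                       contaminant_fraction = 0.08,
                       junk_fraction = 0.015,
                       short_fraction = 0.02,
                       long_fraction = 0.005,
                       no_adapter_fraction = 0.02,
                       genomic_fraction = 0.04,
                       star_fraction = 0.1,
                       de_ratio = 4,
                       near_ratio = 1.5,
                       mature_len_range = c(21L, 24L),
                       loop_len = 8L,
                       ext_stem_len = 15L,
                       n_targets = 8L,
                       n_decoy_targets = 4L,
                       degradome_depth = 4000L,
                       peak_fraction = 0.8,
                       transcript_length = 1200L) {
  cfg <- as.list(environment())
  if (peak_fraction <= 0.5 || peak_fraction > 1)
    stop("peak_fraction must lie in (0.5, 1]")
  stopifnot(library_depth > 0, n_true_hairpins > 0)
  class(cfg) <- "sim_config"
  cfg
}

# decoy types, one per violable screening criterion; "opposite arms"
# cannot be violated without also destroying the duplex, so it has no
# dedicated decoy
decoy_types <- function() {
  c("star_missing", "mismatch_total", "mismatch_run",
    "bulge_count", "bulge_size", "overhang_blunt", "mfei")
}

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")
# for each mature base, star bases that can neither Watson-Crick nor
# G:U pair with it
NONPAIRING <- list(A = c("A", "C", "G"), C = c("A", "C", "T"),
                   G = c("A", "G"), T = c("C", "T"))

rand_dna <- function(n, bases = BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# mature with edge constraints keeping the loop (all-C) and overhang
# geometry unambiguous under the maximum-pairing folder
gen_mature <- function(m, arm, mode = c("uniform", "low_gc", "purine")) {
  mode <- match.arg(mode)
  repeat {
    x <- switch(mode,
      low_gc = {
        y <- sample(c("A", "T"), m, replace = TRUE)
        y[sample(3:(m - 4), 2)] <- sample(c("G", "C"), 2, replace = TRUE)
        y
      },
      # purine-only matures cannot pair with themselves, and their
      # pyrimidine stars cannot either; G-dominance makes the intended
      # G:C register strictly heavier than any G:U-shifted alternative
      # -- used for planted-mismatch decoys
      purine = sample(c("A", "G"), m, replace = TRUE,
                      prob = c(0.2, 0.8)),
      sample(BASES, m, replace = TRUE))
    if (arm == "5p") {
      x[m - 2] <- if (mode == "purine") "A" else sample(c("A", "T"), 1)
      x[(m - 1):m] <- sample(c("A", "C"), 2, replace = TRUE)
    } else {
      x[1] <- if (mode == "purine") "A" else sample(c("A", "T"), 1)
    }
    s <- paste(x, collapse = "")
    gc <- nchar(gsub("[^GC]", "", s)) / m
    ok_gc <- switch(mode, low_gc = TRUE, purine = TRUE,
                    gc >= 0.3 && gc <= 0.65)
    min_distinct <- if (mode == "purine") 2L else 3L
    if (length(unique(x)) >= min_distinct && ok_gc) return(x)
  }
}

#' Construct a synthetic pre-miRNA hairpin
#'
#' Builds a precursor whose fallback-folded structure satisfies all five
#' screening criteria (`type = "true"`, `"star_missing"` or `"mfei"`
#' structure-wise) or violates exactly the specified one (remaining decoy
#' types): mismatches are planted as pinned A-opposite-A sites, bulges as
#' star-side insertions, the blunt decoy drops both 2-nt 3' overhangs,
#' and the MFEI decoy drops the extension stem (its genomic context is
#' made GC-rich but unpairable, so the window energy cannot clear the
#' MFEI threshold).  Callers are expected to validate the folded block and
#' retry, as base changes can occasionally open alternative structures.
#'
#' @param mature_len mature length (21-24 nt).
#' @param loop_len terminal loop length.
#' @param type `"true"` or one of [decoy_types()].
#' @param arm which arm carries the mature, `"5p"` or `"3p"`.
#' @param ext_stem_len extra stem below the duplex (0 for the MFEI
#'   decoy).
#' @return list with `precursor`, `mir_span`, `star_span` (0-based
#'   half-open precursor coordinates), `mature`, `star`, `arm`, `type`.
#' @export
make_hairpin <- function(mature_len = 21L, loop_len = 8L, type = "true",
                         arm = c("5p", "3p"), ext_stem_len = 15L) {
  arm <- match.arg(arm)
  stopifnot(type %in% c("true", decoy_types()))
  m <- mature_len
  if (type == "mfei") ext_stem_len <- 0L
  mat <- gen_mature(m, arm, mode = "uniform")
  if (type %in% c("mismatch_total", "mismatch_run")) {
    # planted mismatches are A opposite A (no Watson-Crick or wobble
    # partner), each pinned between forced G:C anchor pairs deep in the
    # duplex so the maximum-pairing folder cannot slide the register to
    # rescue them
    K <- if (type == "mismatch_total") c(5L, 9L, 13L, 17L) else 9:12
    mat[K] <- "A"
    anchor <- setdiff(unique(c(K - 1L, K + 1L)), K)
    mat[anchor] <- sample(c("G", "C"), length(anchor), replace = TRUE)
  }
  core <- rev(unname(COMP[mat[1:(m - 2)]]))
  if (type %in% c("mismatch_total", "mismatch_run")) {
    core[m - 1L - K] <- "A"
  } else if (type == "bulge_count") {
    j1 <- floor((m - 2) / 3); j2 <- floor(2 * (m - 2) / 3)
    core <- append(append(core, sample(BASES, 1), after = j2),
                   sample(BASES, 1), after = j1)
  } else if (type == "bulge_size") {
    core <- append(core, sample(BASES, 3, replace = TRUE),
                   after = floor((m - 2) / 2))
  }
  if (type == "overhang_blunt") {
    star <- rev(unname(COMP[mat]))          # full-length, no overhangs
  } else {
    over <- sample(c("A", "C"), 2, replace = TRUE)
    star <- c(core, over)
  }
  loop <- rep("C", loop_len)
  ext5 <- if (ext_stem_len > 0) sample(BASES, ext_stem_len, TRUE)
  else character(0)
  ext3 <- if (ext_stem_len > 0)
    rev(unname(COMP[ext5])) else character(0)
  if (arm == "5p") {
    parts <- list(ext5, mat, loop, star, ext3)
    mir_off <- length(ext5)
    star_off <- length(ext5) + m + loop_len
  } else {
    parts <- list(ext5, star, loop, mat, ext3)
    star_off <- length(ext5)
    mir_off <- length(ext5) + length(star) + loop_len
  }
  precursor <- paste(unlist(parts), collapse = "")
  list(precursor = precursor,
       mir_span = c(mir_off, mir_off + m),
       star_span = c(star_off, star_off + length(star)),
       mature = paste(mat, collapse = ""),
       star = paste(star, collapse = ""),
       arm = arm, type = type)
}

# expected failed criteria (five-criterion level) per hairpin type
expected_failed <- function(type) {
  switch(type,
         true = character(0),
         star_missing = "star",
         mismatch_total = "mismatches",
         mismatch_run = "mismatches",
         bulge_count = "bulges",
         bulge_size = "bulges",
         overhang_blunt = "duplex_geometry",
         mfei = "mfei")
}

# screen a padded hairpin block exactly the way the pipeline will and
# check the verdict matches the construction intent
validate_block <- function(block, mat_span, star_span, type) {
  g <- Biostrings::DNAStringSet(block)
  names(g) <- "blk"
  locus <- list(chrom = "blk", start = mat_span[1], end = mat_span[2],
                strand = "+")
  sf <- function(w) list(c(star_span[1] - w$start, star_span[2] - w$start))
  scr <- screen_hairpin(g, locus,
                        star_finder = if (type == "star_missing") NULL
                        else sf)
  if (is.null(scr)) return(FALSE)
  if (!setequal(scr$verdict$failed, expected_failed(type))) return(FALSE)
  if (type == "star_missing") {
    # the structure itself must be sound: with the star supplied it passes
    scr2 <- screen_hairpin(g, locus, star_finder = sf)
    if (is.null(scr2) || !scr2$pass) return(FALSE)
  }
  TRUE
}

# generate a validated hairpin block.  The MFEI decoy gets all-C pads:
# C cannot pair C, so the pads add no folding energy while driving the
# window GC% up -- the standard duplex then cannot reach MFEI > 0.8.
gen_hairpin_block <- function(type, arm, cfg, pad = 160L,
                              max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    m <- sample(cfg$mature_len_range[1]:cfg$mature_len_range[2], 1)
    hp <- make_hairpin(m, cfg$loop_len, type, arm, cfg$ext_stem_len)
    pads <- if (type == "mfei") "C" else BASES
    left <- rand_dna(pad, pads)
    right <- rand_dna(pad, pads)
    block <- paste0(left, hp$precursor, right)
    mat_span <- hp$mir_span + pad
    star_span <- hp$star_span + pad
    if (validate_block(block, mat_span, star_span, type)) {
      return(list(block = block, mat_span = mat_span,
                  star_span = star_span, hairpin = hp))
    }
  }
  stop("hairpin construction failed after ", max_tries, " tries: type=",
       type, " arm=", arm)
}

# log-uniform weights
loguni <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Build the synthetic genome and the two small RNA libraries
#'
#' Plants validated true hairpins and single-criterion decoys into a
#' genome, assigns per-library abundances (differential-expression
#' classes cycle through up-in-B, up-in-A, unchanged and a 1.5-fold
#' "near" class), admixes contaminant, junk, length-violating,
#' adapterless and unannotated genomic reads, appends the 3' adapter,
#' draws Poisson read counts and returns everything with machine-readable
#' ground truth.  Each read species is passed through the real
#' preprocessing chain at generation time so the planted removal ledger
#' matches the pipeline's exactly.
#'
#' @param config a [sim_config()].
#' @return a list (class `srna_sim`) with `genome`, `reads_A`, `reads_B`
#'   (read data frames), `rfam`, `repbase`, `known_set`, `plant_mirs`,
#'   `adapter`, `config` and `truth` (lists of data frames: `hairpins`,
#'   `abundance`, `filter_counts`, `species`).
#' @export
build_genome_and_libraries <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)

  # contaminant reference sets, synthetic stand-ins for Rfam/Repbase
  rfam <- setNames(vapply(1:5, function(i)
    rand_dna(sample(300:800, 1)), ""), paste0("synthetic_rRNA_", 1:5))
  repbase <- setNames(vapply(1:3, function(i)
    rand_dna(sample(200:500, 1)), ""), paste0("synthetic_repeat_", 1:3))

  # hairpins: true ones first, then one decoy set per criterion
  types <- c(rep("true", cfg$n_true_hairpins),
             rep(decoy_types(), cfg$n_decoys_per_criterion))
  n_hp <- length(types)
  arms <- rep(c("5p", "3p"), length.out = n_hp)
  strands <- ifelse(types == "true" &
                      seq_len(n_hp) %% 3 == 0, "-", "+")
  blocks <- vector("list", n_hp)
  for (i in seq_len(n_hp)) {
    repeat {
      b <- gen_hairpin_block(types[i], arms[i], cfg)
      seqs_so_far <- unlist(lapply(blocks[seq_len(i - 1)], function(x)
        c(x$hairpin$mature, x$hairpin$star)))
      if (!(b$hairpin$mature %in% seqs_so_far) &&
          !(b$hairpin$star %in% seqs_so_far) &&
          b$hairpin$mature != b$hairpin$star) {
        blocks[[i]] <- b
        break
      }
    }
  }

  # assemble genome: lead, blocks with spacers, then a noise region that
  # unannotated genomic reads are drawn from (never overlapping hairpins)
  segments <- character(0)
  offsets <- integer(n_hp)
  pos <- 0L
  lead <- rand_dna(200)
  segments <- c(segments, lead); pos <- pos + nchar(lead)
  for (i in seq_len(n_hp)) {
    blk <- blocks[[i]]$block
    if (strands[i] == "-") blk <- revcomp_chr(blk)
    offsets[i] <- pos
    segments <- c(segments, blk, rand_dna(60))
    pos <- pos + nchar(blk) + 60L
  }
  noise_start <- pos
  noise_region <- rand_dna(3000)
  segments <- c(segments, noise_region, rand_dna(100))
  genome_seq <- paste(segments, collapse = "")
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chr1"

  # genome coordinates of mature/star spans (strand-aware)
  hp_truth <- do.call(rbind, lapply(seq_len(n_hp), function(i) {
    b <- blocks[[i]]
    L <- nchar(b$block)
    to_genome <- function(span) {
      if (strands[i] == "+") offsets[i] + span
      else c(offsets[i] + L - span[2], offsets[i] + L - span[1])
    }
    ms <- to_genome(b$mat_span)
    ss <- to_genome(b$star_span)
    data.frame(hairpin_id = sprintf("hp%02d", i),
               type = types[i], arm = b$hairpin$arm,
               strand = strands[i], chrom = "chr1",
               mat_start = ms[1], mat_end = ms[2],
               star_start = ss[1], star_end = ss[2],
               mature = b$hairpin$mature, star = b$hairpin$star,
               expected_pass = types[i] == "true",
               violated = ifelse(types[i] == "true", "",
                                 expected_failed(types[i])),
               stringsAsFactors = FALSE)
  }))

  # known mature set (unrelated) and plant references; the first two true
  # hairpins get a 2-mismatch plant relative so they classify conserved
  known_set <- setNames(vapply(1:5, function(i) rand_dna(21), ""),
                        sprintf("bra-miR9%02da", 1:5))
  mk_variant <- function(s, nmm = 2) {
    x <- strsplit(s, "")[[1]]
    pos <- sample(3:(length(x) - 3), nmm)
    for (p in pos) x[p] <- sample(setdiff(BASES, x[p]), 1)
    paste(x, collapse = "")
  }
  plant_mirs <- c(
    setNames(mk_variant(hp_truth$mature[1]), "ath-miR8501-5p"),
    setNames(mk_variant(hp_truth$mature[2]), "osa-miR8502-3p"),
    setNames(vapply(1:4, function(i) rand_dna(21), ""),
             sprintf("zma-miR86%02d", 1:4)))
  hp_truth$class <- ifelse(seq_len(n_hp) <= 2 & types == "true",
                           "conserved", "novel")

  # ---- read species -------------------------------------------------
  depth <- cfg$library_depth
  mirna_frac <- 1 - cfg$contaminant_fraction - cfg$junk_fraction -
    cfg$short_fraction - cfg$long_fraction - cfg$no_adapter_fraction -
    cfg$genomic_fraction
  classes <- rep(c("up_B", "up_A", "unchanged", "near"),
                 length.out = cfg$n_true_hairpins)
  classes <- c(classes, rep("unchanged", n_hp - cfg$n_true_hairpins))
  ratio <- c(up_B = cfg$de_ratio, up_A = 1 / cfg$de_ratio,
             unchanged = 1, near = cfg$near_ratio)[classes]
  w <- loguni(n_hp, cfg$mature_weight_range)
  scale <- depth * mirna_frac / (1 + cfg$star_fraction) / sum(w)
  e_mat_A <- scale * w / sqrt(ratio)
  e_mat_B <- scale * w * sqrt(ratio)

  species <- list()
  add_species <- function(id, category, insert, e_A, e_B,
                          hairpin_id = NA, arm = NA, read = NULL) {
    if (is.null(read)) {
      read <- substr(paste0(insert, cfg$adapter), 1, cfg$read_length)
    }
    species[[length(species) + 1L]] <<- data.frame(
      species_id = id, category = category, insert = insert,
      read_string = read, e_A = e_A, e_B = e_B,
      hairpin_id = hairpin_id, arm = arm, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_hp)) {
    add_species(sprintf("mat_hp%02d", i), "mature", hp_truth$mature[i],
                e_mat_A[i], e_mat_B[i], hp_truth$hairpin_id[i],
                hp_truth$arm[i])
    if (types[i] != "star_missing") {
      star_arm <- ifelse(hp_truth$arm[i] == "5p", "3p", "5p")
      add_species(sprintf("star_hp%02d", i), "star", hp_truth$star[i],
                  cfg$star_fraction * e_mat_A[i],
                  cfg$star_fraction * e_mat_B[i],
                  hp_truth$hairpin_id[i], star_arm)
    }
  }
  budget_species <- function(frac, n, category, gen_insert,
                             read_fun = NULL) {
    wts <- loguni(n, c(1, 4))
    e <- depth * frac * wts / sum(wts)
    for (i in seq_len(n)) {
      ins <- gen_insert(i)
      add_species(sprintf("%s_%03d", category, i), category, ins,
                  e[i], e[i],
                  read = if (is.null(read_fun)) NULL else read_fun(ins))
    }
  }
  contaminant_window <- function(set) {
    s <- set[[sample(length(set), 1)]]
    len <- sample(18:28, 1)
    a <- sample(nchar(s) - len, 1)
    substr(s, a, a + len - 1)
  }
  budget_species(cfg$contaminant_fraction * 2 / 3, 60, "rfam",
                 function(i) contaminant_window(rfam))
  budget_species(cfg$contaminant_fraction * 1 / 3, 30, "repbase",
                 function(i) contaminant_window(repbase))
  budget_species(cfg$junk_fraction, 30, "junk", function(i) {
    if (i %% 3 == 0) {
      n <- sample(15:30, 1)   # N-rich
      x <- strsplit(rand_dna(n), "")[[1]]
      x[sample(n, ceiling(n * 0.2))] <- "N"
      paste(x, collapse = "")
    } else {
      b <- sample(BASES, 2)
      paste(rep(b, length.out = sample(15:30, 1)), collapse = "")
    }
  })
  budget_species(cfg$short_fraction, 20, "short",
                 function(i) rand_dna(sample(8:14, 1)))
  budget_species(cfg$long_fraction, 10, "long",
                 function(i) rand_dna(sample(31:38, 1)))
  budget_species(cfg$no_adapter_fraction, 25, "noadt",
                 function(i) rand_dna(cfg$read_length),
                 read_fun = function(ins) ins)
  budget_species(cfg$genomic_fraction, 80, "genomic", function(i) {
    len <- sample(20:24, 1)
    a <- sample(3000 - len, 1)
    substr(noise_region, a, a + len - 1)
  })
  sp <- do.call(rbind, species)

  # validate every species against the real filter chain; redraw species
  # whose classification would not match the planted category
  expect_cat <- c(mature = "kept", star = "kept", genomic = "kept",
                  rfam = "rfam", repbase = "repbase", junk = "junk",
                  short = "too_short", long = "too_long",
                  noadt = "no_3adt")
  classify_one <- function(read) {
    r <- preprocess_reads(srna_reads("x", read), cfg$adapter,
                          rfam, repbase)$reads
    list(state = if (r$kept) "kept" else r$removal_reason,
         insert = r$sequence)
  }
  redraw <- function(category, i) {
    switch(category,
           rfam = contaminant_window(rfam),
           repbase = contaminant_window(repbase),
           genomic = {
             len <- sample(20:24, 1)
             a <- sample(3000 - len, 1)
             substr(noise_region, a, a + len - 1)
           },
           short = rand_dna(sample(8:14, 1)),
           long = rand_dna(sample(31:38, 1)),
           noadt = rand_dna(cfg$read_length),
           junk = paste(rep(sample(BASES, 2),
                            length.out = sample(15:30, 1)), collapse = ""),
           stop("cannot redraw category ", category))
  }
  suppressWarnings(for (i in seq_len(nrow(sp))) {
    tries <- 0
    repeat {
      cl <- classify_one(sp$read_string[i])
      dup <- sp$read_string[i] %in% sp$read_string[-i] ||
        (expect_cat[sp$category[i]] == "kept" &&
           sp$insert[i] %in% sp$insert[-i])
      ok <- !dup && cl$state == expect_cat[sp$category[i]] &&
        (cl$state != "kept" || cl$insert == sp$insert[i])
      if (ok) break
      tries <- tries + 1
      if (tries > 200)
        stop("species validation failed for ", sp$species_id[i])
      if (sp$category[i] %in% c("mature", "star"))
        stop("planted miRNA read fails its own filter chain: ",
             sp$species_id[i])
      sp$insert[i] <- redraw(sp$category[i], i)
      sp$read_string[i] <- if (sp$category[i] == "noadt") sp$insert[i]
      else substr(paste0(sp$insert[i], cfg$adapter), 1, cfg$read_length)
    }
  })

  # Poisson read counts per species per library
  sp$count_A <- rpois(nrow(sp), sp$e_A)
  sp$count_B <- rpois(nrow(sp), sp$e_B)

  expand <- function(counts, lib) {
    idx <- rep(seq_len(nrow(sp)), counts)
    srna_reads(
      read_id = sprintf("%s_%07d", lib, seq_along(idx)),
      sequence = sp$read_string[idx], count = 1L)
  }
  reads_A <- expand(sp$count_A, "A")
  reads_B <- expand(sp$count_B, "B")

  # planted removal ledger (exact, per library)
  ledger <- function(counts) {
    cat_of <- expect_cat[sp$category]
    sums <- tapply(counts, cat_of, sum)
    get <- function(k) if (k %in% names(sums)) unname(sums[k]) else 0
    data.frame(
      category = c("no_3adt", "too_short", "too_long", "junk",
                   "rfam", "repbase", "mappable", "raw"),
      reads = c(get("no_3adt"), get("too_short"), get("too_long"),
                get("junk"), get("rfam"), get("repbase"), get("kept"),
                sum(counts)))
  }
  filter_counts <- rbind(
    cbind(library = "A", ledger(sp$count_A)),
    cbind(library = "B", ledger(sp$count_B)))

  # abundance truth with planted fold on the expected-RPM scale
  mapp <- sp$category %in% c("mature", "star", "genomic")
  EM_A <- sum(sp$e_A[mapp]); EM_B <- sum(sp$e_B[mapp])
  mi <- which(sp$category %in% c("mature", "star"))
  pf <- (sp$e_B[mi] / EM_B) / (sp$e_A[mi] / EM_A)
  abundance <- data.frame(
    species_id = sp$species_id[mi], hairpin_id = sp$hairpin_id[mi],
    role = sp$category[mi], arm = sp$arm[mi], sequence = sp$insert[mi],
    name = paste0("syn-miR",
                  sub("^hp0?", "", sp$hairpin_id[mi]), "-", sp$arm[mi]),
    e_A = sp$e_A[mi], e_B = sp$e_B[mi],
    count_A = sp$count_A[mi], count_B = sp$count_B[mi],
    de_class = classes[match(sp$hairpin_id[mi], hp_truth$hairpin_id)],
    planted_fold = pmax(pf, 1 / pf),
    planted_direction = ifelse(abs(log(pf)) < 1e-9, "unchanged",
                               ifelse(pf > 1, "up_in_B", "up_in_A")),
    expect_de = pmax(pf, 1 / pf) > 2,
    stringsAsFactors = FALSE)

  out <- list(genome = genome, reads_A = reads_A, reads_B = reads_B,
              rfam = rfam, repbase = repbase, known_set = known_set,
              plant_mirs = plant_mirs, adapter = cfg$adapter,
              config = cfg,
              truth = list(hairpins = hp_truth, abundance = abundance,
                           filter_counts = filter_counts, species = sp))
  class(out) <- "srna_sim"
  out
}

#' Build synthetic degradome data for planted targets
#'
#' Target transcripts embed a perfect reverse-complement binding site of
#' a planted mature miRNA; degradome reads place `peak_fraction` of each
#' target's depth at the position opposite miRNA nucleotide 10 and the
#' remainder uniformly (none when `peak_fraction` is 1).  Decoy
#' transcripts carry a shuffled binding site, validated to align with no
#' planted mature under the retention cutoff, and only background reads.
#'
#' @param config a [sim_config()].
#' @param sim an `srna_sim` from [build_genome_and_libraries()] (used for
#'   the planted matures); pass the same config.
#' @return list with `transcripts` (`DNAStringSet`), `degradome_reads`
#'   (read data frame), `homology_map`, `targets` (truth data frame).
#' @export
build_degradome <- function(config, sim) {
  cfg <- config
  set.seed(cfg$seed + 777L)
  hp <- sim$truth$hairpins
  true_hp <- hp[hp$type == "true", , drop = FALSE]
  pick <- rep(seq_len(nrow(true_hp)), length.out = cfg$n_targets)
  L <- cfg$transcript_length
  per_target <- floor(cfg$degradome_depth / cfg$n_targets)
  txs <- character(0); tx_names <- character(0)
  targets <- list(); reads <- list(); hom <- list()
  all_matures <- hp$mature
  for (t in seq_len(cfg$n_targets)) {
    mat <- true_hp$mature[pick[t]]
    m <- nchar(mat)
    repeat {
      tx <- rand_dna(L)
      b1 <- sample(400:(L - 400), 1)
      substr(tx, b1, b1 + m - 1) <- revcomp_chr(mat)
      al <- align_mir_target(mat, tx)
      if (nrow(al) == 1 && al$binding_start == b1 && al$score == 0)
        break
    }
    id <- sprintf("TX%02d", t)
    b2 <- b1 + m - 1L
    site <- b2 - 9L
    n_peak <- round(cfg$peak_fraction * per_target)
    pos <- rep(site, n_peak)
    if (n_peak < per_target)
      pos <- c(pos, sample(L - 19, per_target - n_peak, replace = TRUE))
    reads[[length(reads) + 1L]] <- data.frame(
      transcript = id, pos = pos,
      seq = substr(rep(tx, length(pos)), pos, pos + 19L),
      stringsAsFactors = FALSE)
    fam <- paste0("miR", sub("^hp0?", "", true_hp$hairpin_id[pick[t]]))
    targets[[length(targets) + 1L]] <- data.frame(
      transcript_id = id, hairpin_id = true_hp$hairpin_id[pick[t]],
      mir_name = paste0("syn-", fam, "-", true_hp$arm[pick[t]]),
      family = fam, binding_start = b1, binding_end = b2,
      cleavage_site = site, is_decoy = FALSE, stringsAsFactors = FALSE)
    hom[[length(hom) + 1L]] <- data.frame(
      transcript_id = id, at_gene_id = sprintf("AT1G%05d", 10 * t),
      known_target_of = fam, stringsAsFactors = FALSE)
    txs <- c(txs, tx); tx_names <- c(tx_names, id)
  }
  # decoy transcripts: shuffled binding site, background reads only
  for (d in seq_len(cfg$n_decoy_targets)) {
    mat <- true_hp$mature[pick[(d - 1) %% cfg$n_targets + 1]]
    m <- nchar(mat)
    repeat {
      tx <- rand_dna(L)
      b1 <- sample(400:(L - 400), 1)
      shuf <- paste(sample(strsplit(revcomp_chr(mat), "")[[1]]),
                    collapse = "")
      substr(tx, b1, b1 + m - 1) <- shuf
      ok <- all(vapply(all_matures, function(s)
        nrow(align_mir_target(s, tx)) == 0, TRUE))
      if (ok) break
    }
    id <- sprintf("DX%02d", d)
    n_bg <- round((1 - cfg$peak_fraction) * per_target)
    if (n_bg > 0) {
      pos <- sample(L - 19, n_bg, replace = TRUE)
      reads[[length(reads) + 1L]] <- data.frame(
        transcript = id, pos = pos,
        seq = substr(rep(tx, length(pos)), pos, pos + 19L),
        stringsAsFactors = FALSE)
    }
    targets[[length(targets) + 1L]] <- data.frame(
      transcript_id = id, hairpin_id = NA, mir_name = NA, family = NA,
      binding_start = b1, binding_end = b1 + m - 1L,
      cleavage_site = NA, is_decoy = TRUE, stringsAsFactors = FALSE)
    hom[[length(hom) + 1L]] <- data.frame(
      transcript_id = id, at_gene_id = sprintf("AT9G%05d", 10 * d),
      known_target_of = "", stringsAsFactors = FALSE)
    txs <- c(txs, tx); tx_names <- c(tx_names, id)
  }
  transcripts <- Biostrings::DNAStringSet(txs)
  names(transcripts) <- tx_names
  rd <- do.call(rbind, reads)
  degradome_reads <- srna_reads(
    read_id = sprintf("D_%06d", seq_len(nrow(rd))), sequence = rd$seq)
  list(transcripts = transcripts, degradome_reads = degradome_reads,
       homology_map = do.call(rbind, hom),
       targets = do.call(rbind, targets))
}

#' Simulate the complete synthetic study
#'
#' Runs [build_genome_and_libraries()] and [build_degradome()] and
#' optionally writes every input file (FASTA/FASTQ/TSV) plus the truth
#' tables to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return an `srna_sim` list with a `degradome` element added.
#' @export
simulate_srna_study <- function(config = sim_config(), out_dir = NULL) {
  sim <- build_genome_and_libraries(config)
  sim$degradome <- build_degradome(config, sim)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
    write_fastq(sim$reads_A$read_id, sim$reads_A$sequence,
                p("reads_A.fastq"))
    write_fastq(sim$reads_B$read_id, sim$reads_B$sequence,
                p("reads_B.fastq"))
    write_set <- function(x, f) {
      s <- Biostrings::DNAStringSet(unname(x)); names(s) <- names(x)
      Biostrings::writeXStringSet(s, p(f))
    }
    write_set(sim$rfam, "rfam_synthetic.fa")
    write_set(sim$repbase, "repbase_synthetic.fa")
    write_set(sim$known_set, "known_mature.fa")
    write_set(sim$plant_mirs, "plant_mature.fa")
    Biostrings::writeXStringSet(sim$degradome$transcripts,
                                p("transcripts.fa"))
    write_fastq(sim$degradome$degradome_reads$read_id,
                sim$degradome$degradome_reads$sequence,
                p("degradome.fastq"))
    write_tsv(sim$degradome$homology_map, p("homology_map.tsv"))
    write_tsv(sim$truth$hairpins, p("truth_hairpins.tsv"))
    write_tsv(sim$truth$abundance, p("truth_abundance.tsv"))
    write_tsv(sim$truth$filter_counts, p("truth_filter_counts.tsv"))
    write_tsv(sim$degradome$targets, p("truth_targets.tsv"))
  }
  sim
}
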