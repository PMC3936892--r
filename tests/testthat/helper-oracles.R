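# Independent oracles used by property tests.  These deliberately share
# no code with the package implementation.

# exhaustive maximum-weight pseudoknot-free pairing for tiny sequences
oracle_fold_weight <- function(seq, min_loop = 3) {
  s <- chartr("T", "U", toupper(seq))
  x <- strsplit(s, "")[[1]]
  w <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) 2
    else if (p %in% c("AU", "UA", "GU", "UG")) 1
    else 0
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      wk <- w(x[i], x[k])
      if (wk == 0) next
      left <- if (k - i >= 2) rec(i + 1, k - 1) else 0
      right <- if (k < j) rec(k + 1, j) else 0
      best <- max(best, wk + left + right)
    }
    best
  }
  if (length(x) < 2) 0 else rec(1, length(x))
}

# brute-force partner table: for every "(" scan forward with a depth
# counter to find its mate (quadratic on purpose, no shared stack code)
oracle_partners <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- integer(length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] != "(") next
    depth <- 0
    for (j in (i + 1):length(ch)) {
      if (ch[j] == "(") depth <- depth + 1
      if (ch[j] == ")") {
        if (depth == 0) { partner[i] <- j; partner[j] <- i; break }
        depth <- depth - 1
      }
    }
  }
  partner
}

# re-derive the duplex statistics directly from the dot-bracket with
# plain loops; definitions mirror the documented contract
oracle_duplex <- function(structure, mir_span, star_span) {
  p <- oracle_partners(structure)
  mir <- (mir_span[1] + 1):mir_span[2]
  in_star <- function(q) q > star_span[1] & q <= star_span[2]
  in_mir <- function(q) q > mir_span[1] & q <= mir_span[2]
  mism <- vapply(mir, function(i) p[i] == 0 || !in_star(p[i]), TRUE)
  anchors <- mir[!mism]
  # trailing overhang (up to 2 unpaired 3' bases) is not a mismatch
  eff <- mism
  if (length(anchors)) {
    drop <- min(mir_span[2] - max(anchors), 2)
    if (drop > 0) eff <- eff[1:(length(eff) - drop)]
  }
  n_mm <- sum(eff)
  run <- 0; cur <- 0
  for (v in eff) { cur <- if (v) cur + 1 else 0; run <- max(run, cur) }
  sizes <- integer(0)
  if (length(anchors) > 1) {
    for (k in 1:(length(anchors) - 1)) {
      gm <- anchors[k + 1] - anchors[k] - 1
      gs <- abs(p[anchors[k]] - p[anchors[k + 1]]) - 1
      if (gm > 0 && gs == 0) sizes <- c(sizes, gm)
      if (gs > 0 && gm == 0) sizes <- c(sizes, gs)
    }
  }
  star <- (star_span[1] + 1):star_span[2]
  star_anch <- star[vapply(star, function(i)
    p[i] > 0 && in_mir(p[i]), TRUE)]
  ov <- length(anchors) > 0 && length(star_anch) > 0 &&
    mir_span[2] - max(anchors) == 2 &&
    star_span[2] - max(star_anch) == 2
  list(mismatch_count = n_mm, max_consecutive_mismatches = run,
       asymmetric_bulge_count = length(sizes),
       max_asymmetric_bulge_size = if (length(sizes)) max(sizes) else 0,
       overhang_3p_ok = ov)
}

# explicit max/median category rules
oracle_category <- function(profile, site) {
  x <- profile[site]
  if (x == 1) return(4L)
  nz <- sort(profile[profile > 0])
  mx <- nz[length(nz)]
  if (x == mx) {
    if (sum(profile == mx) == 1) return(0L) else return(1L)
  }
  n <- length(nz)
  med <- if (n %% 2 == 1) nz[(n + 1) / 2] else (nz[n / 2] + nz[n / 2 + 1]) / 2
  if (x > med) 2L else 3L
}

# quick random hairpin (precursor + pads) for duplex property tests
random_eval_case <- function() {
  type <- sample(c("true", "mismatch_total", "mismatch_run",
                   "bulge_count", "bulge_size", "overhang_blunt"), 1)
  hp <- make_hairpin(sample(21:24, 1), 8, type,
                     sample(c("5p", "3p"), 1), 15)
  pad <- 20
  block <- paste0(paste(sample(c("A", "C", "G", "T"), pad, TRUE),
                        collapse = ""),
                  hp$precursor,
                  paste(sample(c("A", "C", "G", "T"), pad, TRUE),
                        collapse = ""))
  f <- fold_hairpin(block)
  list(structure = f$structure, mir_span = hp$mir_span + pad,
       star_span = hp$star_span + pad)
}
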