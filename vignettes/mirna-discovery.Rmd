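---
title: "Methods: small RNA miRNA discovery, hairpin screening and degradome target calling"
author: "mirseeker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA miRNA discovery, hairpin screening and degradome target calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseeker)
```

# The problem

Plant miRNAs are 21-24 nt guides excised from fold-back precursors
(pre-miRNAs).  Discovering them from small RNA sequencing of two
conditions — here a male-sterile (A) and male-fertile (B) flower-bud
library of *Brassica campestris* — involves four stages, each of which
this package implements as plain functions with a pipeline driver
(`discover_mirnas()`) on top:

1. **Preprocessing** (`preprocess_reads()`): 3' adapter trimming,
   inclusive 15-30 nt length bounds, a low-complexity ("junk") screen,
   and removal of reads matching ncRNA (Rfam-style) or repeat
   (Repbase-style) references, with an exact removal ledger in which
   every read carries exactly one removal reason.
2. **Annotation** (`match_known()`, `map_to_genome()`,
   `find_conserved_candidates()`): reads identical to known matures of
   the target species are *known* miRNAs; reads that map exactly to the
   genome and lie within 3 Hamming mismatches of any known plant mature
   are *conserved* candidates; exact genome hits matching nothing are
   *novel* candidates.
3. **Hairpin screening** (`screen_hairpin()`): genomic windows around
   each candidate are folded and the miRNA/miRNA* duplex judged against
   five criteria (below).
4. **Quantification** (`normalize_rpm()`, `fold_change()`,
   `call_targets()`): reads-per-million abundances, a strict two-fold
   differential-expression rule, and degradome-based target calling.

# The five screening criteria

A candidate locus is reported as a miRNA only if

1. the partner strand (miRNA*) was itself sequenced;
2. the duplex has fewer than four mismatched bases, with no run of four
   consecutive mismatches;
3. at most one asymmetric bulge, at most 2 nt large;
4. the two matures sit on opposite stem arms and form a duplex with
   two-nucleotide 3' overhangs;
5. the precursor has MFEI strictly above 0.8, where
   AMFE = |MFE| / precursor length × 100 and MFEI = AMFE / GC%.

Notes on how the ambiguous parts were pinned down:

* The bulge-size bound is read as **≤ 2 nt** (the source phrasing is
  ungrammatical); it is a configurable argument of
  `classify_candidate()`.
* The mismatch bound applies to the **total** (< 4) *and* to the longest
  run (< 4).
* A *mismatch* is a mature position unpaired or paired outside the star
  span.  Up to two unpaired bases at the mature 3' end are the expected
  duplex overhang and are not counted — otherwise a perfect duplex would
  score two mismatches.
* An *asymmetric bulge* is a maximal unpaired run on one duplex strand
  with no opposing unpaired run; symmetric internal loops count as
  mismatches instead.
* *Opposite arms* is evaluated topologically: the spans must be disjoint
  and ordered, no base of either span may pair within its own span or
  into the region between the spans, and at least one mature base must
  anchor into the star span.  A span crossing the terminal loop
  necessarily violates one of these.
* MFEI = 0.8 exactly **fails** (strict inequality).

# Folding backend

Published precursor energies come from nearest-neighbour thermodynamic
folders.  Reimplementing one is out of scope; instead `fold_hairpin()`
provides two backends:

* `"vienna_file"` parses an externally produced dot-bracket file
  (including the `(dG = …)` energy comment), so real thermodynamic
  structures can be supplied;
* `"nussinov"` (default) is a screening-grade **weighted
  maximum-base-pairing dynamic program** (Watson-Crick plus G:U, minimum
  hairpin loop 3, pseudoknot-free) with an explicit energy proxy of
  −2.0 kcal/mol per GC pair and −1.0 per AU/GU pair, implemented in C++.
  Ties resolve deterministically (the unpaired branch first, then the
  smallest pairing partner), so results are reproducible.

The proxy is *not* an approximation of real folding energies: maximum
pairing overpairs random sequence, and its energies are on a different
scale.  The package therefore never claims MFE parity with
thermodynamic folders; MFEI screening under the fallback is exercised on
synthetic data whose construction is validated under the same fallback.
Published MFEI values are recomputed from the printed table quantities
(`compute_metrics()` accepts explicit length and GC%), not by refolding.

Several published novel-precursor rows are internally inconsistent with
the MFEI = AMFE/GC% identity (e.g. bra-miRn1-1 prints 1.2 where the
formula gives 1.7, while bra-miRn2, bra-miRn5, bra-miRn6, bra-miRn10-1
and bra-miRn12 match exactly).  The package implements the standard
formula and records the discrepancy; it does not tune to reproduce the
inconsistent rows.

# Precursor window ladder

The source does not define how much flanking genome to fold.  We use a
flank ladder of 20/50/100/150 nt on each side (truncated at contig
ends) and retain the **smallest window whose structure passes all five
criteria**; when none passes, the window with the fewest failed criteria
(smallest on ties) defines the reported rejection reasons.  A locus with
no extractable flank at all is skipped with a diagnostic.

# Preprocessing conventions

* **Adapter**: a prefix of the 3' adapter of at least `min_overlap = 6`
  bases must align to the read's 3' end within a mismatch rate of 0.1;
  the leftmost qualifying match wins; a read equal to the adapter leaves
  an empty insert that the length filter then removes as `too_short`.
* **Junk** is undefined in the source; we define it as N-fraction > 0.1
  or fewer than 3 distinct bases (homopolymer/dimer artifacts), the
  standard low-complexity screen.
* **Contaminants** are matched as exact substrings on either strand
  (the original used BLAST; exact matching is deterministic and
  sufficient at desk scale), with fixed precedence adapter → length →
  junk → Rfam → Repbase so the ledger partitions the reads.  The
  published accounting's own categories evidently overlap (mappable ≠
  surviving − Rfam − Repbase by 19,228 reads in library A); this package
  enforces disjoint accounting and does not attempt to reproduce that
  figure.
* The filter chain is idempotent on its kept output from the length
  filter onward; trimming is excluded from the idempotence property
  because kept inserts no longer carry an adapter.

# Annotation conventions

* Conserved matching requires **equal length** (the source is silent;
  this avoids indel ambiguity) and uses Hamming distance; ties between
  families resolve to the lexicographically smallest family name and are
  logged.
* Reads with more than 20 exact genome hits are dropped as repetitive
  (threshold configurable).
* Identical matures from distinct loci become sub-members (`-1`, `-2`
  … in genome coordinate order); arms are suffixed `-5p`/`-3p` (or the
  older `-p5`/`-p3` dialect); a mature whose partner arm was never
  sequenced is reported with a `P-` ("predicted") prefix on the partner.

# Expression

Counts are normalized to reads per million **mappable** reads per
library (the source says only "normalized"; the denominator is
configurable).  Fold change is the larger/smaller RPM ratio; a zero cell
on one side only is replaced by a pseudo-RPM of 0.01 — small enough
never to flip a call at these depths while keeping the ratio finite.
Differential expression requires fold > 2, strictly.  qRT-PCR relative
expression is 2^−ΔΔCt against an internal control gene
(`ddct()`).  No replicate statistics are computed because the design has
none.

# Degradome target calling

Degradome (PARE) reads mark uncapped 5' ends of cleaved transcripts.
`map_degradome_reads()` anchors each read's first 20 nt by exact sense
match and accumulates 5'-end counts per transcript position;
multi-mapped reads count on every matching transcript, flagged.
t-plot categories follow the CleaveLand conventions (the source uses
0-4 without defining them): 0 = above one read, unique transcript
maximum; 1 = shared maximum; 2 = above the median of nonzero positions;
3 = at/below that median but above one read; 4 = exactly one read.

Alignment uses plant-standard penalties (mismatch 1, G:U 0.5, doubled
at miRNA positions 2-13, cutoff 4.5, ungapped scanning; scoring is
configurable).  The predicted slice site is the transcript position
opposite miRNA position 10.

The source's "cleavage at the 9th or 10th nucleotide of the binding
region" is ambiguous about the counting end.  Counting from the target
5' end places the admissible sites opposite miRNA nucleotides 12-13 of
a 21-mer — which contradicts the canonical 10-11 cleavage and would
make the predicted and observed rules mutually exclusive.  We therefore
count from the binding-region end **adjacent to the miRNA 5' end** by
default, which makes the 9th/10th positions exactly those opposite
miRNA nucleotides 9-10; the other convention remains available via
`check_cleavage_position(count_from = "target5")`.  A call requires
degradome evidence at an admissible site; the homology filter
(user-supplied transcript → *A. thaliana* map) is advisory when no map
is given.

# The synthetic data generator

`simulate_srna_study()` builds the entire input universe with
machine-readable truth.  Its defaults are the study conditions the
package is tested under: two libraries of 2×10^5 reads, ten true
hairpins plus one decoy per violable criterion, miRNA* at 10% of the
mature abundance (typical biology; the source's own extreme example is
2664 vs 1 reads across arms), planted fold classes of 4 (differential),
1.5 ("near", never to be called) and 1, ~8% contaminant, 1.5% junk, 2%
adapterless, 2% too-short, 0.5% too-long and 4% unannotated genomic
reads, a 21-base adapter, 48-base reads, and degradome libraries with
80% of each target's reads at the true slice site (100% in the
zero-background setting used for deterministic recovery checks).
Decoy hairpins violate exactly one criterion each: an unsequenced star,
four isolated mismatches, a four-mismatch run, two 1-nt bulges, one
3-nt bulge, a blunt (overhang-free) duplex, and an MFEI failure.
"Opposite arms" has no dedicated decoy because it cannot be violated
without also destroying the duplex pairing.

Because the fallback folder maximizes pairing, planted features must be
*unrescuable*: mismatches are A-opposite-A sites pinned between forced
G:C anchors, bulges are star-side insertions, and the MFEI decoy sits in
an unpairable all-C neighbourhood that raises window GC% without adding
energy.  Every hairpin block and every read species is validated
against the real pipeline code at generation time and redrawn on
failure, so the planted truth matches pipeline behaviour exactly —
including the removal ledger, which is reproduced read-for-read.

What the simulation does **not** emulate: sequencing errors and quality
scores, isomiR heterogeneity, multi-locus repetitive families, RNA
editing, partial adapter dimers, and thermodynamically realistic folding
landscapes.  A green test suite therefore demonstrates the pipeline's
logic, bookkeeping and screening semantics — not performance on real
noisy libraries.

# Problem sizes and determinism

Unit tests run on reduced simulations (4 true hairpins, 3×10^4 reads
per library); the acceptance suite runs the default study-scale
conditions (17 hairpins, 2×10^5 reads per library, about two minutes on
one CPU) plus 1000-case oracle-equivalence loops for the duplex
evaluator and the t-plot categorizer.  All randomness flows through R's
RNG: the same seed reproduces every simulated file byte for byte.

# A small worked example

```{r example}
sim <- simulate_srna_study(sim_config(seed = 5, n_true_hairpins = 4,
                                      library_depth = 3e4))
res <- discover_mirnas(sim)
summary(res)
score <- score_discovery(res, sim)
score$recovery
score$hairpins[score$hairpins$type != "true",
               c("type", "violated", "reported_failed")]
```

# Known limitations

* The fallback folder's energies are proxies; MFEI under it is
  comparable only within this package.  Real-data use should supply
  Vienna-format structures from a thermodynamic folder.
* Target alignment is ungapped (binding-region length equals miRNA
  length); plant miRNA targets rarely need gaps, and gapped scoring
  would require an affine scheme the source does not specify.
* Conserved matching ignores length-polymorphic variants of known
  matures.
* The homology criterion is only as good as the user-supplied map; no
  sequence-level homology search is performed.
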