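#' Printed summary tables of the reimplemented study
#'
#' The pipeline reimplements a published *Brassica campestris* flower-bud
#' small RNA study comparing a male-sterile (A) and a male-fertile (B)
#' line.  These accessors return the study's printed summary tables,
#' which serve as reference inputs: the read-accounting ledger per
#' library, the eight known-precursor other-arm miRNAs with per-library
#' read counts, and the 25 novel miRNA/miRNA* pairs with their precursor
#' statistics (mature length LM, precursor length LP, GC percentage,
#' folding energy dG in kcal/mol, MFEI, and reads in the A and B flower
#' bud libraries).
#'
#' @return `study_read_accounting()`: one row per library with the raw
#'   read total and per-category removal counts.
#' @export
study_read_accounting <- function() {
  data.frame(
    library = c("A", "B"),
    raw = c(6998586, 6792888),
    raw_unique = c(2093851, 2463600),
    no_3adt = c(507331, 212884),
    too_short = c(1365432, 1237678),
    junk = c(27276, 33207),
    rfam = c(541924, 611768),
    repbase = c(35231, 73970),
    mappable = c(4540620, 4667617),
    mappable_unique = c(1696791, 2075669),
    stringsAsFactors = FALSE)
}

#' @rdname study_read_accounting
#' @return `study_known_arm_counts()`: the eight other-arm miRNAs of
#'   known precursors with reads in each library.
#' @export
study_known_arm_counts <- function() {
  data.frame(
    mir_name = c("bra-miR164a-p3", "bra-miR167b-p3", "bra-miR171b-p5",
                 "bra-miR171e-p5", "bra-miR172a-p5", "bra-miR824-p3",
                 "bra-miR1140-p5", "bra-miR5718-p5"),
    sequence = c("CACGTGCTCCACTCCTCCAAC", "GATCATGTTCGCAGTTTCACC",
                 "AGATATTAGTGCGGTTCAATC", "TATTGGCCTGGTTCACTCAGA",
                 "GCAGCACCATCAAGATTCACA", "CCTTCTCATCGATGGTCTAGA",
                 "TCCGATTGGCTTTAGGCTGTTG", "TGTTCTGGTTTGATTTTGAAC"),
    length = c(21, 21, 21, 21, 21, 21, 22, 21),
    reads_A = c(108, 6061, 53, 200, 8, 520, 709, 1686),
    reads_B = c(44, 3762, 17, 1049, 8, 3882, 1068, 1258),
    stringsAsFactors = FALSE)
}

#' @rdname study_read_accounting
#' @return `study_novel_mirna_table()`: one row per reported novel
#'   mature (50 rows, 25 precursors identified by `precursor_id`).
#' @export
study_novel_mirna_table <- function() {
  txt <- "
name\tsequence\tLM\tLP\tCG\tdG\tMFEI\tFbA\tFbB
bra-miRn1-1-5p\tCTATCGGTCTACTCGGTCAGC\t21\t153\t50\t-131.5\t1.2\t19\t7
bra-miRn1-1-3p\tTGACCGAGTAGACCGATAGTC\t21\t153\t50\t-131.5\t1.2\t87\t222
bra-miRn1-2-5p\tCTATCGGTCTACTCGGTCAGC\t21\t153\t47\t-152.2\t1.3\t19\t7
bra-miRn1-2-3p\tTGACCGAGTAGACCGATAGTC\t21\t153\t47\t-152.2\t1.3\t87\t222
bra-miRn2-5p\tCAACAGTCTCAGGATGGAAAA\t21\t134\t35\t-47.6\t1\t3\t12
bra-miRn2-3p\tTTTCATCTTAGAGAATGTTGTT\t22\t134\t35\t-47.6\t1\t57\t153
bra-miRn3-5p\tTACAAAGCTGAAGCTAATTATG\t22\t141\t41\t-70.2\t0.9\t18\t56
bra-miRn3-3p\tTAATCAGCTCCAGCTATGTACA\t22\t141\t41\t-70.2\t0.9\t145\t175
bra-miRn4-5p\tGAATGATACTTGGATATGATC\t21\t147\t34.7\t-80.3\t1.5\t14\t6
bra-miRn4-3p\tTTATATCCAAGTATCATTCCT\t21\t147\t34.7\t-80.3\t1.5\t15\t34
bra-miRn5-5p\tTTCTAAGCTTTACGGGAAACC\t21\t201\t29\t-101.4\t1.7\t10\t11
bra-miRn5-3p\tTTTCCCGTAAAGCTTAGAACC\t21\t201\t29\t-101.4\t1.7\t12\t7
bra-miRn6-5p\tGTCAATTGGTGATAGTAGTTC\t21\t84\t36.7\t-38.3\t1.2\t11\t41
bra-miRn6-3p\tTCTACTTTCACCAATTGGCCT\t21\t84\t36.7\t-38.3\t1.2\t4\t54
bra-miRn7-5p\tTTTTGCGTTTCAACTCGGTCC\t21\t139\t38.8\t-64\t0.9\t73\t61
bra-miRn7-3p\tGCTGAGTTGGAACACAAAATC\t21\t139\t38.8\t-64\t0.9\t19\t8
bra-miRn8-5p\tAGAGATGTCTGGCTTGCAACA\t21\t140\t44.5\t-74.3\t1.1\t1\t3
bra-miRn8-3p\tTTGCAAGCCAGACATTTCCTTT\t22\t140\t44.5\t-74.3\t1.1\t5\t9
bra-miRn9-5p\tTTTGGATTTTGGTCATTGTTG\t21\t107\t32.1\t-50.7\t1.4\t0\t2
bra-miRn9-3p\tACAATGAACGAAATCCAAATC\t21\t107\t32.1\t-50.7\t1.4\t4\t9
bra-miRn10-1-5p\tACAGGTGGTGGAACAAATATGAGT\t24\t128\t31.8\t-52.5\t1.3\t1\t13
bra-miRn10-1-3p\tTCATATTAGTTCTACCTCCTGCTG\t24\t128\t31.8\t-52.5\t1.3\t2\t7
bra-miRn10-2-5p\tACAGGTGGTGGAACAAATATGAGT\t24\t130\t31.6\t-44.4\t1\t1\t13
bra-miRn10-2-3p\tTCATATTAGTTCTACCTCCTGCTG\t24\t130\t31.6\t-44.4\t1\t2\t7
bra-miRn11-5p\tTGAGTCTCTCACCAGTCTTTCAC\t23\t117\t34.1\t-59.3\t1.4\t2\t2
bra-miRn11-3p\tGAGAGACTCTGAAAGACTCACC\t22\t117\t34.1\t-59.3\t1.4\t8\t5
bra-miRn12-5p\tTGTAATTGCGGGGTTCTAAGC\t21\t204\t29.1\t-103.6\t1.7\t7\t9
bra-miRn12-3p\tTTAGAAACCTGCAATTATATA\t21\t204\t29.1\t-103.6\t1.7\t3\t3
bra-miRn13-5p\tACTATGCAATTGTGAACAAAC\t21\t128\t29.5\t-56.4\t1.3\t2\t3
bra-miRn13-3p\tTTATTCACAACTGCATAATTC\t21\t128\t29.5\t-56.4\t1.3\t2\t0
bra-miRn14-5p\tGGGAGCCAGGGAAGAGGCAGT\t21\t165\t41.7\t-66\t0.9\t0\t2
bra-miRn14-3p\tTGCTTGTTCCCTGTCTCTCTC\t21\t165\t41.7\t-66\t0.9\t4\t1
bra-miRn15-5p\tACCCGTCTCTTAATTTTTAAC\t21\t161\t31.7\t-59.4\t1.1\t19\t32
bra-miRn15-3p\tTAAAAGTTAAGAGACAAGTTA\t21\t161\t31.7\t-59.4\t1.1\t0\t1
bra-miRn16-5p\tATAAAACGATTACACAGCTCGGTC\t24\t230\t42.1\t-209.8\t2.1\t1\t1
bra-miRn16-3p\tCGAGCTGTGTAATCGTTTTGTTA\t23\t230\t42.1\t-209.8\t2.1\t1\t0
bra-miRn17-5p\tTCTCGTTCTCTCGTTTCAGCT\t21\t114\t39.6\t-56.6\t1\t0\t3
bra-miRn17-3p\tCTGAAGCTAGTGAAAGAGAGA\t21\t114\t39.6\t-56.6\t1\t0\t2
bra-miRn18-5p\tTTGTTGACAAATACTTAGGCTC\t22\t154\t33.5\t-121.6\t1.7\t3\t7
bra-miRn18-3p\tGAGCCTAAGTATTTGTCAACAATG\t24\t154\t33.5\t-121.6\t1.7\t0\t7
bra-miRn19-5p\tTAAACAACACATATACTTTGC\t21\t132\t37\t-89.6\t1.8\t0\t2
bra-miRn19-3p\tAAACTATATGTGTTGCTTAGA\t21\t132\t37\t-89.6\t1.8\t1\t0
bra-miRn20-5p\tAAGAACTCGTCTCTTAACTTTTAA\t24\t177\t30.7\t-86.7\t1.2\t1\t5
bra-miRn20-3p\tAAACTAAGAGATGAATTCTTAC\t22\t177\t30.7\t-86.7\t1.2\t1\t1
bra-miRn21-5p\tNGCGGATATCTTAGGATGAGGT\t22\t144\t28.7\t-55.8\t1.3\t0\t1
bra-miRn21-3p\tTCATCGTAAGAGATCTGCATT\t21\t144\t28.7\t-55.8\t1.3\t0\t1
bra-miRn22-5p\tTGAGTTATCATTGGTCTTGTG\t21\t186\t28.1\t-94.6\t1.8\t0\t1
bra-miRn22-3p\tACACAGGAACAATACTAACTCATT\t24\t186\t28.1\t-94.6\t1.8\t2664\t4123
bra-miRn23-5p\tCTTTGTCTATCGTTTGGAAAAG\t22\t101\t37.4\t-37\t0.9\t25\t95
bra-miRn23-3p\tTTTCCAAATGTAGACAAAGCT\t21\t101\t37.4\t-37\t0.9\t0\t1
"
  df <- read.delim(text = txt, stringsAsFactors = FALSE)
  df$precursor_id <- sub("-(p[35]|[35]p)$", "", df$name)
  df
}
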