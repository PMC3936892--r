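#' Normalize per-miRNA counts to reads per million
#'
#' The denominator is the mappable-read total of each library, so RPM sums
#' to 1e6 per library when normalizing over all mappable sequences.
#'
#' @param counts data frame with `mir_name`, `reads_A`, `reads_B`.
#' @param lib_sizes numeric c(A = , B = ) mappable totals, > 0.
#' @return the data frame with `rpm_A`, `rpm_B`, `lib_size_A`,
#'   `lib_size_B` added.
#' @export
normalize_rpm <- function(counts, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  counts$lib_size_A <- unname(lib_sizes["A"])
  counts$lib_size_B <- unname(lib_sizes["B"])
  counts$rpm_A <- counts$reads_A / counts$lib_size_A * 1e6
  counts$rpm_B <- counts$reads_B / counts$lib_size_B * 1e6
  counts
}

#' Call fold change and differential expression between two libraries
#'
#' Fold change is the ratio of the larger normalized abundance to the
#' smaller, so it is always >= 1; the direction records which library is
#' larger.  A zero cell on one side only is replaced by `pseudo_rpm` to
#' keep the ratio finite; nonzero ratios are never perturbed.  Both cells
#' zero gives fold 1, unchanged.  The differential-expression call is
#' strict: more than two-fold.
#'
#' @param records data frame with `rpm_A` and `rpm_B` (see
#'   [normalize_rpm()]).
#' @param pseudo_rpm replacement for a zero cell when the other is
#'   positive.
#' @param de_threshold strict fold-change threshold.
#' @return the data frame with `fold_change`, `direction`
#'   (`up_in_A`/`up_in_B`/`unchanged`) and `is_de` added.
#' @export
fold_change <- function(records, pseudo_rpm = 0.01, de_threshold = 2) {
  a <- records$rpm_A
  b <- records$rpm_B
  both_zero <- a == 0 & b == 0
  a2 <- ifelse(a == 0 & b > 0, pseudo_rpm, a)
  b2 <- ifelse(b == 0 & a > 0, pseudo_rpm, b)
  fold <- ifelse(both_zero, 1, pmax(a2, b2) / pmin(a2, b2))
  direction <- ifelse(both_zero | a2 == b2, "unchanged",
                      ifelse(b2 > a2, "up_in_B", "up_in_A"))
  records$fold_change <- fold
  records$direction <- direction
  records$is_de <- fold > de_threshold
  records
}

#' Relative qRT-PCR quantification by the 2^-ddCt method
#'
#' ddCt = (target - reference) Ct of the test sample minus the same
#' difference in the calibrator; relative expression is 2^-ddCt against an
#' internal control gene.
#'
#' @param target_ct_test,ref_ct_test Ct values in the test sample.
#' @param target_ct_calibrator,ref_ct_calibrator Ct values in the
#'   calibrator sample.
#' @return list with `delta_ct_test`, `delta_ct_calibrator`,
#'   `delta_delta_ct` and `relative_expression`.
#' @export
ddct <- function(target_ct_test, ref_ct_test,
                 target_ct_calibrator, ref_ct_calibrator) {
  if (any(c(target_ct_test, ref_ct_test, target_ct_calibrator,
            ref_ct_calibrator) <= 0))
    stop("Ct values must be positive")
  d_test <- target_ct_test - ref_ct_test
  d_cal <- target_ct_calibrator - ref_ct_calibrator
  ddct <- d_test - d_cal
  list(delta_ct_test = d_test, delta_ct_calibrator = d_cal,
       delta_delta_ct = ddct, relative_expression = 2^(-ddct))
}
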