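#' Assemble a qPCR CT record
#'
#' One record holds the four cycle-threshold measurements of the
#' double-delta-CT design: target and reference gene, each in the test
#' sample and in a calibrator sample known to be diploid at both loci.
#' Replicate CTs may be supplied for any slot; they are averaged. CT
#' values above `ct_cap` (default 40 cycles, the usual run length) are
#' truncated to it, which is how a complete deletion (no amplification)
#' enters the arithmetic.
#'
#' @param ct_target_test,ct_ref_test,ct_target_cal,ct_ref_cal numeric
#'   vectors of replicate CT values (> 0).
#' @param assay assay identifier.
#' @param ct_cap maximal meaningful CT.
#' @return a list of class `qpcr_record` with the four averaged CTs.
#' @export
qpcr_record <- function(ct_target_test, ct_ref_test, ct_target_cal,
                        ct_ref_cal, assay = "assay", ct_cap = 40) {
  avg <- function(x, what) {
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("missing CT replicates for ", what)
    if (any(x <= 0)) stop("CT values must be positive (", what, ")")
    mean(pmin(x, ct_cap))
  }
  structure(list(assay = assay,
                 ct_target_test = avg(ct_target_test, "target/test"),
                 ct_ref_test = avg(ct_ref_test, "reference/test"),
                 ct_target_cal = avg(ct_target_cal, "target/calibrator"),
                 ct_ref_cal = avg(ct_ref_cal, "reference/calibrator"),
                 ct_cap = ct_cap),
            class = "qpcr_record")
}

#' Copy-number ratio by the 2^-ddCT method
#'
#' `ddCT = (CT_target,test - CT_ref,test) - (CT_target,cal - CT_ref,cal)`;
#' the fold change is `2^-ddCT` (amplification efficiency fixed at perfect
#' doubling) and the diploid-normalized ratio is `NR = 2 * 2^-ddCT`, so a
#' sample with no copy-number change gives NR = 2, a one-copy deletion
#' NR = 1, a one-copy gain NR = 3.
#'
#' @param record a [qpcr_record()].
#' @return list with `ddct`, `fold` (= 2^-ddct), `nr` (= 2 * fold) and
#'   `status` (see [interpret_nr()]).
#' @export
ddct <- function(record) {
  stopifnot(inherits(record, "qpcr_record"))
  dd <- (record$ct_target_test - record$ct_ref_test) -
    (record$ct_target_cal - record$ct_ref_cal)
  fold <- 2^(-dd)
  nr <- 2 * fold
  list(ddct = dd, fold = fold, nr = nr, status = interpret_nr(nr))
}

#' Interpret a diploid-normalized qPCR ratio
#'
#' Thresholds are the midpoints between the NR values of integer copy
#' numbers (0, 1, 2, >= 3): NR < 0.5 is a double deletion, 0.5 <= NR < 1.5
#' a single deletion, 1.5 <= NR < 2.5 normal, NR >= 2.5 a gain of one or
#' more copies.
#'
#' @param nr positive normalized ratio(s).
#' @return character vector of statuses: `"double-deletion"`,
#'   `"single-deletion"`, `"normal"` or `"gain"`.
#' @export
interpret_nr <- function(nr) {
  if (any(nr <= 0)) stop("NR must be positive")
  ifelse(nr < 0.5, "double-deletion",
         ifelse(nr < 1.5, "single-deletion",
                ifelse(nr < 2.5, "normal", "gain")))
}

#' Concordance between array copy-number predictions and qPCR ratios
#'
#' Pearson correlation (with the two-sided t-based p-value) between the
#' array-predicted copy numbers and the measured normalized ratios of the
#' validated assays.
#'
#' @param predicted_cn numeric vector of array copy numbers.
#' @param nr matching vector of qPCR normalized ratios.
#' @return list with `r`, `p`, `n`.
#' @export
cn_concordance <- function(predicted_cn, nr) {
  if (length(predicted_cn) != length(nr) || length(nr) < 3)
    stop("need paired vectors of length >= 3")
  if (sd(predicted_cn) == 0 || sd(nr) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(predicted_cn, nr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(nr))
}
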