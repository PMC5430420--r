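#' Per-sample signal quality control
#'
#' Computes the four per-sample array quality metrics used to gate CNV
#' calling, and a pass flag:
#' \itemize{
#'   \item call rate: fraction of markers with a genotype call (not "NC");
#'   \item `sd_lrr`: standard deviation of non-missing autosomal LRR;
#'   \item `baf_drift`: fraction of non-missing BAF falling in the artifact
#'     bands `[0.2, 0.25]` or `[0.75, 0.8]`;
#'   \item `waviness`: SD of the per-window median LRR (default 1-Mb
#'     windows), capturing long-range LRR oscillation.
#' }
#' A sample passes iff call rate >= `min_call_rate`, `sd_lrr` <
#' `max_sd_lrr`, `baf_drift` < `max_baf_drift` and `waviness` <
#' `max_waviness` (defaults 0.90 / 0.30 / 0.01 / 0.05).
#'
#' @param sig a [signal_set()].
#' @param window_size window for the waviness metric, in bp.
#' @param min_call_rate,max_sd_lrr,max_baf_drift,max_waviness thresholds.
#' @return data.frame with one row per sample: `sample`, `call_rate`,
#'   `sd_lrr`, `baf_drift`, `waviness`, `pass`.
#' @export
sample_qc <- function(sig, window_size = 1e6, min_call_rate = 0.90,
                      max_sd_lrr = 0.30, max_baf_drift = 0.01,
                      max_waviness = 0.05) {
  win <- paste(sig$map$chr, floor((sig$map$pos - 1) / window_size))
  res <- lapply(sig$samples, function(s) {
    lrr <- sig$lrr[, s]; baf <- sig$baf[, s]
    if (sum(!is.na(lrr)) < 2)
      stop("sample ", s, " has fewer than 2 non-missing markers")
    call_rate <- mean(sig$gtype[, s] != "NC")
    sd_lrr <- sd(lrr, na.rm = TRUE)
    bn <- baf[!is.na(baf)]
    drift <- mean((bn >= 0.2 & bn <= 0.25) | (bn >= 0.75 & bn <= 0.8))
    med <- tapply(lrr, win, median, na.rm = TRUE)
    med <- med[!is.na(med)]
    wav <- if (length(med) < 2) 0 else sd(med)
    data.frame(sample = s, call_rate = call_rate, sd_lrr = sd_lrr,
               baf_drift = drift, waviness = wav, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pass <- out$call_rate >= min_call_rate & out$sd_lrr < max_sd_lrr &
    out$baf_drift < max_baf_drift & out$waviness < max_waviness
  rownames(out) <- NULL
  out
}

#' Per-marker genotype quality control
#'
#' For each marker: missingness (fraction "NC"), minor allele frequency
#' from the called genotypes, and a 1-df chi-square goodness-of-fit test
#' against Hardy-Weinberg proportions. The HWE threshold is applied after
#' Bonferroni adjustment across the tested markers: a marker fails HWE iff
#' its adjusted P (`min(1, P * n_markers)`) falls below `hwe_alpha`.
#' Monomorphic markers have HWE P defined as 1. A marker passes iff
#' missingness <= `max_missing`, MAF >= `min_maf` and it does not fail HWE.
#'
#' @param gtype character matrix of genotypes (markers x samples) with
#'   entries `"AA"`, `"AB"`, `"BB"`, `"NC"`.
#' @param max_missing,min_maf,hwe_alpha thresholds (defaults 0.10, 0.05,
#'   1e-5).
#' @return data.frame with one row per marker: `marker`, `missing`, `maf`,
#'   `hwe_p` (raw), `hwe_p_adj`, `pass`.
#' @export
marker_qc <- function(gtype, max_missing = 0.10, min_maf = 0.05,
                      hwe_alpha = 1e-5) {
  gtype <- as.matrix(gtype)
  m <- nrow(gtype)
  marker <- rownames(gtype)
  if (is.null(marker)) marker <- paste0("m", seq_len(m))
  nAA <- rowSums(gtype == "AA")
  nAB <- rowSums(gtype == "AB")
  nBB <- rowSums(gtype == "BB")
  n <- nAA + nAB + nBB
  missing <- 1 - n / ncol(gtype)
  pA <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  maf <- pmin(pA, 1 - pA)
  hwe_p <- mapply(hwe_chisq_p, nAA, nAB, nBB)
  hwe_p_adj <- pmin(1, hwe_p * m)
  pass <- !is.na(maf) & missing <= max_missing & maf >= min_maf &
    hwe_p_adj >= hwe_alpha
  data.frame(marker = marker, missing = missing, maf = maf,
             hwe_p = hwe_p, hwe_p_adj = hwe_p_adj, pass = pass,
             row.names = NULL, stringsAsFactors = FALSE)
}

# 1-df chi-square goodness of fit to Hardy-Weinberg genotype proportions
hwe_chisq_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n == 0) return(NA_real_)
  p <- (2 * nAA + nAB) / (2 * n)
  if (p == 0 || p == 1) return(1)         # monomorphic: no test
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(nAA, nAB, nBB) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Population frequency of the B allele (PFB) from cohort BAF
#'
#' The PFB of each marker is the arithmetic mean of its non-missing BAF
#' values across the cohort, clamped to `[0.01, 0.99]` so the HMM's
#' binomial genotype prior never degenerates. Markers with no non-missing
#' BAF get PFB 0.5 with a warning.
#'
#' @param sig a [signal_set()].
#' @return the signal set's [marker_map()] with the `pfb` column replaced.
#' @export
compute_pfb <- function(sig) {
  n_ok <- rowSums(!is.na(sig$baf))
  pfb <- rowMeans(sig$baf, na.rm = TRUE)
  if (any(n_ok == 0)) {
    warning(sum(n_ok == 0), " marker(s) with no non-missing BAF; PFB set to 0.5")
    pfb[n_ok == 0] <- 0.5
  }
  map <- sig$map
  map$pfb <- pmin(0.99, pmax(0.01, pfb))
  map
}
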