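# Brute-force / closed-form oracles, written independently of the package
# internals so they can arbitrate the interval and statistical operations.

# random interval set on one small chromosome (1-based inclusive)
random_intervals <- function(n, chr_len, min_len = 50, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(min_len, round(chr_len / 5))
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chr_len - l + 1L, 1), integer(1))
  data.frame(chr = "1", start = start, end = start + len - 1)
}

# single-linkage union by iterated pairwise merging: O(n^2) per pass,
# repeated to a fixed point -- deliberately naive
oracle_single_linkage <- function(iv) {
  regions <- split(iv, seq_len(nrow(iv)))
  regions <- lapply(regions, function(r)
    list(chr = r$chr, start = r$start, end = r$end))
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < length(regions)) {
      j <- i + 1
      while (j <= length(regions)) {
        a <- regions[[i]]; b <- regions[[j]]
        if (a$chr == b$chr && a$start <= b$end && b$start <= a$end) {
          regions[[i]] <- list(chr = a$chr, start = min(a$start, b$start),
                               end = max(a$end, b$end))
          regions[[j]] <- NULL
          merged_any <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(regions, as.data.frame))
  out[order(out$chr, out$start), , drop = FALSE]
}

# per-base occupancy bitmap of a set of intervals on one chromosome
oracle_bitmap <- function(iv, chr_len) {
  bits <- logical(chr_len)
  for (i in seq_len(nrow(iv))) bits[iv$start[i]:iv$end[i]] <- TRUE
  bits
}

# all-pairs overlap scan: which rows of a overlap >= 1 bp with any row of b
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chr == a$chr[i] & a$start[i] <= b$end & b$start <= a$end[i])
  }, logical(1))
}

# exact conditional Hardy-Weinberg test (two-sided, by heterozygote count)
oracle_hwe_exact <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    na <- (nA - h) / 2; nb <- n - na - h
    lchoose(n, na) + lchoose(n - na, h) + h * log(2) -
      lchoose(2 * n, nA)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[p <= p[hets == nAB] * (1 + 1e-9)])
}

# hypergeometric upper tail by explicit enumeration over draws
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# truth-to-calls adapter: treat simulated truth CNVs as if they were calls
truth_as_calls <- function(truth) {
  data.frame(sample = truth$sample, chr = truth$chr, start = truth$start,
             end = truth$end, cn = truth$cn, state = truth$state,
             numsnp = NA_integer_, stringsAsFactors = FALSE)
}

# small diploid-only signal set used across QC tests
toy_signal_set <- function(n = 100, samples = c("A", "B"), lrr = 0,
                           baf_levels = c(0, 0.5, 1)) {
  map <- marker_map(paste0("m", seq_len(n)), rep("1", n),
                    seq(1e4, by = 1e4, length.out = n))
  L <- matrix(lrr, n, length(samples), dimnames = list(NULL, samples))
  B <- matrix(rep_len(baf_levels, n * length(samples)), n, length(samples),
              dimnames = list(NULL, samples))
  G <- matrix(c("AA", "AB", "BB")[match(B, c(0, 0.5, 1))], n,
              length(samples), dimnames = list(NULL, samples))
  signal_set(map, L, B, G)
}
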