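#' Specification of the copy-number hidden Markov model
#'
#' Five hidden states, one per copy number 0..4 (diploid = 2). Emissions
#' combine a Gaussian LRR term around the per-state mean with a BAF term:
#' a PFB-weighted mixture over the genotype clusters allowed by the state
#' (cn 2 -> 0, 1/2, 1; cn 1 -> 0, 1; cn 3 -> 0, 1/3, 2/3, 1; cn 4 ->
#' quarters; cn 0 -> uniform on `[0, 1]`), with half-Gaussian clusters at
#' the 0/1 boundaries and binomial-in-PFB mixture weights over B-allele
#' dosage. Transitions are distance-dependent:
#' `P(stay) = 1 - (1 - p_stay) * (1 - exp(-d / d0))`, so the chain almost
#' never jumps across tightly spaced markers and relaxes towards `p_stay`
#' at large gaps; off-diagonal mass is split uniformly. Setting `d0 = Inf`
#' disables the distance decay (`P(stay) = p_stay` everywhere).
#'
#' @param mu per-state LRR means (copy numbers 0..4).
#' @param lrr_sd per-state LRR SDs (recycled if length 1).
#' @param baf_sd BAF cluster SD.
#' @param p_stay long-distance self-transition probability.
#' @param d0 distance-decay constant in bp.
#' @param min_snps minimum markers per emitted CNV call.
#' @param pi_diploid prior probability of starting a chromosome diploid.
#' @return a list of class `hmm_spec`.
#' @export
hmm_spec <- function(mu = c(`0` = -3.5, `1` = -0.66, `2` = 0,
                            `3` = 0.40, `4` = 0.68),
                     lrr_sd = c(1.5, 0.35, 0.25, 0.25, 0.30),
                     baf_sd = 0.03, p_stay = 0.999, d0 = 1e5,
                     min_snps = 3L, pi_diploid = 0.996) {
  lrr_sd <- rep_len(lrr_sd, 5)
  stopifnot(length(mu) == 5, all(lrr_sd > 0), baf_sd > 0,
            p_stay > 0, p_stay < 1, d0 > 0, min_snps >= 1,
            pi_diploid > 0, pi_diploid < 1)
  structure(list(states = 0:4, mu = unname(mu), lrr_sd = lrr_sd,
                 baf_sd = baf_sd, p_stay = p_stay, d0 = d0,
                 min_snps = as.integer(min_snps), pi_diploid = pi_diploid),
            class = "hmm_spec")
}

#' BAF mixture density under a copy-number state
#'
#' Density over `[0, 1]` of the B Allele Frequency given copy number `cn`
#' and marker PFB. For cn >= 1 the mixture has one Gaussian component per
#' B-allele dosage `b = 0..cn` centred at `b / cn` with weight
#' `dbinom(b, cn, pfb)`; the boundary components at 0 and 1 are
#' half-Gaussians (doubled, folded into the unit interval). cn 0 has no
#' genotype signal: the density is uniform (1).
#'
#' @param baf,pfb numeric vectors in `[0, 1]` (recycled).
#' @param cn copy number, a single value in 0..4.
#' @param baf_sd cluster SD.
#' @return density values (not logged).
#' @export
baf_mixture_density <- function(baf, pfb, cn, baf_sd = 0.03) {
  if (cn == 0) return(rep(1, length(baf)))
  n <- max(length(baf), length(pfb))
  baf <- rep_len(baf, n); pfb <- rep_len(pfb, n)
  dens <- numeric(n)
  for (b in 0:cn) {
    w <- dbinom(b, cn, pfb)
    centre <- b / cn
    comp <- if (b == 0) {
      2 * dnorm(baf, 0, baf_sd) * (baf >= 0)
    } else if (b == cn) {
      2 * dnorm(baf, 1, baf_sd) * (baf <= 1)
    } else {
      dnorm(baf, centre, baf_sd)
    }
    dens <- dens + w * comp
  }
  dens
}

#' Per-marker emission log-likelihood of a copy-number state
#'
#' Sum of the Gaussian LRR log-density at the state's mean and the log of
#' the state's BAF mixture density. A missing LRR or BAF contributes 0 to
#' its term, so a marker with both missing is effectively skipped.
#'
#' @param lrr,baf,pfb numeric vectors (recycled to common length); `NA`
#'   allowed in `lrr` and `baf`.
#' @param cn copy-number state in 0..4.
#' @param hmm an [hmm_spec()].
#' @return vector of log-likelihood contributions.
#' @export
emission_loglik <- function(lrr, baf, pfb, cn, hmm = hmm_spec()) {
  stopifnot(cn %in% 0:4)
  n <- max(length(lrr), length(baf), length(pfb))
  lrr <- rep_len(lrr, n); baf <- rep_len(baf, n); pfb <- rep_len(pfb, n)
  s <- cn + 1L
  ll_lrr <- ifelse(is.na(lrr), 0,
                   dnorm(lrr, hmm$mu[s], hmm$lrr_sd[s], log = TRUE))
  d <- baf_mixture_density(ifelse(is.na(baf), 0.5, baf), pfb, cn, hmm$baf_sd)
  ll_baf <- ifelse(is.na(baf), 0, log(pmax(d, 1e-300)))
  ll_lrr + ll_baf
}

#' Viterbi decoding of a state sequence from emission log-likelihoods
#'
#' Low-level decoder: given an `n x 5` matrix of per-marker per-state
#' emission log-likelihoods and the marker positions, returns the
#' maximum-a-posteriori copy-number path under the distance-dependent
#' transition model of the [hmm_spec()]. All arithmetic is in log space.
#'
#' @param emis numeric matrix, markers x 5 states (copy numbers 0..4).
#' @param pos marker positions (bp), sorted increasing.
#' @param hmm an [hmm_spec()].
#' @return integer vector of decoded copy numbers (0..4).
#' @export
viterbi_path <- function(emis, pos, hmm = hmm_spec()) {
  n <- nrow(emis)
  if (n == 0) return(integer(0))
  pi0 <- rep((1 - hmm$pi_diploid) / 4, 5); pi0[3] <- hmm$pi_diploid
  score <- log(pi0) + emis[1, ]
  bp <- matrix(1L, n, 5)
  if (n > 1) {
    d <- diff(pos)
    decay <- if (is.finite(hmm$d0)) 1 - exp(-d / hmm$d0) else rep(1, n - 1)
    stay <- 1 - (1 - hmm$p_stay) * decay
    lstay <- log(stay); loff <- log((1 - stay) / 4)
    for (t in 2:n) {
      off <- score + loff[t - 1]
      o1 <- which.max(off)
      off2 <- off; off2[o1] <- -Inf
      o2 <- which.max(off2)
      alt <- rep(off[o1], 5); alt[o1] <- off[o2]
      alt_from <- rep(o1, 5); alt_from[o1] <- o2
      stayv <- score + lstay[t - 1]
      take_stay <- stayv >= alt
      bp[t, ] <- ifelse(take_stay, 1:5, alt_from)
      score <- ifelse(take_stay, stayv, alt) + emis[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(score)
  if (n > 1) for (t in n:2) path[t - 1] <- bp[t, path[t]]
  path - 1L
}

#' Segment one sample's signals into CNV calls
#'
#' Decodes each chromosome separately with [viterbi_path()] and converts
#' maximal runs of a non-diploid state into CNV calls whose boundaries are
#' the first and last marker of the run. Runs with fewer than
#' `hmm$min_snps` markers are absorbed back into the diploid state.
#' Chromosomes with fewer than `min_snps` markers yield no calls, with a
#' warning.
#'
#' @param lrr,baf numeric vectors aligned to `map`.
#' @param map a [marker_map()] (with PFB filled in).
#' @param hmm an [hmm_spec()].
#' @param sample sample id stamped on the calls.
#' @return data.frame of calls: `sample`, `chr`, `start`, `end`, `cn`,
#'   `state`, `numsnp`, `mean_lrr`.
#' @export
viterbi_segment <- function(lrr, baf, map, hmm = hmm_spec(), sample = "S") {
  out <- list()
  for (ch in unique(map$chr)) {
    i <- which(map$chr == ch)
    if (length(i) < hmm$min_snps) {
      warning("chromosome ", ch, " has fewer than ", hmm$min_snps,
              " markers; skipped")
      next
    }
    emis <- sapply(0:4, function(cn)
      emission_loglik(lrr[i], baf[i], map$pfb[i], cn, hmm))
    path <- viterbi_path(emis, map$pos[i], hmm)
    path <- absorb_short_runs(path, hmm$min_snps)
    r <- rle(path)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != 2L)) {
      idx <- i[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, chr = ch,
        start = map$pos[idx[1]], end = map$pos[idx[length(idx)]],
        cn = r$values[k],
        state = if (r$values[k] < 2) "loss" else "gain",
        numsnp = length(idx),
        mean_lrr = mean(lrr[idx], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chr = character(),
                      start = numeric(), end = numeric(), cn = integer(),
                      state = character(), numsnp = integer(),
                      mean_lrr = numeric()))
  do.call(rbind, out)
}

# set non-diploid runs shorter than min_snps back to diploid
absorb_short_runs <- function(path, min_snps) {
  r <- rle(path)
  short <- r$values != 2L & r$lengths < min_snps
  r$values[short] <- 2L
  inverse.rle(r)
}

#' Call CNVs across a whole cohort
#'
#' Runs [viterbi_segment()] on every sample of a [signal_set()].
#'
#' @param sig a [signal_set()]; its marker map must carry PFB (see
#'   [compute_pfb()]).
#' @param hmm an [hmm_spec()].
#' @return one calls data.frame for the cohort (same columns as
#'   [viterbi_segment()]).
#' @export
call_cnvs <- function(sig, hmm = hmm_spec()) {
  res <- lapply(sig$samples, function(s)
    viterbi_segment(sig$lrr[, s], sig$baf[, s], sig$map, hmm, sample = s))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Breakpoint-tolerant precision and recall against simulated truth
#'
#' A call matches a truth CNV iff they share sample, chromosome and
#' direction (loss/gain) and both breakpoints agree within
#' `tol_markers` marker positions of the map. Precision is the fraction of
#' calls matching some truth CNV; recall the fraction of truth CNVs
#' matched by some call.
#'
#' @param calls calls data.frame (from [call_cnvs()]).
#' @param truth truth data.frame (from [simulate_truth()]).
#' @param map the [marker_map()] both refer to.
#' @param tol_markers breakpoint tolerance in markers.
#' @return list with `precision`, `recall`, `n_calls`, `n_truth`.
#' @export
call_performance <- function(calls, truth, map, tol_markers = 2L) {
  # index of the first/last map marker inside an interval, per chromosome
  span_idx <- function(chr, start, end) {
    i <- which(map$chr == chr & map$pos >= start & map$pos <= end)
    if (length(i) == 0) c(NA_integer_, NA_integer_) else range(i)
  }
  t_idx <- t(mapply(span_idx, truth$chr, truth$start, truth$end))
  c_idx <- t(mapply(span_idx, calls$chr, calls$start, calls$end))
  t_state <- ifelse(truth$cn < 2, "loss", "gain")
  truth_hit <- rep(FALSE, nrow(truth))
  call_hit <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    j <- which(truth$sample == calls$sample[i] &
                 truth$chr == calls$chr[i] &
                 t_state == calls$state[i] &
                 abs(t_idx[, 1] - c_idx[i, 1]) <= tol_markers &
                 abs(t_idx[, 2] - c_idx[i, 2]) <= tol_markers)
    if (length(j) > 0) {
      call_hit[i] <- TRUE
      truth_hit[j] <- TRUE
    }
  }
  list(precision = if (nrow(calls)) mean(call_hit) else NA_real_,
       recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
       n_calls = nrow(calls), n_truth = nrow(truth))
}
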