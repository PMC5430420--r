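#' Merge per-sample CNV calls into copy-number-variable regions (CNVRs)
#'
#' CNVs from all samples are aggregated by single-linkage transitive
#' union: two intervals join iff they overlap by at least 1 bp, and
#' chained overlaps join into one region, so a CNVR may span call pairs
#' that do not directly overlap each other. Regions shorter than
#' `min_len` are removed *after* merging. The frequency of a CNVR is the
#' percentage of the cohort carrying at least one overlapping CNV (an
#' animal with two CNVs in one region is counted once).
#'
#' @param calls calls data.frame (`sample`, `chr`, `start`, `end`, `cn`,
#'   `state`, ...).
#' @param cohort_size number of samples in the post-QC cohort; must be at
#'   least the number of distinct samples in `calls`.
#' @param min_len minimum CNVR length in bp (default 1 kb).
#' @return data.frame of CNVRs: `chr`, `start`, `end`, `length`, `state`
#'   (`loss`/`gain`/`both`), `n_cnv`, `n_samples`, `freq` (percent),
#'   `samples` (comma-separated ids), sorted by chromosome and start.
#' @export
merge_to_cnvrs <- function(calls, cohort_size, min_len = 1000) {
  n_dist <- length(unique(calls$sample))
  if (cohort_size < n_dist)
    stop("cohort_size (", cohort_size, ") is smaller than the number of ",
         "distinct samples in the calls (", n_dist, ")")
  empty <- data.frame(chr = character(), start = numeric(), end = numeric(),
                      length = numeric(), state = character(),
                      n_cnv = integer(), n_samples = integer(),
                      freq = numeric(), samples = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  gr <- as_granges(calls)
  red <- reduce(gr, min.gapwidth = 0L)   # join only on >= 1 bp overlap
  hits <- findOverlaps(gr, red)
  grp <- subjectHits(hits)[order(queryHits(hits))]  # one region per call
  regions <- data.frame(chr = as.character(GenomicRanges::seqnames(red)),
                        start = start(red), end = end(red))
  rows <- lapply(seq_len(nrow(regions)), function(j) {
    members <- calls[grp == j, , drop = FALSE]
    sam <- sort(unique(members$sample))
    data.frame(chr = regions$chr[j], start = regions$start[j],
               end = regions$end[j],
               length = regions$end[j] - regions$start[j] + 1,
               state = assign_state(members$cn),
               n_cnv = nrow(members), n_samples = length(sam),
               freq = 100 * length(sam) / cohort_size,
               samples = paste(sam, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$length >= min_len, , drop = FALSE]
  out <- out[order_chr(out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CNVR state from its contributing copy numbers
#'
#' `loss` if every contributing CNV has cn < 2, `gain` if every one has
#' cn > 2, `both` otherwise. A contributing cn of 2 is impossible for a
#' CNV and raises an error.
#'
#' @param cn integer vector of contributing copy numbers.
#' @return `"loss"`, `"gain"` or `"both"`.
#' @export
assign_state <- function(cn) {
  if (length(cn) == 0) stop("a CNVR needs at least one contributing CNV")
  if (any(cn == 2)) stop("contributing CNV with cn=2 is not a CNV")
  if (all(cn < 2)) "loss" else if (all(cn > 2)) "gain" else "both"
}

#' Chromosome-level CNVR summary, length histogram and count regression
#'
#' Per chromosome: CNVR count, total and average CNVR length, percent
#' chromosome coverage, and the mean/min/max distance between consecutive
#' CNVRs (`next start - current end - 1`; `NA` on chromosomes with fewer
#' than two CNVRs). Genome-wide: an ordinary least-squares regression of
#' per-chromosome CNVR count on chromosome length (slope, intercept, R^2)
#' and a length histogram over the bins <10, 10-50, 50-100, 100-500,
#' 500-1000 and >1000 kb.
#'
#' @param cnvrs CNVR data.frame from [merge_to_cnvrs()].
#' @param genome a [genome_build()]; every genome chromosome appears in
#'   the summary (count 0 where no CNVR was seen) and in the regression.
#' @return list with `per_chr` (data.frame), `regression`
#'   (`slope`, `intercept`, `r_squared`), and `histogram` (data.frame
#'   `bin`, `n`, `fraction`).
#' @export
summarize_cnvrs <- function(cnvrs, genome) {
  chrs <- names(genome$lengths)
  per <- lapply(chrs, function(ch) {
    x <- cnvrs[cnvrs$chr == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    dist <- if (nrow(x) >= 2) x$start[-1] - x$end[-nrow(x)] - 1 else NA_real_
    data.frame(chr = ch, n = nrow(x),
               total_len = sum(x$length),
               avg_len = if (nrow(x)) mean(x$length) else NA_real_,
               coverage_pct = 100 * sum(x$length) / genome$lengths[[ch]],
               mean_dist = if (all(is.na(dist))) NA_real_ else mean(dist),
               min_dist = if (all(is.na(dist))) NA_real_ else min(dist),
               max_dist = if (all(is.na(dist))) NA_real_ else max(dist),
               stringsAsFactors = FALSE)
  })
  per_chr <- do.call(rbind, per)
  rownames(per_chr) <- NULL

  fit <- lm(per_chr$n ~ genome$lengths)
  ss_tot <- sum((per_chr$n - mean(per_chr$n))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  regression <- list(slope = unname(coef(fit)[2]),
                     intercept = unname(coef(fit)[1]),
                     r_squared = r2)

  breaks <- c(0, 10, 50, 100, 500, 1000, Inf) * 1000
  labels <- c("<10kb", "10-50kb", "50-100kb", "100-500kb",
              "500-1000kb", ">1000kb")
  counts <- if (nrow(cnvrs) > 0)
    table(cut(cnvrs$length, breaks, labels = labels, right = FALSE))
  else setNames(rep(0L, length(labels)), labels)
  histogram <- data.frame(bin = labels, n = as.integer(counts),
                          fraction = if (nrow(cnvrs) > 0)
                            as.integer(counts) / nrow(cnvrs) else NA_real_,
                          stringsAsFactors = FALSE)
  list(per_chr = per_chr, regression = regression, histogram = histogram)
}

#' @rdname read_study_table
#' @param cnvrs CNVR data.frame; written as a study table with the given
#'   label.
#' @param study study label stamped on the rows.
#' @export
cnvrs_as_study <- function(cnvrs, study) {
  data.frame(study = study, chr = cnvrs$chr, start = cnvrs$start,
             end = cnvrs$end, state = cnvrs$state, stringsAsFactors = FALSE)
}
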