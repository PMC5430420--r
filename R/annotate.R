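#' Overlap CNVRs with annotated features
#'
#' Every overlap of at least 1 bp between a CNVR and a feature interval is
#' reported. A CNVR is *genic* iff it overlaps at least one feature of
#' category `"gene"`; per-category counts give the number of CNVRs
#' touching at least one feature of each category (QTL classes, etc.).
#'
#' @param cnvrs CNVR data.frame (`chr`, `start`, `end`).
#' @param features interval records (see [interval_records()] /
#'   [read_bed_like()]) with `id` and `category`.
#' @return list with `hits` (data.frame `cnvr` row index, `id`,
#'   `category`), `genic` (logical per CNVR), `n_genic`, `n_intergenic`,
#'   and `category_counts` (named vector: CNVRs overlapping >= 1 feature
#'   of that category).
#' @export
overlap_features <- function(cnvrs, features) {
  if (nrow(features) == 0 || nrow(cnvrs) == 0) {
    hits <- data.frame(cnvr = integer(), id = character(),
                       category = character())
  } else {
    ov <- findOverlaps(as_granges(cnvrs), as_granges(features))
    hits <- data.frame(cnvr = queryHits(ov),
                       id = features$id[subjectHits(ov)],
                       category = features$category[subjectHits(ov)],
                       stringsAsFactors = FALSE)
  }
  genic <- rep(FALSE, nrow(cnvrs))
  genic[unique(hits$cnvr[hits$category == "gene"])] <- TRUE
  cats <- unique(features$category)
  category_counts <- vapply(cats, function(cc)
    length(unique(hits$cnvr[hits$category == cc])), integer(1))
  list(hits = hits, genic = genic,
       n_genic = sum(genic), n_intergenic = sum(!genic),
       category_counts = category_counts)
}

#' Overlap of CNV calls with assembly gaps
#'
#' Gaps shorter than `min_gap` (default 1 kb) are ignored. Reports how
#' many calls touch at least one gap, how many distinct gaps are touched,
#' and the corresponding fractions.
#'
#' @param calls CNV calls or CNVRs (`chr`, `start`, `end`).
#' @param gaps gap intervals (`chr`, `start`, `end`), e.g.
#'   `genome$gaps` of a [genome_build()].
#' @param min_gap minimum gap length in bp.
#' @return list with `n_calls_in_gap`, `frac_calls_in_gap`,
#'   `n_gaps_hit`, `frac_gaps_hit`, `n_gaps_considered`.
#' @export
gap_overlap <- function(calls, gaps, min_gap = 1000) {
  gaps <- gaps[(gaps$end - gaps$start + 1) >= min_gap, , drop = FALSE]
  call_hit <- overlaps_any(calls, gaps)
  gap_hit <- overlaps_any(gaps, calls)
  list(n_calls_in_gap = sum(call_hit),
       frac_calls_in_gap = if (nrow(calls)) mean(call_hit) else NA_real_,
       n_gaps_hit = sum(gap_hit),
       frac_gaps_hit = if (nrow(gaps)) mean(gap_hit) else NA_real_,
       n_gaps_considered = nrow(gaps))
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the seen number of hit genes in the set, given the
#' universe, followed by Benjamini-Hochberg adjustment across sets. The
#' universe defaults to all genes of the annotation the hits were drawn
#' from; it must contain every hit and every set member.
#'
#' @param hits character vector of hit gene ids (e.g. genes overlapped by
#'   CNVRs).
#' @param sets data.frame with columns `set` and `gene`.
#' @param universe character vector of all considered gene ids.
#' @return data.frame, one row per set: `set`, `size`, `overlap`,
#'   `p_value`, `q_value`, sorted by p.
#' @export
enrich <- function(hits, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  if (!all(sets$gene %in% universe))
    stop("gene sets must be subsets of the universe")
  N <- length(universe); n <- length(hits)
  by_set <- split(unique(sets[, c("set", "gene")])$gene,
                  unique(sets[, c("set", "gene")])$set)
  rows <- lapply(names(by_set), function(nm) {
    K <- length(by_set[[nm]])
    k <- length(intersect(hits, by_set[[nm]]))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, size = K, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
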