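#' Classify query CNVRs as known or novel against reference studies
#'
#' A query CNVR is "known" iff it overlaps (>= 1 bp) at least one CNVR in
#' at least one reference dataset, "novel" otherwise. Per-study counts of
#' overlapping query CNVRs are reported alongside.
#'
#' @param query CNVR data.frame (`chr`, `start`, `end`, ...).
#' @param references named list of reference tables (each with `chr`,
#'   `start`, `end`).
#' @return list with `known` (logical per query row), `n_known`,
#'   `n_novel`, and `per_study` (named integer vector of overlap counts).
#' @export
classify_novelty <- function(query, references) {
  per_study <- vapply(references, function(ref)
    sum(overlaps_any(query, ref)), integer(1))
  known <- Reduce(`|`, lapply(references, function(ref)
    overlaps_any(query, ref)), rep(FALSE, nrow(query)))
  list(known = known, n_known = sum(known), n_novel = sum(!known),
       per_study = per_study)
}

#' Build a composite CNVR set and study presence matrix
#'
#' All datasets' CNVRs are pooled and merged by single-linkage union
#' (>= 1 bp overlap), yielding one composite region list; the presence
#' matrix has one row per study and one column per composite region, with
#' entry 1 iff the study has at least one CNVR overlapping that region.
#'
#' @param datasets named list (>= 2) of CNVR tables (`chr`, `start`,
#'   `end`).
#' @return list with `composite` (data.frame `chr`, `start`, `end`) and
#'   `presence` (binary matrix, studies x composite regions).
#' @export
build_composite <- function(datasets) {
  if (length(datasets) < 2) stop("need at least two datasets")
  pool <- do.call(rbind, lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    data.frame(chr = norm_chr(d$chr), start = d$start, end = d$end)
  }))
  red <- reduce(as_granges(pool), min.gapwidth = 0L)
  composite <- data.frame(chr = as.character(GenomicRanges::seqnames(red)),
                          start = start(red), end = end(red))
  composite <- composite[order_chr(composite$chr, composite$start), ]
  rownames(composite) <- NULL
  cgr <- as_granges(composite)
  presence <- matrix(0L, length(datasets), nrow(composite),
                     dimnames = list(names(datasets), NULL))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (nrow(d) == 0) next
    hits <- findOverlaps(cgr, as_granges(d))
    presence[i, unique(queryHits(hits))] <- 1L
  }
  colnames(presence) <- sprintf("cnvr%04d", seq_len(nrow(composite)))
  list(composite = composite, presence = presence)
}

#' Ordination of studies by their CNVR presence profiles
#'
#' PCA of the row-centred presence matrix (each study's row has its mean
#' subtracted; no scaling, the data being binary): principal-component
#' scores are obtained from the singular value decomposition of the
#' centred matrix, equivalent to an eigen-decomposition of the covariance
#' between study profiles. Hierarchical clustering uses average linkage on
#' the Jaccard distance between binary presence rows.
#'
#' @param presence binary matrix, studies x regions (from
#'   [build_composite()]).
#' @return list with `scores` (studies x PCs), `var_explained` (fraction
#'   per PC), `dist` (Jaccard `dist` object), `hclust` (the tree), and
#'   `newick` (the tree serialised as a Newick string).
#' @export
ordinate <- function(presence) {
  if (nrow(presence) < 2 || ncol(presence) < 2)
    stop("need at least 2 studies and 2 composite regions")
  xc <- presence - rowMeans(presence)
  if (all(abs(xc) < 1e-12)) stop("presence matrix has zero variance")
  sv <- svd(xc)
  k <- sum(sv$d > 1e-9)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(presence)
  colnames(scores) <- paste0("PC", seq_len(k))
  var_explained <- sv$d[seq_len(k)]^2 / sum(sv$d^2)

  d <- vegan::vegdist(presence, method = "jaccard", binary = TRUE)
  hc <- hclust(d, method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(scores = scores, var_explained = var_explained,
       dist = d, hclust = hc, newick = nwk)
}

#' Breed-specific CNVRs across datasets
#'
#' Within each dataset, intervals shorter than `min_len` (default 100 kb)
#' are removed and the survivors re-merged (single linkage, >= 1 bp).
#' A merged region is specific to its dataset iff it overlaps no filtered
#' region of any other dataset. Venn-style membership counts over all
#' datasets are returned: for every merged region of every dataset, the
#' set of datasets it overlaps.
#'
#' @param datasets named list of CNV/CNVR tables (`chr`, `start`, `end`).
#' @param min_len minimum interval length in bp before merging.
#' @return list with `specific` (named list of data.frames of private
#'   regions), `n_specific` (named integer vector) and `membership`
#'   (data.frame `dataset`, `chr`, `start`, `end`, `pattern` where
#'   `pattern` lists the datasets the region overlaps, `+`-separated).
#' @export
breed_specific <- function(datasets, min_len = 1e5) {
  merged <- lapply(datasets, function(d) {
    d <- d[(d$end - d$start + 1) >= min_len, , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(chr = character(), start = numeric(), end = numeric()))
    red <- reduce(as_granges(d), min.gapwidth = 0L)
    data.frame(chr = as.character(GenomicRanges::seqnames(red)),
               start = start(red), end = end(red))
  })
  nms <- names(datasets)
  membership <- list(); specific <- list()
  for (nm in nms) {
    own <- merged[[nm]]
    others <- nms[nms != nm]
    hit <- vapply(others, function(o) overlaps_any(own, merged[[o]]),
                  logical(nrow(own)))
    hit <- matrix(hit, nrow = nrow(own))
    pattern <- apply(hit, 1, function(h)
      paste(c(nm, others[h]), collapse = "+"))
    membership[[nm]] <- data.frame(dataset = nm, own,
                                   pattern = if (nrow(own)) pattern else character(),
                                   stringsAsFactors = FALSE)
    specific[[nm]] <- own[rowSums(hit) == 0, , drop = FALSE]
    rownames(specific[[nm]]) <- NULL
  }
  list(specific = specific,
       n_specific = vapply(specific, nrow, integer(1)),
       membership = do.call(rbind, c(membership, list(make.row.names = FALSE))))
}
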