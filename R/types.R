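#' Construct a genome build
#'
#' A genome build is the coordinate frame for all interval work: a set of
#' uniquely named chromosomes with positive lengths, optionally carrying
#' assembly-gap intervals (1-based, inclusive) used by [gap_overlap()].
#'
#' @param lengths named numeric vector, chromosome name -> length in bp.
#'   Names default to `"1" .. "26"` style autosome labels if the vector is
#'   unnamed.
#' @param gaps optional data.frame with columns `chr`, `start`, `end`
#'   (1-based inclusive) giving assembly gaps; each gap must lie inside its
#'   chromosome.
#' @return an object of class `genome_build`: a list with elements
#'   `lengths` and `gaps`.
#' @examples
#' gb <- genome_build(c(`1` = 5e6, `2` = 3e6))
#' gb$lengths
#' @export
genome_build <- function(lengths, gaps = NULL) {
  if (is.null(names(lengths))) names(lengths) <- as.character(seq_along(lengths))
  lengths <- setNames(as.numeric(lengths), norm_chr(names(lengths)))
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names in genome build")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(gaps)) {
    gaps <- data.frame(chr = character(), start = numeric(), end = numeric())
  } else {
    gaps <- as.data.frame(gaps)[, c("chr", "start", "end")]
    gaps$chr <- norm_chr(gaps$chr)
    bad <- !(gaps$chr %in% names(lengths))
    if (any(bad)) stop("gap on unknown chromosome: ", gaps$chr[which(bad)[1]])
    if (any(gaps$start < 1) || any(gaps$end > lengths[gaps$chr]) ||
        any(gaps$start > gaps$end))
      stop("gap intervals must lie within [1, chromosome length]")
  }
  structure(list(lengths = lengths, gaps = gaps), class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", length(x$lengths), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp,",
      nrow(x$gaps), "gaps\n")
  invisible(x)
}

#' Construct and validate a marker map
#'
#' The marker map orders the SNP markers of the array along the genome and
#' carries the population frequency of the B allele (PFB) used as the
#' allele-frequency prior of the HMM.
#'
#' @param marker character vector of unique marker ids.
#' @param chr chromosome of each marker.
#' @param pos 1-based bp position; must be strictly increasing within each
#'   chromosome.
#' @param pfb population B-allele frequency in `[0, 1]`; defaults to 0.5.
#' @return a `data.frame` of class `marker_map` with columns
#'   `marker`, `chr`, `pos`, `pfb`, sorted in genome order.
#' @export
marker_map <- function(marker, chr, pos, pfb = rep(0.5, length(marker))) {
  df <- data.frame(marker = as.character(marker), chr = norm_chr(chr),
                   pos = as.numeric(pos), pfb = as.numeric(pfb),
                   stringsAsFactors = FALSE)
  df <- df[order_chr(df$chr, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  validate_marker_map(df)
  class(df) <- c("marker_map", "data.frame")
  df
}

validate_marker_map <- function(df) {
  if (anyDuplicated(df$marker))
    stop("marker ids must be unique: ", df$marker[anyDuplicated(df$marker)])
  if (any(df$pfb < 0 | df$pfb > 1, na.rm = TRUE))
    stop("PFB must lie in [0, 1]")
  by_chr <- split(df$pos, df$chr)
  for (ch in names(by_chr)) {
    p <- by_chr[[ch]]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("marker positions must be strictly increasing on chromosome ", ch)
  }
  invisible(df)
}

#' Construct interval records
#'
#' Generic 1-based inclusive genomic intervals used for genes, QTLs and
#' assembly gaps.
#'
#' @param chr,start,end interval coordinates (1-based inclusive).
#' @param id feature identifier.
#' @param category feature category label (e.g. `"gene"`, a QTL class, or
#'   `"gap"`).
#' @return a data.frame with columns `chr`, `start`, `end`, `id`,
#'   `category`, sorted by chromosome then start.
#' @export
interval_records <- function(chr, start, end, id = NULL, category = NA_character_) {
  n <- length(chr)
  if (is.null(id)) id <- sprintf("iv%d", seq_len(n))
  df <- data.frame(chr = norm_chr(chr), start = as.numeric(start),
                   end = as.numeric(end), id = as.character(id),
                   category = rep_len(as.character(category), n),
                   stringsAsFactors = FALSE)
  if (any(df$start < 1) || any(df$start > df$end))
    stop("intervals must satisfy 1 <= start <= end")
  df <- df[order_chr(df$chr, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## ---- internal helpers shared across modules ----

# chromosome labels arrive in mixed dialects ("chr1" vs "1"); normalise once
norm_chr <- function(x) sub("^chr", "", as.character(x))

# order chromosomes numerically when all labels are numeric, else lexically
order_chr <- function(chr, pos) {
  suppressWarnings(num <- as.numeric(chr))
  if (!anyNA(num)) order(num, pos) else order(chr, pos)
}

# data.frame of intervals -> GRanges (coordinates already 1-based inclusive)
as_granges <- function(df) {
  GRanges(seqnames = df$chr, ranges = IRanges(start = df$start, end = df$end))
}

# logical: which rows of `query` overlap (>= 1 bp) any row of `subject`
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0L) return(logical(0))
  hits <- findOverlaps(as_granges(query), as_granges(subject))
  out <- rep(FALSE, nrow(query))
  out[unique(queryHits(hits))] <- TRUE
  out
}
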