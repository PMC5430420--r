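#' Bundle aligned per-sample signals into a signal set
#'
#' A signal set is the in-memory form of an Illumina "final report": for a
#' cohort of samples it holds, aligned to one [marker_map()], the Log R
#' Ratio (LRR), B Allele Frequency (BAF) and genotype call of every marker.
#' Missing intensities are `NA`, missing genotypes are `"NC"`.
#'
#' @param map a `marker_map`.
#' @param lrr,baf numeric matrices, markers in rows (in `map` order),
#'   samples in columns; column names are sample ids.
#' @param gtype optional character matrix of the same shape with entries
#'   `"AA"`, `"AB"`, `"BB"` or `"NC"`.
#' @return a list of class `signal_set` with elements `map`, `lrr`, `baf`,
#'   `gtype`, `samples`.
#' @export
signal_set <- function(map, lrr, baf, gtype = NULL) {
  lrr <- as.matrix(lrr); baf <- as.matrix(baf)
  if (nrow(lrr) != nrow(map) || nrow(baf) != nrow(map))
    stop("signal matrices must have one row per marker in the map")
  if (!identical(dim(lrr), dim(baf)))
    stop("lrr and baf must have identical dimensions")
  if (is.null(colnames(lrr))) colnames(lrr) <- paste0("S", seq_len(ncol(lrr)))
  colnames(baf) <- colnames(lrr)
  bad <- baf < 0 | baf > 1
  if (any(bad, na.rm = TRUE))
    stop("BAF out of range [0, 1] for marker ",
         map$marker[which(rowSums(bad, na.rm = TRUE) > 0)[1]])
  if (is.null(gtype)) {
    gtype <- matrix("NC", nrow(lrr), ncol(lrr), dimnames = dimnames(lrr))
  } else {
    gtype <- as.matrix(gtype)
    if (!identical(dim(gtype), dim(lrr)))
      stop("gtype must match the signal matrices in shape")
    gtype[is.na(gtype)] <- "NC"
    if (!all(gtype %in% c("AA", "AB", "BB", "NC")))
      stop("genotypes must be AA/AB/BB/NC")
    dimnames(gtype) <- dimnames(lrr)
  }
  structure(list(map = map, lrr = lrr, baf = baf, gtype = gtype,
                 samples = colnames(lrr)),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("signal_set:", nrow(x$map), "markers x", length(x$samples), "samples\n")
  invisible(x)
}

#' Read a final-report-style signal table
#'
#' Parses a tab-delimited table with columns `Name`, `Chr`, `Position` and,
#' per sample, `<id>.Log R Ratio`, `<id>.B Allele Freq` and (optionally)
#' `<id>.GType`. Rows are re-aligned to the marker map's genome order;
#' markers present in the map but absent from the file get missing signals.
#'
#' @param path file to read.
#' @param map the [marker_map()] the signals belong to. Unknown marker ids
#'   in the file are an error.
#' @return a [signal_set()].
#' @export
read_signal_table <- function(path, map) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("Name", "Chr", "Position")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns Name, Chr, Position")
  unknown <- setdiff(tab$Name, map$marker)
  if (length(unknown) > 0)
    stop("signal table names a marker absent from the map: ", unknown[1])
  lrr_cols <- grep("\\.Log R Ratio$", names(tab), value = TRUE)
  samples <- sub("\\.Log R Ratio$", "", lrr_cols)
  if (length(samples) == 0) stop("no '<id>.Log R Ratio' columns found")
  baf_cols <- paste0(samples, ".B Allele Freq")
  if (!all(baf_cols %in% names(tab)))
    stop("missing B Allele Freq column for sample ",
         samples[which(!(baf_cols %in% names(tab)))[1]])
  gt_cols <- paste0(samples, ".GType")
  have_gt <- all(gt_cols %in% names(tab))

  idx <- match(map$marker, tab$Name)      # NA rows -> all-missing marker
  num_col <- function(col) {
    raw <- tab[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(v))
    if (length(bad) > 0)
      stop("non-numeric value '", raw[bad[1]], "' in column '", col,
           "' at line ", bad[1] + 1L)
    v[raw == ""] <- NA_real_
    v
  }
  lrr <- sapply(lrr_cols, num_col)[idx, , drop = FALSE]
  baf <- sapply(baf_cols, num_col)[idx, , drop = FALSE]
  colnames(lrr) <- colnames(baf) <- samples
  gtype <- NULL
  if (have_gt) {
    gtype <- as.matrix(tab[, gt_cols, drop = FALSE])[idx, , drop = FALSE]
    colnames(gtype) <- samples
  }
  signal_set(map, lrr, baf, gtype)
}

#' Write a signal set as a final-report-style table
#'
#' Inverse of [read_signal_table()]; values are written with enough digits
#' that a round trip reproduces them to at least six decimals.
#'
#' @param sig a [signal_set()].
#' @param path output file.
#' @export
write_signal_table <- function(sig, path) {
  out <- data.frame(Name = sig$map$marker, Chr = sig$map$chr,
                    Position = sig$map$pos, check.names = FALSE)
  for (s in sig$samples) {
    out[[paste0(s, ".Log R Ratio")]] <- format_num(sig$lrr[, s])
    out[[paste0(s, ".B Allele Freq")]] <- format_num(sig$baf[, s])
    out[[paste0(s, ".GType")]] <- sig$gtype[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Read or write a PFB table
#'
#' Four tab-separated columns: `Name`, `Chr`, `Position`, `PFB`.
#'
#' @param path file to read or write.
#' @return `read_pfb` returns a [marker_map()].
#' @export
read_pfb <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  need <- c("Name", "Chr", "Position", "PFB")
  if (!all(need %in% names(tab))) stop("PFB file must have columns ",
                                       paste(need, collapse = ", "))
  marker_map(tab$Name, tab$Chr, tab$Position, tab$PFB)
}

#' @rdname read_pfb
#' @param map a `marker_map` with PFB filled in.
#' @export
write_pfb <- function(map, path) {
  out <- data.frame(Name = map$marker, Chr = map$chr, Position = map$pos,
                    PFB = sprintf("%.6f", map$pfb))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PennCNV-dialect CNV calls ("rawcnv")
#'
#' Each non-empty line looks like
#' `chr2:100-300 numsnp=4 length=201 state2,cn=1 sample1 startsnp=rs1 endsnp=rs4`.
#' The copy number is taken from `cn=`; the call state is `loss` for cn < 2
#' and `gain` for cn > 2 (cn = 2 is not a CNV and is rejected). If the
#' `length=` field disagrees with `end - start + 1` a warning is emitted
#' and the coordinates are trusted.
#'
#' @param path file to read.
#' @return a data.frame of calls with columns `sample`, `chr`, `start`,
#'   `end`, `cn`, `state`, `numsnp`.
#' @export
read_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pat <- paste0("^chr(\\S+):(\\d+)-(\\d+)\\s+numsnp=(\\d+)\\s+",
                "length=([0-9,]+)\\s+state\\d+,cn=(\\d)\\s+(\\S+)")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(lengths(m) == 0)
  if (length(bad) > 0)
    stop("malformed rawcnv line ", bad[1], ": ", lines[bad[1]])
  fields <- do.call(rbind, m)
  calls <- data.frame(
    sample = fields[, 8],
    chr = norm_chr(fields[, 2]),
    start = as.numeric(fields[, 3]),
    end = as.numeric(fields[, 4]),
    cn = as.integer(fields[, 7]),
    numsnp = as.integer(fields[, 5]),
    stringsAsFactors = FALSE)
  len <- as.numeric(gsub(",", "", fields[, 6]))
  mismatch <- which(len != calls$end - calls$start + 1)
  if (length(mismatch) > 0)
    warning("length field disagrees with coordinates on ",
            length(mismatch), " line(s); trusting coordinates")
  if (any(calls$cn == 2))
    stop("rawcnv line with cn=2: a CNV call must deviate from diploid")
  calls$state <- ifelse(calls$cn < 2, "loss", "gain")
  calls[, c("sample", "chr", "start", "end", "cn", "state", "numsnp")]
}

#' @rdname read_rawcnv
#' @param calls a CNV-call data.frame as returned by [read_rawcnv()] or
#'   [call_cnvs()].
#' @export
write_rawcnv <- function(calls, path) {
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s",
                   calls$chr, as.integer(calls$start), as.integer(calls$end),
                   as.integer(calls$numsnp),
                   as.integer(calls$end - calls$start + 1),
                   state_code(calls$cn), as.integer(calls$cn), calls$sample)
  writeLines(lines, path)
  invisible(path)
}

# PennCNV state labels for copy numbers 0..4 (state 3/4 = diploid, unused)
state_code <- function(cn) c(1L, 2L, 3L, 5L, 6L)[cn + 1L]

#' Read a BED-like feature file
#'
#' BED uses 0-based half-open coordinates; on read they are converted to
#' the package's 1-based inclusive convention (`start + 1`, `end`), an
#' exact bijection reversed by [write_bed_like()]. Column 4, when present,
#' is the feature id.
#'
#' @param path file to read.
#' @param category category label attached to every record (e.g. "gene").
#' @return a data.frame of interval records (see [interval_records()]).
#' @export
read_bed_like <- function(path, category = NA_character_) {
  tab <- tryCatch(read.delim(path, header = FALSE, colClasses = "character"),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0)
    return(interval_records(character(), numeric(), numeric()))
  start <- as.numeric(tab[[2]]) + 1
  end <- as.numeric(tab[[3]])
  if (any(start > end))
    stop("BED record with start >= end after conversion (zero-width interval)")
  id <- if (ncol(tab) >= 4) tab[[4]] else paste0("iv", seq_len(nrow(tab)))
  interval_records(tab[[1]], start, end, id, category)
}

#' @rdname read_bed_like
#' @param records interval records to write (1-based inclusive; converted
#'   back to BED's 0-based half-open convention).
#' @export
write_bed_like <- function(records, path) {
  out <- data.frame(records$chr, as.integer(records$start - 1),
                    as.integer(records$end), records$id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a study CNVR table
#'
#' Tab-delimited with header `study`, `chr`, `start`, `end`, `state`
#' (1-based inclusive coordinates). An empty file yields an empty table.
#'
#' @param path file to read or write.
#' @return a data.frame sorted by chromosome and start, with the columns
#'   above.
#' @export
read_study_table <- function(path) {
  empty <- data.frame(study = character(), chr = character(),
                      start = numeric(), end = numeric(),
                      state = character(), stringsAsFactors = FALSE)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) return(empty)
  tab <- read.delim(path, colClasses = "character")
  if (nrow(tab) == 0) return(empty)
  need <- c("study", "chr", "start", "end")
  if (!all(need %in% names(tab)))
    stop("study table must have columns study, chr, start, end")
  df <- data.frame(study = tab$study, chr = norm_chr(tab$chr),
                   start = as.numeric(tab$start), end = as.numeric(tab$end),
                   state = if ("state" %in% names(tab)) tab$state else NA_character_,
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("study table record with start > end")
  df <- df[order_chr(df$chr, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_study_table
#' @param tab a study table data.frame.
#' @export
write_study_table <- function(tab, path) {
  out <- tab[, c("study", "chr", "start", "end", "state")]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
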