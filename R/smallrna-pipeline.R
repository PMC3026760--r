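#' Parse a 4-line FASTQ file
#'
#' Strict parser for 4-line FASTQ records. Truncated records and malformed
#' headers raise errors that name the offending line.
#'
#' @param path FASTQ file (plain or gzip; `.gz` is detected by extension).
#' @return data.frame with columns `id`, `sequence`, `quality`; quality
#'   strings are carried but unused downstream.
#' @export
readFastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record at line ", (n %/% 4L) * 4L + 1L,
         ": file has ", n, " lines (not a multiple of 4)")
  if (n == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ header at line ", (bad[1L] - 1L) * 4L + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ separator at line ", (bad[1L] - 1L) * 4L + 3L)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("sequence/quality length mismatch in record starting at line ",
         (bad[1L] - 1L) * 4L + 1L)
  data.frame(id = sub("^@", "", hdr), sequence = toupper(seqs),
             quality = qual, stringsAsFactors = FALSE)
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path (gzipped when ending in `.gz`).
#' @export
writeFastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con, sep = "\n")
  invisible(path)
}

#' Demultiplex reads by exact 4-nt barcode prefix
#'
#' Reads containing any missing base (N) anywhere, and reads whose first four
#' bases match none of the expected barcodes, are excluded.
#'
#' @param reads data.frame from [readFastq()].
#' @param barcodes character vector of distinct 4-nt barcodes.
#' @return list with `reads` (retained reads with a `barcode` column) and
#'   `tally` (named counts: `parsed`, `assigned`, `excluded_N`,
#'   `excluded_barcode`).
#' @export
demultiplexReads <- function(reads, barcodes) {
  if (length(barcodes) == 0L) stop("barcodes must be non-empty")
  if (any(nchar(barcodes) != 4L)) stop("all barcodes must be 4 nt")
  if (anyDuplicated(barcodes)) stop("barcodes must be pairwise distinct")
  hasN <- grepl("N", reads$sequence, fixed = TRUE)
  prefix <- substr(reads$sequence, 1L, 4L)
  matched <- prefix %in% barcodes & !hasN
  tally <- c(parsed = nrow(reads), assigned = sum(matched),
             excluded_N = sum(hasN),
             excluded_barcode = sum(!hasN & !prefix %in% barcodes))
  kept <- reads[matched, , drop = FALSE]
  kept$barcode <- prefix[matched]
  rownames(kept) <- NULL
  list(reads = kept, tally = tally)
}

#' Trim the barcode and 3' A-tail from read sequences
#'
#' Removes the first four nucleotides (the barcode) and then the maximal run
#' of trailing A's. The A rule is unconditional, so genuine terminal A's of an
#' insert are removed too — a known bias of this trimming scheme. May return
#' empty strings.
#'
#' @param x character vector of read sequences (length >= 4 each).
#' @return character vector of insert sequences.
#' @examples
#' trimInsert("ACGTGGCCTTGGCCAAA")  # "GGCCTTGGCC"
#' @export
trimInsert <- function(x) {
  if (any(nchar(x) < 4L)) stop("reads shorter than 4 nt cannot be trimmed")
  sub("A*$", "", substring(x, 5L))
}

#' Collapse inserts to unique sequences and filter by length
#'
#' Inserts outside `[minLen, maxLen]` (inclusive) are dropped; identical
#' (barcode, sequence) pairs are merged with summed read counts. Output order
#' is deterministic: barcode, then sequence, lexicographically.
#'
#' @param inserts data.frame with columns `sequence` and `barcode`.
#' @param minLen,maxLen inclusive insert length bounds (defaults 18 and 30,
#'   the selected small-RNA size range).
#' @param pool merge all barcodes into one library before collapsing.
#' @return data.frame with `barcode`, `sequence`, `length`, `read_count`.
#' @export
collapseAndFilter <- function(inserts, minLen = 18L, maxLen = 30L,
                              pool = FALSE) {
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  len <- nchar(inserts$sequence)
  keep <- len >= minLen & len <= maxLen
  x <- inserts[keep, , drop = FALSE]
  if (pool) x$barcode <- "pooled"
  if (nrow(x) == 0L)
    return(data.frame(barcode = character(0), sequence = character(0),
                      length = integer(0), read_count = integer(0),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(read_count = rep(1L, nrow(x))),
                          by = list(barcode = x$barcode,
                                    sequence = x$sequence), FUN = sum)
  agg <- agg[order(agg$barcode, agg$sequence), , drop = FALSE]
  rownames(agg) <- NULL
  data.frame(barcode = agg$barcode, sequence = agg$sequence,
             length = nchar(agg$sequence), read_count = agg$read_count,
             stringsAsFactors = FALSE)
}

#' Run the complete small-RNA preprocessing pipeline on a FASTQ file
#'
#' Parses, demultiplexes (exact 4-nt barcode, N exclusion), trims the barcode
#' and 3' A-tails, collapses to unique inserts per barcode and filters to the
#' selected size range. Filtering happens after trimming, in pipeline order.
#'
#' @param path FASTQ file.
#' @param barcodes expected 4-nt barcodes.
#' @param minLen,maxLen inclusive length bounds after trimming.
#' @param pool collapse across barcodes.
#' @return list with `collapsed` (see [collapseAndFilter()]) and `tally`
#'   (read-conservation counts, including `in_range`/`out_of_range`).
#' @export
processSmallRnaFastq <- function(path, barcodes, minLen = 18L, maxLen = 30L,
                                 pool = FALSE) {
  reads <- readFastq(path)
  dm <- demultiplexReads(reads, barcodes)
  inserts <- data.frame(
    sequence = trimInsert(dm$reads$sequence),
    barcode = dm$reads$barcode, stringsAsFactors = FALSE)
  len <- nchar(inserts$sequence)
  collapsed <- collapseAndFilter(inserts, minLen, maxLen, pool = pool)
  tally <- c(dm$tally,
             in_range = sum(len >= minLen & len <= maxLen),
             out_of_range = sum(len < minLen | len > maxLen))
  list(collapsed = collapsed, tally = tally)
}

#' Write / read a collapsed unique-insert table (TSV)
#'
#' @param collapsed data.frame from [collapseAndFilter()].
#' @param path TSV path.
#' @export
writeCollapsedTsv <- function(collapsed, path) {
  utils::write.table(collapsed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCollapsedTsv
#' @export
readCollapsedTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
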