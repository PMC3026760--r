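## Encode the first k bases of each query as a base-4 integer code.
## k <= 15 keeps codes below 2^31.
.kmerCode <- function(x, k) {
  strtoi(chartr("ACGT", "0123", substr(x, 1L, k)), base = 4L)
}

#' Build an exact-substring index over a reference union
#'
#' Indexes every plus-strand k-mer start of every record; queries are seeded
#' by their first k-mer and verified by full string comparison, so reported
#' matches are exact. Reverse-strand occurrences are found by looking up the
#' reverse complement of the query (see [findExactMatches()]).
#'
#' @param refs a [ReferenceSet-class].
#' @param k seed length (default 12, below the minimum insert length so
#'   every insert is seedable).
#' @return a [KmerIndex-class].
#' @export
buildReferenceIndex <- function(refs, k = 12L) {
  stopifnot(methods::is(refs, "ReferenceSet"))
  methods::validObject(refs)
  k <- as.integer(k)
  if (k < 1L || k > 15L) stop("k must be between 1 and 15")
  chars <- as.character(refs@seqs)
  lens <- nchar(chars)
  codes <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    m <- lens[i] - k + 1L
    if (m < 1L) { codes[[i]] <- integer(0); next }
    starts <- seq_len(m)
    codes[[i]] <- .kmerCode(substring(chars[i], starts, starts + k - 1L), k)
  }
  rec <- rep.int(seq_along(chars), lengths(codes))
  pos <- unlist(lapply(codes, function(x) seq_along(x) - 1L),
                use.names = FALSE)
  if (is.null(pos)) pos <- integer(0)
  cd <- unlist(codes, use.names = FALSE)
  if (is.null(cd)) cd <- integer(0)
  o <- order(cd, rec, pos)
  new("KmerIndex", refs = refs, k = k, codes = as.numeric(cd[o]),
      rec = rec[o], pos = pos[o])
}

## Seed-and-verify lookup of full queries on the plus strand of all records.
## Returns data.frame(qi, rec, pos) with 0-based positions.
.lookupBatch <- function(queries, index, refChars, refLens) {
  k <- index@k
  code <- .kmerCode(queries, k)
  lo <- findInterval(code - 0.5, index@codes) + 1L
  hi <- findInterval(code + 0.5, index@codes)
  nc <- pmax(hi - lo + 1L, 0L)
  if (sum(nc) == 0L)
    return(data.frame(qi = integer(0), rec = integer(0), pos = integer(0)))
  qi <- rep.int(seq_along(queries), nc)
  ci <- sequence(nc) + rep.int(lo - 1L, nc)
  rec <- index@rec[ci]
  pos <- index@pos[ci]
  qlen <- nchar(queries)[qi]
  ok <- pos + qlen <= refLens[rec]
  qi <- qi[ok]; rec <- rec[ok]; pos <- pos[ok]; qlen <- qlen[ok]
  eq <- substring(refChars[rec], pos + 1L, pos + qlen) == queries[qi]
  data.frame(qi = qi[eq], rec = rec[eq], pos = pos[eq])
}

#' Find all exact occurrences of a query on both strands
#'
#' Reports every occurrence of `query` on the plus strand of every record,
#' and every occurrence of its reverse complement (as minus-strand hits, with
#' the position of the occurrence on the plus strand). Order is
#' deterministic: record, then strand (+ before -), then position.
#'
#' @param query ACGT string of length >= k (N raises an alphabet error).
#' @param index a [KmerIndex-class].
#' @return data.frame with `reference_id`, `position` (0-based plus-strand
#'   start), `strand`.
#' @export
findExactMatches <- function(query, index) {
  query <- normalizeNt(query)
  if (nchar(query) < index@k)
    stop("query shorter than seed length k = ", index@k)
  refChars <- as.character(index@refs@seqs)
  refLens <- nchar(refChars)
  fwd <- .lookupBatch(query, index, refChars, refLens)
  rev <- .lookupBatch(revComp(query), index, refChars, refLens)
  df <- rbind(data.frame(rec = fwd$rec, pos = fwd$pos,
                         strand = rep("+", nrow(fwd))),
              data.frame(rec = rev$rec, pos = rev$pos,
                         strand = rep("-", nrow(rev))))
  df <- df[order(df$rec, df$strand == "-", df$pos), , drop = FALSE]
  data.frame(reference_id = names(index@refs@seqs)[df$rec],
             position = df$pos, strand = df$strand,
             stringsAsFactors = FALSE)
}

#' Classify unique inserts by exact unambiguous mapping
#'
#' Applies the perfect-and-unambiguous rule: an insert is assigned to the
#' virus (sense or antisense by hit strand) or to the host only when it has
#' exactly one exact hit — one (record, position, strand) — in the entire
#' host+virus union. Two or more hits anywhere (including a host hit next to
#' a viral one, two host hits, or a palindromic self-hit) make it
#' `ambiguous`; no hit makes it `unmapped`. Any host co-hit therefore removes
#' a sequence from the viral profiles.
#'
#' @param collapsed data.frame with at least `sequence` (and typically
#'   `barcode`, `read_count`) from [collapseAndFilter()].
#' @param index a [KmerIndex-class] over the host+virus union.
#' @return the input data.frame with added columns `category` (one of
#'   `virus_sense`, `virus_antisense`, `host`, `ambiguous`, `unmapped`),
#'   `reference_id`, `position` (0-based), `strand` (hit fields NA unless
#'   uniquely mapped).
#' @export
classifySequences <- function(collapsed, index) {
  qs <- collapsed$sequence
  refChars <- as.character(index@refs@seqs)
  refLens <- nchar(refChars)
  fwd <- .lookupBatch(qs, index, refChars, refLens)
  rev <- .lookupBatch(revComp(qs), index, refChars, refLens)
  n <- length(qs)
  nhits <- tabulate(fwd$qi, n) + tabulate(rev$qi, n)
  category <- rep("unmapped", n)
  refId <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  single <- which(nhits == 1L)
  category[nhits >= 2L] <- "ambiguous"
  if (length(single)) {
    sf <- fwd[fwd$qi %in% single, , drop = FALSE]
    sr <- rev[rev$qi %in% single, , drop = FALSE]
    one <- rbind(data.frame(sf, strand = rep("+", nrow(sf))),
                 data.frame(sr, strand = rep("-", nrow(sr))))
    cls <- index@refs@refClass[one$rec]
    category[one$qi] <- ifelse(cls == "host", "host",
                               ifelse(one$strand == "+", "virus_sense",
                                      "virus_antisense"))
    refId[one$qi] <- names(index@refs@seqs)[one$rec]
    position[one$qi] <- one$pos
    strand[one$qi] <- one$strand
  }
  out <- collapsed
  out$category <- category
  out$reference_id <- refId
  out$position <- position
  out$strand <- strand
  out
}

#' Tally mapping categories
#'
#' @param mapped data.frame from [classifySequences()].
#' @return named integer vector over the five categories.
#' @export
categoryTally <- function(mapped) {
  lv <- c("virus_sense", "virus_antisense", "host", "ambiguous", "unmapped")
  table(factor(mapped$category, levels = lv))
}
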