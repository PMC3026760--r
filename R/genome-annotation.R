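#' Translate a nucleotide sequence with the standard genetic code
#'
#' Codon-by-codon translation using the standard code (table 1); stop codons
#' yield `*`.
#'
#' @param nt nucleotide string (U normalized to T).
#' @param requireTriplet error on non-triplet length (default); otherwise any
#'   trailing partial codon is ignored.
#' @return amino-acid string, one residue per codon.
#' @examples
#' translateCodons("ATGTAA")  # "M*"
#' @export
translateCodons <- function(nt, requireTriplet = TRUE) {
  nt <- normalizeNt(nt)
  if (requireTriplet && nchar(nt) %% 3L != 0L)
    stop("sequence length ", nchar(nt), " is not a multiple of 3")
  cods <- codonsFrom(nt, 0L)
  if (length(cods) == 0L) return("")
  paste(Biostrings::GENETIC_CODE[cods], collapse = "")
}

## ORF scan of one reading strand; returns 0-based half-open coordinates on
## the scanned strand. Maximal = 5'-most ATG per stop codon.
.scanStrandOrfs <- function(seq, minAa, allowPartial) {
  L <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    cods <- codonsFrom(seq, f)
    nc <- length(cods)
    if (nc == 0L) next
    atg <- which(cods == "ATG")
    if (length(atg) == 0L) next
    stp <- which(cods %in% STOP_CODONS)
    # index in stp of the first stop at/after each ATG
    si <- findInterval(atg - 0.5, stp) + 1L
    complete <- si <= length(stp)
    if (any(complete)) {
      s <- stp[si[complete]]
      a <- atg[complete]
      # keep the 5'-most ATG per stop
      keep <- !duplicated(s)
      a <- a[keep]; s <- s[keep]
      aa <- s - a
      sel <- aa >= minAa
      if (any(sel)) {
        a <- a[sel]; s <- s[sel]; aa <- aa[sel]
        prot <- vapply(seq_along(a), function(i)
          paste(Biostrings::GENETIC_CODE[cods[a[i]:(s[i] - 1L)]],
                collapse = ""), "")
        out[[length(out) + 1L]] <- data.frame(
          start = f + 3L * (a - 1L), end = f + 3L * s, frame = f,
          aaLength = aa, protein = prot, partial3p = FALSE)
      }
    }
    if (allowPartial && any(!complete)) {
      a <- min(atg[!complete])
      aa <- nc - a + 1L
      if (aa >= minAa)
        out[[length(out) + 1L]] <- data.frame(
          start = f + 3L * (a - 1L), end = f + 3L * nc, frame = f,
          aaLength = aa,
          protein = paste(Biostrings::GENETIC_CODE[cods[a:nc]], collapse = ""),
          partial3p = TRUE)
    }
  }
  if (length(out) == 0L)
    data.frame(start = integer(0), end = integer(0), frame = integer(0),
               aaLength = integer(0), protein = character(0),
               partial3p = logical(0))
  else do.call(rbind, out)
}

#' Scan open reading frames of a viral segment
#'
#' An ORF is an ATG-initiated, stop-terminated codon run; for each in-frame
#' stop the 5'-most compatible ATG is reported (maximal ORF). Coordinates are
#' returned as a `GRanges` (1-based, closed, on the plus strand); the range of
#' a complete call includes its stop codon. `aaLength` excludes the stop and
#' the stored protein starts with M for complete calls.
#'
#' @param segment a [ViralSegment-class].
#' @param minAa minimum product length in amino acids (default 50, which
#'   suppresses spurious micro-ORFs while retaining all real products).
#' @param allowPartial also report ATG-initiated runs reaching the segment end
#'   with no stop (flagged `partial3p`).
#' @param bothStrands scan the reverse complement too; minus-strand calls are
#'   reported in plus-strand coordinates with strand `-`, and their `frame` is
#'   the reading-strand frame (offset on the reverse complement).
#' @return `GRanges` sorted by start with metadata columns `frame`,
#'   `aaLength`, `protein`, `partial3p`.
#' @examples
#' scanOrfs(ViralSegment("s", "ATGAAATAG"), minAa = 1)
#' @export
scanOrfs <- function(segment, minAa = 50, allowPartial = FALSE,
                     bothStrands = TRUE) {
  stopifnot(methods::is(segment, "ViralSegment"))
  if (minAa < 0) stop("minAa must be >= 0")
  seq <- segmentSeq(segment)
  L <- nchar(seq)
  fwd <- .scanStrandOrfs(seq, minAa, allowPartial)
  fwd$strand <- if (nrow(fwd)) "+" else character(0)
  if (bothStrands) {
    rev <- .scanStrandOrfs(revComp(seq), minAa, allowPartial)
    if (nrow(rev)) {
      tmp <- rev$start
      rev$start <- L - rev$end
      rev$end <- L - tmp
      rev$strand <- "-"
      fwd <- rbind(fwd, rev)
    }
  }
  o <- order(fwd$start, fwd$end, fwd$strand)
  fwd <- fwd[o, , drop = FALSE]
  sl <- stats::setNames(L, segmentId(segment))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(segmentId(segment), nrow(fwd)),
    ranges = IRanges::IRanges(start = fwd$start + 1L, end = fwd$end),
    strand = if (nrow(fwd)) fwd$strand else character(0),
    seqlengths = sl)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    frame = fwd$frame, aaLength = fwd$aaLength, protein = fwd$protein,
    partial3p = fwd$partial3p)
  gr
}

## longest call of a GRanges of ORFs (ties -> 5'-most); empty GRanges if none
.longestOrf <- function(gr) {
  if (length(gr) == 0L) return(gr)
  aa <- S4Vectors::mcols(gr)$aaLength
  gr[order(-aa, GenomicRanges::start(gr))][1L]
}

.emptyLike <- function(gr) gr[0L]

#' Find an overlapping +1-frame ORF at the C-terminus of an anchor ORF
#'
#' Nodavirus B2 RNAi-suppressor ORFs overlap the C-terminal portion of the
#' RNA-dependent RNA polymerase ORF and are read in the +1 frame relative to
#' it. This returns the longest plus-strand ORF in frame
#' `(anchor frame + 1) mod 3` whose span intersects the final `ctermWindow`
#' nucleotides of the anchor, or an empty `GRanges` when none qualifies.
#'
#' @param orfs `GRanges` from [scanOrfs()] for the anchor's segment.
#' @param anchor single plus-strand ORF (`GRanges` of length 1) in `orfs`
#'   coordinates, typically the polymerase candidate.
#' @param minAa minimum candidate length in amino acids.
#' @param ctermWindow size in nt of the anchor C-terminal window (default
#'   300; the overlap region is not standardized, so this is configurable).
#' @return `GRanges` with zero or one row.
#' @export
findOverlappingPlus1Orf <- function(orfs, anchor, minAa = 50,
                                    ctermWindow = 300) {
  stopifnot(length(anchor) == 1L)
  if (as.character(GenomicRanges::strand(anchor)) != "+")
    stop("anchor must be a plus-strand ORF")
  if (ctermWindow > GenomicRanges::width(anchor))
    stop("ctermWindow exceeds anchor length")
  if (!as.character(GenomicRanges::seqnames(anchor)) %in%
      as.character(GenomicRanges::seqnames(orfs)) &&
      length(orfs) > 0L)
    stop("anchor does not belong to the scanned segment")
  aEnd <- GenomicRanges::end(anchor)
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(anchor),
    ranges = IRanges::IRanges(start = aEnd - ctermWindow + 1L, end = aEnd))
  targetFrame <- (S4Vectors::mcols(anchor)$frame + 1L) %% 3L
  cand <- orfs[as.logical(GenomicRanges::strand(orfs) == "+") &
               S4Vectors::mcols(orfs)$frame == targetFrame &
               S4Vectors::mcols(orfs)$aaLength >= minAa]
  # drop the anchor itself if it sneaks in (frame differs, but be safe)
  same <- GenomicRanges::start(cand) == GenomicRanges::start(anchor) &
    GenomicRanges::end(cand) == GenomicRanges::end(anchor)
  cand <- cand[!same]
  hit <- IRanges::overlapsAny(cand, win, ignore.strand = TRUE)
  .longestOrf(cand[hit])
}

#' Classify the genome organization of a segment pair
#'
#' Annotates a 1- or 2-segment genome against the bipartite nodavirus
#' convention: RNA1 (~3.1 kb) carries the RNA-dependent RNA polymerase ORF,
#' possibly with a B2-like +1-frame overlap at its C-terminus; RNA2 (~1.4 kb)
#' carries a single 5' capsid ORF. Deviations flagged here — an additional
#' 3' ORF on RNA2 ("ORF delta") and an oversized RNA2 — are the organization
#' hallmarks of the Orsay/Santeuil nematode viruses.
#'
#' Role assignment: with two segments, the segment carrying the longest
#' plus-strand ORF becomes RNA1 (tie broken by segment length); pre-assigned
#' non-`unknown` roles on both segments are respected.
#'
#' @param segments list of 1-2 [ViralSegment-class] objects.
#' @param minAa ORF length cutoff in amino acids.
#' @param rna2ConventionLength conventional RNA2 length in nt (1400).
#' @param oversizeMargin RNA2 is flagged oversize when its length exceeds
#'   `rna2ConventionLength` by at least this margin (default 500 nt).
#' @param ctermWindow B2 search window, see [findOverlappingPlus1Orf()].
#' @param allowPartial passed to [scanOrfs()].
#' @return an [OrganizationReport-class].
#' @export
classifyOrganization <- function(segments, minAa = 50,
                                 rna2ConventionLength = 1400,
                                 oversizeMargin = 500, ctermWindow = 300,
                                 allowPartial = FALSE) {
  if (methods::is(segments, "ViralSegment")) segments <- list(segments)
  if (length(segments) < 1L || length(segments) > 2L)
    stop("expected 1 or 2 segments, got ", length(segments))
  orfsBySeg <- lapply(segments, scanOrfs, minAa = minAa,
                      allowPartial = allowPartial, bothStrands = TRUE)
  plusLongest <- lapply(orfsBySeg, function(gr)
    .longestOrf(gr[as.logical(GenomicRanges::strand(gr) == "+")]))
  ids <- vapply(segments, segmentId, "")
  lens <- vapply(segments, function(s) nchar(segmentSeq(s)), 0L)

  roles <- vapply(segments, segmentRole, "")
  if (length(segments) == 2L && any(roles == "unknown")) {
    aa <- vapply(plusLongest, function(g)
      if (length(g)) S4Vectors::mcols(g)$aaLength else -1L, 0L)
    rna1 <- order(-aa, -lens)[1L]
    roles <- c("RNA2", "RNA2")
    roles[rna1] <- "RNA1"
  }
  names(roles) <- ids
  segments <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]; s@role <- roles[[i]]; s
  })

  allOrfs <- suppressWarnings(do.call(c, orfsBySeg))
  empty <- .emptyLike(allOrfs)
  if (length(allOrfs) == 0L)
    warning("no ORF of >= ", minAa, " aa on any segment")

  rdrp <- b2 <- capsid <- delta <- empty
  oversize <- FALSE
  i1 <- which(roles == "RNA1")[1L]
  i2 <- which(roles == "RNA2")[1L]
  if (!is.na(i1) && length(plusLongest[[i1]])) {
    rdrp <- plusLongest[[i1]]
    b2 <- findOverlappingPlus1Orf(orfsBySeg[[i1]], rdrp, minAa = minAa,
                                  ctermWindow = min(ctermWindow,
                                    GenomicRanges::width(rdrp)))
  }
  if (!is.na(i2)) {
    L2 <- lens[i2]
    gr2 <- orfsBySeg[[i2]]
    plus2 <- gr2[as.logical(GenomicRanges::strand(gr2) == "+")]
    capsid <- .longestOrf(plus2[GenomicRanges::start(plus2) <= L2 / 2])
    if (length(capsid)) {
      after <- plus2[GenomicRanges::start(plus2) >
                       GenomicRanges::start(capsid)]
      delta <- .longestOrf(after)
    }
    oversize <- (L2 - rna2ConventionLength) >= oversizeMargin
  }
  new("OrganizationReport", segments = segments, roles = roles,
      orfs = allOrfs, rdrpCandidate = rdrp, b2Like = b2,
      capsidCandidate = capsid, orfDeltaCandidate = delta,
      rna2Oversize = oversize)
}

#' Tabulate ORF calls for text reports
#'
#' @param orfs `GRanges` from [scanOrfs()] or an [OrganizationReport-class].
#' @return data.frame with 1-based closed coordinates.
#' @export
orfTable <- function(orfs) {
  if (methods::is(orfs, "OrganizationReport")) orfs <- orfs@orfs
  df <- as.data.frame(orfs)
  data.frame(segment = as.character(df$seqnames), start = df$start,
             end = df$end, strand = as.character(df$strand),
             frame = df$frame, aa_length = df$aaLength,
             partial_3prime = df$partial3p, protein = df$protein,
             stringsAsFactors = FALSE)
}

#' Read viral segments from a (multi-)FASTA file
#'
#' @param path FASTA file; sequences may use U or lowercase, normalized on
#'   read; records become [ViralSegment-class] objects with role `"unknown"`.
#' @return list of [ViralSegment-class].
#' @export
readFastaSegments <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i)
    ViralSegment(ids[i], as.character(ss[[i]])))
}

#' Write viral segments to FASTA (60-column wrap)
#'
#' @param segments list of [ViralSegment-class].
#' @param path output file.
#' @export
writeFastaSegments <- function(segments, path) {
  ss <- Biostrings::DNAStringSet(vapply(segments, segmentSeq, ""))
  names(ss) <- vapply(segments, segmentId, "")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read the sequence of a GenBank flat file (sequence-only import)
#'
#' Minimal ORIGIN-block parser: extracts the LOCUS name and the nucleotide
#' sequence; all feature annotation is ignored.
#'
#' @param path GenBank flat file with one record.
#' @return a [ViralSegment-class] with role `"unknown"`.
#' @export
readGenbankSeq <- function(path) {
  lines <- readLines(path)
  loc <- grep("^LOCUS", lines, value = TRUE)
  if (length(loc) == 0L) stop("not a GenBank flat file: no LOCUS line")
  id <- strsplit(trimws(sub("^LOCUS", "", loc[1L])), "\\s+")[[1L]][1L]
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("no ORIGIN block in ", path)
  ei <- grep("^//", lines)
  ei <- ei[ei > oi[1L]][1L]
  if (is.na(ei)) ei <- length(lines) + 1L
  body <- lines[(oi[1L] + 1L):(ei - 1L)]
  seq <- gsub("[0-9 ]", "", paste(body, collapse = ""))
  ViralSegment(id, seq)
}
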