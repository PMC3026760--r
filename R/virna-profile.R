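#' Per-position sense/antisense profile of a viral segment
#'
#' Counts, at each reference position of one segment, the number of unique
#' virus-assigned sequences covering that position (default) or starting
#' there (5'-end mode), separately by orientation. The counting unit is
#' unique sequences, not reads.
#'
#' @param mapped data.frame from [classifySequences()].
#' @param segment the [ViralSegment-class] being profiled (or its id plus
#'   `segmentLength`).
#' @param mode `"coverage"`: every covered position is incremented;
#'   `"end5"`: only the 5'-most position of the hit range.
#' @param segmentLength required when `segment` is given as an id string.
#' @return a [VirnaProfile-class].
#' @export
positionProfile <- function(mapped, segment, mode = c("coverage", "end5"),
                            segmentLength = NULL) {
  mode <- match.arg(mode)
  if (methods::is(segment, "ViralSegment")) {
    segId <- segmentId(segment)
    L <- nchar(segmentSeq(segment))
  } else {
    segId <- as.character(segment)
    if (is.null(segmentLength)) stop("segmentLength required with an id")
    L <- as.integer(segmentLength)
  }
  m <- mapped[!is.na(mapped$reference_id) & mapped$reference_id == segId &
                mapped$category %in% c("virus_sense", "virus_antisense"), ,
              drop = FALSE]
  counts <- list(sense = integer(L), antisense = integer(L))
  for (orient in c("sense", "antisense")) {
    cat <- paste0("virus_", orient)
    mm <- m[m$category == cat, , drop = FALSE]
    if (nrow(mm) == 0L) next
    s <- mm$position + 1L                      # 1-based start
    e <- mm$position + nchar(mm$sequence)      # 1-based inclusive end
    if (any(s < 1L) || any(e > L))
      stop("hit outside segment bounds on ", segId)
    if (mode == "end5") {
      at <- ifelse(mm$strand == "-", e, s)     # 5' end of the small RNA
      counts[[orient]] <- tabulate(at, L)
    } else {
      d <- integer(L + 1L)
      add <- tabulate(s, L)
      sub <- tabulate(e + 1L, L + 1L)
      d[seq_len(L)] <- add
      d <- d - sub
      counts[[orient]] <- as.integer(cumsum(d[seq_len(L)]))
    }
  }
  new("VirnaProfile", segmentId = segId, sense = counts$sense,
      antisense = counts$antisense)
}

#' Tabulate a profile for TSV export
#'
#' @param profile a [VirnaProfile-class].
#' @return data.frame with `segment`, `position` (1-based), `sense`,
#'   `antisense`.
#' @export
profileTable <- function(profile) {
  data.frame(segment = profile@segmentId,
             position = seq_along(profile@sense),
             sense = profile@sense, antisense = profile@antisense,
             stringsAsFactors = FALSE)
}

#' Length-by-first-nucleotide signature matrix
#'
#' Counts each unique virus-assigned sequence of one orientation once, at
#' (insert length, first nucleotide). The first nucleotide is reported in the
#' RNA alphabet (U for T), following small-RNA figure convention.
#'
#' @param mapped data.frame from [classifySequences()].
#' @param orientation `"sense"` or `"antisense"`.
#' @param minLen,maxLen matrix length range (defaults 18-30); a sequence
#'   outside it raises a consistency error.
#' @return integer matrix with rownames `minLen:maxLen` and colnames
#'   `A,C,G,U`; grand total = number of unique sequences of the orientation.
#' @export
lengthFirstNtMatrix <- function(mapped, orientation = c("sense", "antisense"),
                                minLen = 18L, maxLen = 30L) {
  orientation <- match.arg(orientation)
  m <- mapped[mapped$category == paste0("virus_", orientation), ,
              drop = FALSE]
  lens <- nchar(m$sequence)
  if (nrow(m) && (any(lens < minLen) || any(lens > maxLen)))
    stop("sequence length outside ", minLen, "-", maxLen, " nt")
  first <- chartr("T", "U", substr(m$sequence, 1L, 1L))
  mat <- table(factor(lens, levels = minLen:maxLen),
               factor(first, levels = c("A", "C", "G", "U")))
  mat <- matrix(as.integer(mat), nrow = maxLen - minLen + 1L,
                dimnames = list(as.character(minLen:maxLen),
                                c("A", "C", "G", "U")))
  mat
}

#' Summarize the viral small-RNA signature across libraries
#'
#' Computes the unique-sequence tallies and the hallmarks of a 22G secondary
#' siRNA response: the viral fraction of all unambiguously mapped unique
#' sequences, the antisense modal length, the fractions of antisense
#' sequences of length 22 and with a 5' G, and the 22G flag (modal antisense
#' length 22 AND G the modal antisense first base). With zero antisense
#' sequences the modal fields are NA and the flag is FALSE; no error is
#' raised.
#'
#' @param mapped data.frame from [classifySequences()] (one or several
#'   libraries row-bound together).
#' @return a [SignatureSummary-class].
#' @export
signatureSummary <- function(mapped) {
  anti <- mapped[mapped$category == "virus_antisense", , drop = FALSE]
  sens <- mapped[mapped$category == "virus_sense", , drop = FALSE]
  nHost <- sum(mapped$category == "host")
  nA <- nrow(anti); nS <- nrow(sens)
  total <- nA + nS + nHost
  firstBase <- function(x) chartr("T", "U", substr(x, 1L, 1L))
  if (nA > 0L) {
    lt <- table(nchar(anti$sequence))
    modalLen <- as.integer(names(lt)[which.max(lt)])
    bt <- table(firstBase(anti$sequence))
    modalBase <- names(bt)[which.max(bt)]
    fr22 <- mean(nchar(anti$sequence) == 22L)
    frG <- mean(firstBase(anti$sequence) == "G")
    flag <- modalLen == 22L && modalBase == "G"
  } else {
    modalLen <- NA_integer_; fr22 <- NA_real_; frG <- NA_real_; flag <- FALSE
  }
  new("SignatureSummary",
      nUniqueVirusSense = nS, nUniqueVirusAntisense = nA,
      nUniqueUnambiguousTotal = as.integer(total),
      viralFraction = if (total > 0L) (nA + nS) / total else NA_real_,
      antisenseModalLength = modalLen,
      antisenseFractionLen22 = fr22,
      antisenseFraction5primeG = frG,
      senseFraction5primeG = if (nS > 0L)
        mean(firstBase(sens$sequence) == "G") else NA_real_,
      flag22G = flag)
}

#' Plot a per-position viRNA profile
#'
#' Sense counts are drawn upward, antisense counts downward, the layout used
#' for published viral small-RNA coverage panels.
#'
#' @param x a [VirnaProfile-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics lines abline legend
#' @export
setMethod("plot", methods::signature(x = "VirnaProfile", y = "missing"),
  function(x, y, ...) {
    pos <- seq_along(x@sense)
    ylim <- range(c(x@sense, -x@antisense, 0L))
    graphics::plot(pos, x@sense, type = "h", col = "steelblue",
                   ylim = ylim, xlab = paste("position in", x@segmentId),
                   ylab = "unique sequences (sense up / antisense down)",
                   ...)
    graphics::lines(pos, -x@antisense, type = "h", col = "firebrick")
    graphics::abline(h = 0)
    invisible(NULL)
  })
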