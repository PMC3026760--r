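#' @rdname ViralSegment-class
#' @param object a ViralSegment.
#' @export
setGeneric("segmentId", function(object) standardGeneric("segmentId"))
#' @rdname ViralSegment-class
#' @export
setGeneric("segmentSeq", function(object) standardGeneric("segmentSeq"))
#' @rdname ViralSegment-class
#' @export
setGeneric("segmentRole", function(object) standardGeneric("segmentRole"))
#' @rdname VirnaProfile-class
#' @param object a VirnaProfile.
#' @export
setGeneric("senseCounts", function(object) standardGeneric("senseCounts"))
#' @rdname VirnaProfile-class
#' @export
setGeneric("antisenseCounts",
           function(object) standardGeneric("antisenseCounts"))

#' @describeIn ViralSegment-class segment id accessor.
setMethod("segmentId", "ViralSegment", function(object) object@id)
#' @describeIn ViralSegment-class sequence accessor (character).
setMethod("segmentSeq", "ViralSegment", function(object) object@sequence)
#' @describeIn ViralSegment-class role accessor.
setMethod("segmentRole", "ViralSegment", function(object) object@role)

#' @describeIn VirnaProfile-class sense count vector accessor.
setMethod("senseCounts", "VirnaProfile", function(object) object@sense)
#' @describeIn VirnaProfile-class antisense count vector accessor.
setMethod("antisenseCounts", "VirnaProfile",
          function(object) object@antisense)

setMethod("show", "ViralSegment", function(object) {
  cat(sprintf("ViralSegment '%s' (%s), %d nt\n", object@id, object@role,
              nchar(object@sequence)))
})

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf("ReferenceSet: %d record(s) (%d virus, %d host), %d nt total\n",
              length(object@seqs), sum(object@refClass == "virus"),
              sum(object@refClass == "host"),
              sum(Biostrings::width(object@seqs))))
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k=%d over %d record(s), %d seed positions\n",
              object@k, length(object@refs@seqs), length(object@codes)))
})

setMethod("show", "VirnaProfile", function(object) {
  cat(sprintf(
    "VirnaProfile of '%s': %d positions; %d sense / %d antisense covered\n",
    object@segmentId, length(object@sense), sum(object@sense > 0L),
    sum(object@antisense > 0L)))
})

setMethod("show", "SignatureSummary", function(object) {
  cat("Viral small-RNA signature summary\n")
  cat(sprintf("  unique unambiguous sequences: %d (viral fraction %.4g)\n",
              object@nUniqueUnambiguousTotal, object@viralFraction))
  cat(sprintf("  virus sense / antisense: %d / %d\n",
              object@nUniqueVirusSense, object@nUniqueVirusAntisense))
  cat(sprintf("  antisense modal length: %s; len-22 fraction %.3f\n",
              object@antisenseModalLength, object@antisenseFractionLen22))
  cat(sprintf("  5'G fraction antisense / sense: %.3f / %.3f\n",
              object@antisenseFraction5primeG, object@senseFraction5primeG))
  cat(sprintf("  22G signature: %s\n",
              if (isTRUE(object@flag22G)) "present" else "absent"))
})

setMethod("show", "OrganizationReport", function(object) {
  cat("Genome organization report\n")
  for (seg in object@segments)
    cat(sprintf("  %s -> %s (%d nt)\n", segmentId(seg), segmentRole(seg),
                nchar(segmentSeq(seg))))
  fmt <- function(gr, what) {
    if (length(gr) == 0L) cat(sprintf("  %s: none\n", what))
    else cat(sprintf("  %s: %s:%d-%d (%d aa)\n", what,
                     as.character(GenomicRanges::seqnames(gr))[1L],
                     GenomicRanges::start(gr)[1L], GenomicRanges::end(gr)[1L],
                     S4Vectors::mcols(gr)$aaLength[1L]))
  }
  fmt(object@rdrpCandidate, "RdRP candidate")
  fmt(object@b2Like, "B2-like +1 overlap")
  fmt(object@capsidCandidate, "capsid candidate")
  fmt(object@orfDeltaCandidate, "3' ORF (delta) candidate")
  cat(sprintf("  RNA2 oversize vs 1.4 kb convention: %s\n",
              object@rna2Oversize))
})
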