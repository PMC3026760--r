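STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                        paste0), c("T", "C", "A", "G"), paste0)),
  STOP_CODONS)

#' ViralSegment: a named viral genome segment
#'
#' Holds one nucleotide sequence of a (putative) bipartite RNA virus genome
#' together with its segment role. Roles are assigned either by the user or by
#' [classifyOrganization()]; freshly read segments carry role `"unknown"`.
#'
#' @slot id character scalar, short label (e.g. `"RNA1"` contig name).
#' @slot sequence character scalar over \{A,C,G,T\} (U is normalized to T on
#'   construction; ambiguity codes are rejected).
#' @slot role one of `"RNA1"`, `"RNA2"`, `"unknown"`.
#' @export
setClass("ViralSegment",
  representation(id = "character", sequence = "character", role = "character"),
  prototype(role = "unknown"))

setValidity("ViralSegment", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty string")
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  else if (grepl("[^ACGT]", object@sequence))
    msg <- c(msg, "sequence must contain only A, C, G, T")
  if (!object@role %in% c("RNA1", "RNA2", "unknown"))
    msg <- c(msg, "role must be one of RNA1, RNA2, unknown")
  if (length(msg)) msg else TRUE
})

#' Construct a ViralSegment
#'
#' @param id segment label.
#' @param sequence nucleotide string (or `DNAString`); U/lowercase normalized.
#' @param role segment role, default `"unknown"`.
#' @return a [ViralSegment-class] object.
#' @examples
#' seg <- ViralSegment("RNA1", "AUGAAAUAG")
#' segmentSeq(seg)
#' @export
ViralSegment <- function(id, sequence, role = "unknown") {
  if (methods::is(sequence, "XString") || methods::is(sequence, "XStringSet"))
    sequence <- as.character(sequence)[1L]
  new("ViralSegment", id = as.character(id),
      sequence = normalizeNt(sequence), role = role)
}

#' OrganizationReport: genome-organization annotation of a segment pair
#'
#' Result of [classifyOrganization()]. Candidate slots are `GRanges` with zero
#' or one row; an empty `GRanges` means "absent".
#'
#' @slot segments list of [ViralSegment-class] with roles filled in.
#' @slot roles named character, segment id -> assigned role.
#' @slot orfs `GRanges` of all ORFs passing the length cutoff, all segments.
#' @slot rdrpCandidate longest plus-strand ORF on the RNA1-role segment
#'   (polymerase candidate).
#' @slot b2Like overlapping +1-frame ORF intersecting the RdRP C-terminus,
#'   the hallmark of nodavirus B2 RNAi suppressors; empty when none.
#' @slot capsidCandidate longest plus-strand ORF starting in the 5' half of
#'   the RNA2-role segment.
#' @slot orfDeltaCandidate longest ORF starting 3' of the capsid candidate.
#' @slot rna2Oversize logical: RNA2 exceeds the ~1.4 kb nodavirus convention
#'   by at least the configured margin.
#' @export
setClass("OrganizationReport",
  representation(segments = "list", roles = "character",
                 orfs = "GRanges", rdrpCandidate = "GRanges",
                 b2Like = "GRanges", capsidCandidate = "GRanges",
                 orfDeltaCandidate = "GRanges", rna2Oversize = "logical"))

#' ReferenceSet: host + virus reference union for exact mapping
#'
#' @slot seqs named `DNAStringSet` of reference records.
#' @slot refClass character per record, `"host"` or `"virus"`.
#' @slot role character per record: segment role for virus records,
#'   `"unknown"` otherwise.
#' @export
setClass("ReferenceSet",
  representation(seqs = "DNAStringSet", refClass = "character",
                 role = "character"))

setValidity("ReferenceSet", function(object) {
  msg <- character(0)
  ids <- names(object@seqs)
  if (length(object@seqs) == 0L)
    msg <- c(msg, "reference set must contain at least one record")
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "reference ids must be unique non-empty names")
  if (length(object@refClass) != length(object@seqs) ||
      !all(object@refClass %in% c("host", "virus")))
    msg <- c(msg, "refClass must be 'host' or 'virus', one per record")
  if (length(object@role) != length(object@seqs))
    msg <- c(msg, "role must have one entry per record")
  if (any(grepl("[^ACGT]", as.character(object@seqs))))
    msg <- c(msg, "reference sequences must be ACGT-only")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param virus named character vector (or `DNAStringSet`, or list of
#'   [ViralSegment-class]) of viral records.
#' @param host named character vector (or `DNAStringSet`) of host records;
#'   may be empty.
#' @param roles optional named character of segment roles for virus records.
#' @return a [ReferenceSet-class].
#' @export
referenceSet <- function(virus, host = character(0), roles = NULL) {
  asNamed <- function(x, what) {
    if (is.list(x) && all(vapply(x, methods::is, TRUE, "ViralSegment"))) {
      r <- vapply(x, segmentSeq, "")
      names(r) <- vapply(x, segmentId, "")
      if (is.null(roles)) roles <<- setNames(vapply(x, segmentRole, ""), names(r))
      return(r)
    }
    if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
    if (length(x) && is.null(names(x)))
      stop(what, " records must be named")
    x
  }
  v <- asNamed(virus, "virus")
  h <- asNamed(host, "host")
  seqs <- Biostrings::DNAStringSet(vapply(c(v, h), normalizeNt, ""))
  cls <- c(rep("virus", length(v)), rep("host", length(h)))
  rl <- rep("unknown", length(seqs))
  names(rl) <- names(seqs)
  if (!is.null(roles)) rl[names(roles)] <- roles
  new("ReferenceSet", seqs = seqs, refClass = cls, role = unname(rl))
}

#' KmerIndex: exact-substring index over both strands of a ReferenceSet
#'
#' Built by [buildReferenceIndex()]; stores plus-strand k-mer start codes in
#' sorted order for binary-search seeding, with full verification at query
#' time, so matches are exact by construction.
#'
#' @slot refs the indexed [ReferenceSet-class].
#' @slot k integer seed length.
#' @slot codes sorted numeric vector of k-mer codes (base-4 encoding).
#' @slot rec integer record index per code.
#' @slot pos integer 0-based plus-strand start position per code.
#' @export
setClass("KmerIndex",
  representation(refs = "ReferenceSet", k = "integer", codes = "numeric",
                 rec = "integer", pos = "integer"))

#' VirnaProfile: per-position sense/antisense unique-sequence counts
#'
#' One count vector per orientation, indexed by reference position of one
#' viral segment; the counting unit is unique sequences, the display unit of
#' the published coverage panels.
#'
#' @slot segmentId id of the profiled segment.
#' @slot sense integer vector, length = segment length.
#' @slot antisense integer vector, length = segment length.
#' @export
setClass("VirnaProfile",
  representation(segmentId = "character", sense = "integer",
                 antisense = "integer"))

setValidity("VirnaProfile", function(object) {
  if (length(object@sense) != length(object@antisense))
    return("sense and antisense vectors must have equal length")
  if (any(object@sense < 0L) || any(object@antisense < 0L))
    return("counts must be non-negative")
  TRUE
})

#' SignatureSummary: summary statistics of the viral small-RNA signature
#'
#' Captures the hallmarks of a secondary-siRNA (22G) antiviral response:
#' antisense reads concentrated at 22 nt with a 5' G bias, against the total
#' unambiguously mapped unique-sequence background.
#'
#' @slot nUniqueVirusSense unique virus-matching sense sequences.
#' @slot nUniqueVirusAntisense unique virus-matching antisense sequences.
#' @slot nUniqueUnambiguousTotal all unambiguously mapped unique sequences
#'   (virus + host).
#' @slot viralFraction viral / total unambiguous unique sequences.
#' @slot antisenseModalLength modal antisense insert length (NA when no
#'   antisense sequences).
#' @slot antisenseFractionLen22 fraction of antisense sequences of length 22.
#' @slot antisenseFraction5primeG fraction of antisense sequences starting G.
#' @slot senseFraction5primeG fraction of sense sequences starting G.
#' @slot flag22G TRUE iff modal antisense length is 22 and G is the modal
#'   antisense first base.
#' @export
setClass("SignatureSummary",
  representation(nUniqueVirusSense = "integer",
                 nUniqueVirusAntisense = "integer",
                 nUniqueUnambiguousTotal = "integer",
                 viralFraction = "numeric",
                 antisenseModalLength = "integer",
                 antisenseFractionLen22 = "numeric",
                 antisenseFraction5primeG = "numeric",
                 senseFraction5primeG = "numeric",
                 flag22G = "logical"))
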