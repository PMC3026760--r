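## evaluate expr under a temporary RNG state so simulators are pure
## functions of their seed
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    saved <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", saved, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Configuration for the synthetic-data generator
#'
#' One object fixes every draw of the simulators (genomes, host stand-in,
#' small-RNA libraries): the same config is guaranteed to reproduce identical
#' output. Defaults emulate the study conditions of a natural nodavirus-like
#' infection of *Caenorhabditis*: segment lengths and ORF sizes of the
#' bipartite genome, a secondary-siRNA antisense population concentrated at
#' 22 nt with a 5' G bias, sense and host backgrounds, and a viral
#' unique-sequence fraction of about 2 percent of the mappable library.
#'
#' @param seed integer master seed.
#' @param rna1Length,rna2Length segment lengths in nt (defaults 3628 and
#'   2653).
#' @param rdrpAa,capsidAa,deltaAa,b2Aa planted ORF product sizes in amino
#'   acids (initiator Met included, stop excluded).
#' @param plantB2 plant a +1-frame ORF overlapping the polymerase C-terminus.
#' @param plantDelta plant a second ORF 3' of the capsid ORF on RNA2.
#' @param hostLength host stand-in length in nt (50 kb), rejection-sampled so
#'   that no 18-mer is shared (or strand-ambiguous) within the reference
#'   union, keeping planted reads unambiguously mappable.
#' @param nAntisense,nSense,nHost unique insert counts of the infected
#'   library (defaults 300/100/19600: viral fraction 0.02).
#' @param nControlViral viral unique inserts in the control library (0).
#' @param antisenseLenSpill probability mass moved off length 22, split
#'   evenly between 21 and 23 (default 0.2).
#' @param p5primeGAntisense probability an antisense insert is forced (by
#'   window placement) to start with G (default 0.6).
#' @param pATail per-read probability of a 1-4 nt 3' A-tail artifact.
#' @param barcodes named 4-nt barcodes, `infected` and `control`.
#' @param readCountGeomProb geometric parameter for reads per unique insert
#'   (count = 1 + geometric; default 0.5), exercising collapse logic.
#' @param minOrfAa ORF length floor used by the generator's truth checks.
#' @param maxTries bounded retries for rejection sampling.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, rna1Length = 3628L, rna2Length = 2653L,
                      rdrpAa = 982L, capsidAa = 400L, deltaAa = 332L,
                      b2Aa = 60L, plantB2 = FALSE, plantDelta = TRUE,
                      hostLength = 50000L, nAntisense = 300L, nSense = 100L,
                      nHost = 19600L, nControlViral = 0L,
                      antisenseLenSpill = 0.2, p5primeGAntisense = 0.6,
                      pATail = 0.3,
                      barcodes = c(infected = "ACGT", control = "TGCA"),
                      readCountGeomProb = 0.5, minOrfAa = 50L,
                      maxTries = 200L) {
  cfg <- list(seed = as.integer(seed), rna1Length = as.integer(rna1Length),
              rna2Length = as.integer(rna2Length), rdrpAa = as.integer(rdrpAa),
              capsidAa = as.integer(capsidAa), deltaAa = as.integer(deltaAa),
              b2Aa = as.integer(b2Aa), plantB2 = plantB2,
              plantDelta = plantDelta, hostLength = as.integer(hostLength),
              nAntisense = as.integer(nAntisense), nSense = as.integer(nSense),
              nHost = as.integer(nHost),
              nControlViral = as.integer(nControlViral),
              antisenseLenSpill = antisenseLenSpill,
              p5primeGAntisense = p5primeGAntisense, pATail = pATail,
              barcodes = barcodes,
              readCountGeomProb = readCountGeomProb,
              minOrfAa = as.integer(minOrfAa), maxTries = as.integer(maxTries))
  probs <- c(cfg$antisenseLenSpill, cfg$p5primeGAntisense, cfg$pATail,
             cfg$readCountGeomProb)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0,1]")
  if (any(c(cfg$rna1Length, cfg$rna2Length, cfg$hostLength) <= 0))
    stop("lengths must be positive")
  if (any(nchar(cfg$barcodes) != 4L) || anyDuplicated(cfg$barcodes))
    stop("barcodes must be distinct 4-nt strings")
  class(cfg) <- "SimConfig"
  cfg
}

.randNt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
.randOrf <- function(aa) paste0("ATG",
                                paste(sample(SENSE_CODONS, aa - 1L, TRUE),
                                      collapse = ""),
                                sample(STOP_CODONS, 1L))

## overwrite a triplet inside a character-split sequence
.putTriplet <- function(chars, start0, triplet) {
  chars[(start0 + 1L):(start0 + 3L)] <- strsplit(triplet, "")[[1L]]
  chars
}

#' Simulate a bipartite viral genome with planted ORFs and truth record
#'
#' Builds an RNA1 segment with one long planted polymerase-surrogate ORF
#' (and, iff `plantB2`, a +1-frame ORF overlapping its 3' end) and an RNA2
#' segment with a 5' capsid-surrogate ORF (and, iff `plantDelta`, a second
#' 3' ORF). Background regions are uniform random; the planted reading
#' frames are built from sense codons so no internal stop occurs. Rejection
#' sampling guarantees that the package's own annotation recovers exactly
#' the planted truth (the planted ORFs are the longest on their segments,
#' B2-like and delta calls match the planted flags and coordinates).
#'
#' @param cfg a [simConfig()] object.
#' @return list with `segments` (two [ViralSegment-class], roles assigned)
#'   and `truth` (planted coordinates, 1-based closed, stop codon included
#'   in the range).
#' @export
simulateViralGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(deriveSeed(cfg$seed, 101L), {
    rna1 <- .simRna1(cfg)
    rna2 <- .simRna2(cfg)
    list(segments = list(
           ViralSegment("RNA1", rna1$seq, role = "RNA1"),
           ViralSegment("RNA2", rna2$seq, role = "RNA2")),
         truth = c(rna1$truth, rna2$truth,
                   list(plantB2 = cfg$plantB2, plantDelta = cfg$plantDelta)))
  })
}

.simRna1 <- function(cfg) {
  utr5 <- 20L
  orfNt <- 3L * (cfg$rdrpAa + 1L)
  s0 <- utr5                       # 0-based ORF start
  e0 <- s0 + orfNt                 # 0-based half-open end
  if (e0 > cfg$rna1Length)
    stop("infeasible geometry: RNA1 too short for the planted ORF")
  b2s0 <- b2e0 <- NA_integer_
  if (cfg$plantB2) {
    b2s0 <- s0 + 3L * (cfg$rdrpAa + 1L - 30L) + 1L  # ~30 codons of overlap
    b2e0 <- b2s0 + 3L * (cfg$b2Aa + 1L)
    if (b2e0 > cfg$rna1Length)
      stop("infeasible geometry: no room for the planted B2-like ORF")
  }
  for (try in seq_len(cfg$maxTries)) {
    seq <- paste0(.randNt(utr5), .randOrf(cfg$rdrpAa),
                  .randNt(cfg$rna1Length - e0))
    if (cfg$plantB2) {
      chars <- strsplit(seq, "")[[1L]]
      chars <- .putTriplet(chars, b2s0, "ATG")
      chars <- .putTriplet(chars, b2e0 - 3L, sample(STOP_CODONS, 1L))
      # scrub stops in the planted B2 frame and restore the anchor frame
      ok <- TRUE
      for (p in seq.int(b2s0 + 3L, b2e0 - 6L, by = 3L)) {
        cod <- paste(chars[(p + 1L):(p + 3L)], collapse = "")
        if (cod %in% STOP_CODONS) {
          chars[(p + 1L):(p + 3L)] <-
            strsplit(sample(SENSE_CODONS, 1L), "")[[1L]]
        }
      }
      # anchor-frame codons over the B2 region must stay sense codons
      for (p in seq.int(s0, e0 - 6L, by = 3L)) {
        if (p + 3L < b2s0 || p > b2e0) next
        cod <- paste(chars[(p + 1L):(p + 3L)], collapse = "")
        if (cod %in% STOP_CODONS) { ok <- FALSE; break }
      }
      if (!ok) next
      seq <- paste(chars, collapse = "")
    }
    seg <- ViralSegment("RNA1", seq, role = "RNA1")
    orfs <- scanOrfs(seg, minAa = cfg$minOrfAa, bothStrands = TRUE)
    plus <- orfs[as.logical(GenomicRanges::strand(orfs) == "+")]
    top <- .longestOrf(plus)
    if (length(top) == 0L || GenomicRanges::start(top) != s0 + 1L ||
        GenomicRanges::end(top) != e0) next
    b2 <- findOverlappingPlus1Orf(orfs, top, minAa = cfg$minOrfAa,
                                  ctermWindow = min(300L, orfNt))
    if (!cfg$plantB2 && length(b2) > 0L) next
    if (cfg$plantB2 &&
        (length(b2) == 0L || GenomicRanges::start(b2) != b2s0 + 1L ||
         GenomicRanges::end(b2) != b2e0)) next
    return(list(seq = seq, truth = list(
      rdrp = list(start = s0 + 1L, end = e0, aaLength = cfg$rdrpAa),
      b2 = if (cfg$plantB2)
        list(start = b2s0 + 1L, end = b2e0, aaLength = cfg$b2Aa))))
  }
  stop("RNA1 generation failed after ", cfg$maxTries, " tries")
}

.simRna2 <- function(cfg) {
  utr5 <- 20L
  capNt <- 3L * (cfg$capsidAa + 1L)
  cs0 <- utr5
  ce0 <- cs0 + capNt
  ds0 <- de0 <- NA_integer_
  tailStart <- ce0
  if (cfg$plantDelta) {
    ds0 <- ce0 + 30L
    de0 <- ds0 + 3L * (cfg$deltaAa + 1L)
    tailStart <- de0
  }
  if (tailStart > cfg$rna2Length)
    stop("infeasible geometry: RNA2 too short for the planted ORFs")
  if (ce0 - capNt > cfg$rna2Length / 2)
    stop("infeasible geometry: capsid ORF does not start in the 5' half")
  for (try in seq_len(cfg$maxTries)) {
    seq <- paste0(.randNt(utr5), .randOrf(cfg$capsidAa),
                  if (cfg$plantDelta)
                    paste0(.randNt(30L), .randOrf(cfg$deltaAa)) else "",
                  .randNt(cfg$rna2Length - tailStart))
    seg <- ViralSegment("RNA2", seq, role = "RNA2")
    orfs <- scanOrfs(seg, minAa = cfg$minOrfAa, bothStrands = TRUE)
    plus <- orfs[as.logical(GenomicRanges::strand(orfs) == "+")]
    cap <- .longestOrf(plus[GenomicRanges::start(plus) <=
                              cfg$rna2Length / 2])
    if (length(cap) == 0L || GenomicRanges::start(cap) != cs0 + 1L ||
        GenomicRanges::end(cap) != ce0) next
    after <- plus[GenomicRanges::start(plus) > GenomicRanges::start(cap)]
    delta <- .longestOrf(after)
    if (!cfg$plantDelta && length(delta) > 0L) next
    if (cfg$plantDelta &&
        (length(delta) == 0L || GenomicRanges::start(delta) != ds0 + 1L ||
         GenomicRanges::end(delta) != de0)) next
    return(list(seq = seq, truth = list(
      capsid = list(start = cs0 + 1L, end = ce0, aaLength = cfg$capsidAa),
      delta = if (cfg$plantDelta)
        list(start = ds0 + 1L, end = de0, aaLength = cfg$deltaAa))))
  }
  stop("RNA2 generation failed after ", cfg$maxTries, " tries")
}

## all k-mers of a character sequence
.kmers <- function(seq, k) {
  m <- nchar(seq) - k + 1L
  if (m < 1L) return(character(0))
  substring(seq, seq_len(m), seq_len(m) + k - 1L)
}

## TRUE when every 18-mer of the union occurs exactly once on the plus
## strands and never on a minus strand: guarantees unambiguous mapping of
## any >= 18 nt window
.kmerSafe <- function(seqs, k = 18L) {
  fwd <- unlist(lapply(seqs, .kmers, k = k), use.names = FALSE)
  if (anyDuplicated(fwd)) return(FALSE)
  rev <- unlist(lapply(revComp(seqs), .kmers, k = k), use.names = FALSE)
  !any(fwd %in% rev)
}

#' Simulate a host-genome stand-in
#'
#' Uniform random sequence of `hostLength` nt, rejection-sampled jointly
#' with the viral segments so that no 18-mer repeats or is shared across
#' strands anywhere in the union — every insert of 18 nt or more drawn from
#' the union then maps exactly once.
#'
#' @param cfg a [simConfig()] object.
#' @param segments viral segments from [simulateViralGenome()].
#' @return named character scalar (`host`).
#' @export
simulateHostGenome <- function(cfg, segments) {
  vir <- vapply(segments, segmentSeq, "")
  withSeed(deriveSeed(cfg$seed, 202L), {
    for (try in seq_len(cfg$maxTries)) {
      host <- .randNt(cfg$hostLength)
      if (.kmerSafe(c(vir, host))) return(c(host = host))
    }
    stop("host generation failed after ", cfg$maxTries, " tries")
  })
}

## vectorized sampler of unique insert windows from one sequence.
## n inserts; lens sampled by `lenFun(m)`; `firstBaseFun(m)` returns the
## required source-strand base at the position determining the insert's
## first base, or NA for unconstrained; antisense inserts are reverse
## complements of the sampled window. Inserts never end in A (so the
## unconditional 3' A-trim cannot eat into them) and are unique within
## `seen`.
.sampleInserts <- function(seqChars, n, lenFun, antisense, firstConstraint,
                           seen, maxTries) {
  L <- length(seqChars)
  # one length and one first-base constraint per target insert, drawn once:
  # only the window position is resampled on rejection, so the realized
  # first-base distribution equals the drawn one exactly
  fc <- firstConstraint(n)
  ln <- lenFun(n)
  out <- character(n)
  pos <- integer(n)
  todo <- seq_len(n)
  lastBad <- if (antisense) "T" else "A"
  for (try in seq_len(maxTries)) {
    if (length(todo) == 0L) break
    m <- length(todo)
    p <- 1L + as.integer(floor(stats::runif(m) * (L - ln[todo] + 1L)))
    e <- p + ln[todo] - 1L
    firstPos <- if (antisense) e else p
    lastPos <- if (antisense) p else e
    ok <- (is.na(fc[todo]) | seqChars[firstPos] == fc[todo]) &
      seqChars[lastPos] != lastBad
    idx <- which(ok)
    if (length(idx) == 0L) next
    win <- vapply(idx, function(i) paste(seqChars[p[i]:e[i]],
                                         collapse = ""), "")
    ins <- if (antisense) revComp(win) else win
    uok <- !(ins %in% seen) & !duplicated(ins)
    fill <- todo[idx[uok]]
    out[fill] <- ins[uok]
    pos[fill] <- p[idx[uok]] - 1L
    seen <- c(seen, ins[uok])
    todo <- setdiff(todo, fill)
  }
  if (length(todo) > 0L)
    stop("window selection failed after bounded retries")
  list(sequence = out, position = pos, length = ln, seen = seen)
}

#' Simulate a small-RNA sequencing library with truth records
#'
#' Emits reads of the form barcode + insert + optional 3' A-tail. Antisense
#' viral inserts are reverse complements of genome windows with lengths
#' drawn around 22 nt and their first base forced to G (by window placement,
#' never by mutation, so reads stay exact genome substrings) with
#' probability `p5primeGAntisense` — and forced to a non-G base otherwise,
#' so the planted 5' G fraction equals the parameter exactly. Sense viral
#' inserts have uniform 18-30 nt lengths and uniform first base; host
#' inserts are uniform windows of the host stand-in. All inserts of a
#' library are unique sequences; each receives 1 + geometric(p) reads.
#' Inserts never end in A so that unconditional 3' A-trimming reconstructs
#' them exactly.
#'
#' @param cfg a [simConfig()] object.
#' @param genomes result of [simulateViralGenome()].
#' @param host result of [simulateHostGenome()].
#' @param library `"infected"` or `"control"`; the control library draws
#'   `nControlViral` viral inserts (default 0).
#' @return list with `reads` (data.frame `id`, `sequence`, `quality`) and
#'   `truth` (one row per unique insert: sequence, origin, orientation,
#'   segment, 0-based plus-strand position, length, first base in RNA
#'   alphabet, read count, barcode).
#' @export
simulateSmallRnaLibrary <- function(cfg, genomes, host,
                                    library = c("infected", "control")) {
  library <- match.arg(library)
  barcode <- unname(cfg$barcodes[[library]])
  segs <- genomes$segments
  segChars <- lapply(segs, function(s) strsplit(segmentSeq(s), "")[[1L]])
  segLens <- vapply(segChars, length, 0L)
  hostChars <- strsplit(unname(host), "")[[1L]]
  if (library == "infected") {
    nA <- cfg$nAntisense; nS <- cfg$nSense
  } else {
    nv <- cfg$nControlViral
    nA <- nv %/% 2L; nS <- nv - nA
  }
  nH <- cfg$nHost
  withSeed(deriveSeed(cfg$seed, if (library == "infected") 303L else 404L), {
    seen <- character(0)
    truth <- list()
    spill <- cfg$antisenseLenSpill
    aLen <- function(m) sample(c(21L, 22L, 23L), m, TRUE,
                               prob = c(spill / 2, 1 - spill, spill / 2))
    sLen <- function(m) sample(18:30, m, TRUE)
    # per-segment allocation proportional to length
    alloc <- function(n) {
      if (n == 0L) return(integer(length(segs)))
      a <- as.vector(stats::rmultinom(1L, n, segLens / sum(segLens)))
      a
    }
    nAseg <- alloc(nA); nSseg <- alloc(nS)
    for (i in seq_along(segs)) {
      if (nAseg[i] > 0L) {
        # antisense first base G <=> source-strand base C at the window end
        fc <- function(m) {
          g <- stats::runif(m) < cfg$p5primeGAntisense
          out <- rep("C", m)
          out[!g] <- sample(c("A", "G", "T"), sum(!g), TRUE)
          out
        }
        sm <- .sampleInserts(segChars[[i]], nAseg[i], aLen, TRUE, fc, seen,
                             cfg$maxTries)
        seen <- sm$seen
        truth[[length(truth) + 1L]] <- data.frame(
          sequence = sm$sequence, origin = "virus",
          orientation = "antisense", segment = segmentId(segs[[i]]),
          position = sm$position, length = sm$length,
          stringsAsFactors = FALSE)
      }
      if (nSseg[i] > 0L) {
        fc <- function(m) sample(c("A", "C", "G", "T"), m, TRUE)
        sm <- .sampleInserts(segChars[[i]], nSseg[i], sLen, FALSE, fc, seen,
                             cfg$maxTries)
        seen <- sm$seen
        truth[[length(truth) + 1L]] <- data.frame(
          sequence = sm$sequence, origin = "virus", orientation = "sense",
          segment = segmentId(segs[[i]]), position = sm$position,
          length = sm$length, stringsAsFactors = FALSE)
      }
    }
    if (nH > 0L) {
      fc <- function(m) rep(NA_character_, m)
      sm <- .sampleInserts(hostChars, nH, sLen, FALSE, fc, seen, cfg$maxTries)
      truth[[length(truth) + 1L]] <- data.frame(
        sequence = sm$sequence, origin = "host", orientation = "sense",
        segment = "host", position = sm$position, length = sm$length,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth$firstBase <- chartr("T", "U", substr(truth$sequence, 1L, 1L))
    truth$readCount <- 1L + stats::rgeom(nrow(truth),
                                         cfg$readCountGeomProb)
    truth$barcode <- barcode
    # expand to reads with optional A-tails, in shuffled order
    idx <- rep.int(seq_len(nrow(truth)), truth$readCount)
    idx <- sample(idx)
    tail <- ifelse(stats::runif(length(idx)) < cfg$pATail,
                   strrep("A", sample(1:4, length(idx), TRUE)), "")
    seqs <- paste0(barcode, truth$sequence[idx], tail)
    reads <- data.frame(
      id = sprintf("%s_r%06d", library, seq_along(idx)),
      sequence = seqs, quality = strrep("I", nchar(seqs)),
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate symptom-scoring 2x2 tables under known prevalences
#'
#' Binomial draws of symptomatic animals in an infected and a control arm.
#'
#' @param pInfected,pControl per-arm probability of showing >= 1 symptom.
#' @param nPerArm animals per arm.
#' @param seed integer seed.
#' @return list with `table` (2x2: rows infected/control, columns
#'   symptomatic/asymptomatic) and `truth`.
#' @export
simulateSymptomTables <- function(pInfected, pControl, nPerArm, seed = 1L) {
  if (pInfected < 0 || pInfected > 1 || pControl < 0 || pControl > 1)
    stop("probabilities must be in [0,1]")
  if (nPerArm < 1L) stop("nPerArm must be >= 1")
  withSeed(deriveSeed(seed, 505L), {
    a <- stats::rbinom(1L, nPerArm, pInfected)
    c <- stats::rbinom(1L, nPerArm, pControl)
    tab <- matrix(c(a, c, nPerArm - a, nPerArm - c), 2L,
                  dimnames = list(c("infected", "control"),
                                  c("symptomatic", "asymptomatic")))
    list(table = tab, truth = list(pInfected = pInfected,
                                   pControl = pControl, nPerArm = nPerArm))
  })
}
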