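# Independent oracles used across test files. These deliberately use naive
# mechanisms (per-position walks, full scans, direct enumeration) rather than
# the package's own code paths.

randNt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")

# plus-strand ORF oracle: enumerate every ATG, walk codon by codon to the
# next in-frame stop, keep the 5'-most ATG per stop (maximal), then filter.
# Returns 0-based half-open coordinates.
oracleOrfsPlus <- function(seq, minAa, allowPartial = FALSE) {
  L <- nchar(seq)
  rows <- list()
  if (L >= 3L) {
    for (a in seq_len(L - 2L)) {
      if (substr(seq, a, a + 2L) != "ATG") next
      i <- a
      stopAt <- NA_integer_
      while (i + 2L <= L) {
        cod <- substr(seq, i, i + 2L)
        if (i > a && cod %in% c("TAA", "TAG", "TGA")) { stopAt <- i; break }
        i <- i + 3L
      }
      if (!is.na(stopAt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = a - 1L, end = stopAt + 2L, frame = (a - 1L) %% 3L,
          aa = (stopAt - a) %/% 3L, partial = FALSE)
      } else if (allowPartial) {
        nc <- (L - a + 1L) %/% 3L
        if (nc >= 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            start = a - 1L, end = a - 1L + 3L * nc, frame = (a - 1L) %% 3L,
            aa = nc, partial = TRUE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), aa = integer(0),
                      partial = logical(0)))
  df <- do.call(rbind, rows)
  # maximal: one ORF per (frame, end), 5'-most start
  df <- df[order(df$frame, df$end, df$start), ]
  df <- df[!duplicated(df[, c("frame", "end")]), ]
  df <- df[df$aa >= minAa, ]
  df[order(df$start, df$end), ]
}

# both-strand oracle in plus-strand 0-based coordinates
oracleOrfs <- function(seq, minAa, allowPartial = FALSE) {
  L <- nchar(seq)
  fwd <- oracleOrfsPlus(seq, minAa, allowPartial)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- oracleOrfsPlus(revComp(seq), minAa, allowPartial)
  if (nrow(rev)) {
    tmp <- rev$start
    rev$start <- L - rev$end
    rev$end <- L - tmp
    rev$strand <- "-"
  } else rev$strand <- character(0)
  out <- rbind(fwd, rev)
  out[order(out$start, out$end, out$strand), ]
}

# overlap-aware naive substring scan over named references, both strands
oracleHits <- function(query, refs) {
  out <- list()
  rc <- revComp(query)
  n <- nchar(query)
  for (r in names(refs)) {
    ref <- refs[[r]]
    L <- nchar(ref)
    if (n > L) next
    at <- seq_len(L - n + 1L)
    win <- substring(ref, at, at + n - 1L)
    for (p in at[win == query] - 1L)
      out[[length(out) + 1L]] <- data.frame(reference_id = r, position = p,
                                            strand = "+")
    for (p in at[win == rc] - 1L)
      out[[length(out) + 1L]] <- data.frame(reference_id = r, position = p,
                                            strand = "-")
  }
  if (length(out) == 0L)
    return(data.frame(reference_id = character(0), position = integer(0),
                      strand = character(0)))
  df <- do.call(rbind, out)
  ri <- match(df$reference_id, names(refs))
  df <- df[order(ri, df$strand == "-", df$position), ]
  rownames(df) <- NULL
  df
}

# full-scan classifier mirroring the perfect-and-unambiguous rule
oracleClassify <- function(sequence, refs, refClass) {
  h <- oracleHits(sequence, refs)
  if (nrow(h) == 0L) return("unmapped")
  if (nrow(h) >= 2L) return("ambiguous")
  cls <- refClass[[h$reference_id]]
  if (cls == "host") "host"
  else if (h$strand == "+") "virus_sense" else "virus_antisense"
}

# two-sided Fisher p by direct hypergeometric enumeration (dhyper)
oracleFisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0L, k - n):min(k, m)
  p <- dhyper(x, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(p[p <= pObs * (1 + 1e-7)])
}

# bipartition keys of an unrooted tree via a from-scratch edge traversal
oracleSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  anchor <- sort(tree$tip.label)[1L]
  keys <- character(0)
  for (node in unique(tree$edge[, 2L])) {
    if (node <= ntip) next
    side <- desc(node)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# random unrooted binary tree with positive branch lengths; its cophenetic
# matrix is additive by construction
randomAdditiveTree <- function(ntaxa) {
  tr <- ape::unroot(ape::rtree(ntaxa, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

# tiny genome/library configuration for fast end-to-end tests
smallSimConfig <- function(seed, ...) {
  args <- list(seed = seed, rna1Length = 1200L, rna2Length = 900L,
               rdrpAa = 300L, capsidAa = 150L, deltaAa = 80L, b2Aa = 55L,
               hostLength = 20000L, nAntisense = 150L, nSense = 50L,
               nHost = 800L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}
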