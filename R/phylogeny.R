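#' Read an aligned protein FASTA (MSA)
#'
#' @param path aligned FASTA; all rows must have equal length, gap symbol
#'   `-`, and there must be at least 3 uniquely labelled taxa.
#' @return named character vector of aligned rows.
#' @export
readMsa <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  msa <- stats::setNames(toupper(as.character(ss)),
                         sub("\\s.*$", "", names(ss)))
  validateMsa(msa)
  msa
}

validateMsa <- function(msa) {
  if (length(msa) < 3L) stop("an MSA needs at least 3 taxa")
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("taxa labels must be unique")
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned rows must have equal length")
  invisible(msa)
}

#' Pairwise p-distance matrix from a protein MSA
#'
#' Uncorrected p-distance with pairwise gap deletion: for each pair,
#' mismatches divided by the number of columns where neither row has a gap.
#' A Poisson correction (-log(1 - p)) is available.
#'
#' @param msa named character vector (or object accepted by [readMsa()]
#'   conventions) of equal-length aligned rows.
#' @param correction `"none"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @export
pDistanceMatrix <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (methods::is(msa, "XStringSet"))
    msa <- stats::setNames(as.character(msa), names(msa))
  validateMsa(msa)
  n <- length(msa)
  chars <- do.call(rbind, strsplit(msa, ""))
  gap <- chars == "-"
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("taxa '", names(msa)[i], "' and '", names(msa)[j],
           "' share no gap-free column")
    p <- mean(chars[i, ok] != chars[j, ok])
    if (correction == "poisson") {
      if (p >= 1) stop("p-distance 1 cannot be Poisson-corrected")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly joins the pair minimizing
#' the rate-corrected Q criterion, with deterministic tie-breaking by the
#' lowest index pair in current matrix order. Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch, preserving
#' the joined pair's path length.
#'
#' @param d symmetric numeric matrix (or `dist`) with taxa dimnames.
#' @return an unrooted `ape` `phylo` tree (trifurcating root-equivalent).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(neighborJoining(d))  # (A:1,B:1,C:3);
#' @export
neighborJoining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # internal placeholder labels keep the newick assembly safe from
  # metacharacters in taxa names; restored on the parsed tree below
  frag <- sprintf("NJTIP%dX", seq_len(n))
  D <- unname(d)
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    frag <- c(frag[keep], newFrag)
  }
  a <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  b <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  c3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmt(a), frag[2L], fmt(b),
                 frag[3L], fmt(c3))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labs[as.integer(sub("^NJTIP(\\d+)X$", "\\1",
                                        tree$tip.label))]
  tree
}

## canonical keys for the non-trivial bipartitions (splits) of an unrooted
## tree: each split is keyed by the sorted leaf set of the side NOT
## containing the alphabetically first taxon
.splitKeys <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)      # tip sets per internal node
  keys <- character(0)
  ntip <- length(tree$tip.label)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

## key of the bipartition defined by internal node `node` of `tree`
.nodeKey <- function(tree, node, partList) {
  ntip <- length(tree$tip.label)
  side <- tree$tip.label[partList[[node - ntip]]]
  if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
  anchor <- sort(tree$tip.label)[1L]
  if (anchor %in% side) side <- setdiff(tree$tip.label, side)
  paste(sort(side), collapse = "|")
}

#' Bootstrap supports for the neighbor-joining tree of an MSA
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `nReps` times, rebuilds an NJ tree per replicate, and scores
#' each internal branch of the full-data tree by the fraction of replicate
#' trees containing the same leaf bipartition. Supports (in [0, 1]) are
#' stored as internal node labels; the root-equivalent trifurcation carries
#' no label. Reproducible for a given seed; the full-data topology itself
#' does not depend on the seed.
#'
#' @param msa named character vector of aligned rows.
#' @param nReps number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice).
#' @param seed optional integer seed for column resampling.
#' @param correction distance correction, see [pDistanceMatrix()].
#' @return `phylo` tree with `node.label` supports.
#' @export
bootstrapSupport <- function(msa, nReps = 1000L, seed = NULL,
                             correction = "none") {
  if (nReps < 1L) stop("nReps must be >= 1")
  validateMsa(msa)
  full <- neighborJoining(pDistanceMatrix(msa, correction))
  L <- nchar(msa[1L])
  rows <- strsplit(msa, "")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      saved <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", saved, envir = globalenv()))
    }
    set.seed(seed)
  }
  counts <- new.env(parent = emptyenv())
  for (rep in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- vapply(rows, function(ch) paste(ch[cols], collapse = ""), "")
    names(boot) <- names(msa)
    bt <- tryCatch(neighborJoining(pDistanceMatrix(boot, correction)),
                   error = function(e) NULL)
    if (is.null(bt)) next
    for (k in .splitKeys(bt))
      assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L,
             envir = counts)
  }
  partList <- ape::prop.part(full)
  ntip <- length(full$tip.label)
  rootNode <- ntip + 1L
  labels <- character(full$Nnode)
  for (node in (ntip + 1L):(ntip + full$Nnode)) {
    if (node == rootNode) { labels[node - ntip] <- ""; next }
    k <- .nodeKey(full, node, partList)
    hits <- if (!is.na(k) && exists(k, counts)) get(k, counts) else 0L
    labels[node - ntip] <- sprintf("%.4g", hits / nReps)
  }
  full$node.label <- labels
  full
}

#' Write / read a tree in newick format
#'
#' Branch lengths are written with full precision and any bootstrap supports
#' as internal node labels. Labels containing newick metacharacters are
#' quoted automatically. `readNewickTree(writeNewickTree(t))` reproduces the
#' topology and branch lengths.
#'
#' @param tree a `phylo` object.
#' @param path optional output file; when NULL the newick string is returned.
#' @return the newick string, invisibly when written to file.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  if (is.null(tree) || !inherits(tree, "phylo") ||
      length(tree$tip.label) == 0L)
    stop("not a writable tree")
  meta <- "[][ ():;,']"      # ] first so the class parses as intended
  bad <- which(grepl(meta, tree$tip.label))
  orig <- tree$tip.label[bad]
  ph <- sprintf("VTPLACEHOLDER%dX", bad)
  tree$tip.label[bad] <- ph
  nwk <- ape::write.tree(tree, digits = 12)
  for (i in seq_along(bad))
    nwk <- sub(ph[i], sprintf("'%s'", gsub("'", "_", orig[i])), nwk,
               fixed = TRUE)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' @rdname writeNewickTree
#' @param text newick string (or give `path`).
#' @export
readNewickTree <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param d symmetric matrix with taxa dimnames.
#' @param path output file.
#' @export
writePhylipDist <- function(d, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}
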