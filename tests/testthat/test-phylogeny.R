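test_that("p-distances use pairwise gap deletion", {
  msa <- c(a = "AR-K", b = "AR-K", c = "AK-K")
  d <- pDistanceMatrix(msa)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1 / 3)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(pDistanceMatrix(c(a = "AR", b = "AK", c = "AR"))["a", "b"],
               0.5)
  expect_error(pDistanceMatrix(c(a = "A-", b = "-A", c = "AA")),
               "no gap-free column")

  # counting oracle on a random MSA
  set.seed(8)
  alpha <- c(LETTERS[1:20], "-")
  msa6 <- vapply(1:6, function(i)
    paste(sample(alpha, 100, TRUE, prob = c(rep(1, 20), 5)), collapse = ""),
    "")
  names(msa6) <- paste0("t", 1:6)
  d6 <- pDistanceMatrix(msa6)
  rows <- strsplit(msa6, "")
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- rows[[i]] != "-" & rows[[j]] != "-"
    expect_equal(d6[i, j], sum(rows[[i]][ok] != rows[[j]][ok]) / sum(ok))
  }
})

test_that("neighbor joining matches the 3-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  expect_identical(writeNewickTree(tr), "(A:1,B:1,C:3);")
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2)), "symmetric|taxa")
  dd <- d; dd[1, 2] <- 5
  expect_error(neighborJoining(dd), "symmetric")
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(101)
  for (i in 1:25) {
    tr <- randomAdditiveTree(sample(4:12, 1))
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    got <- neighborJoining(d)
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    cg <- ape::cophenetic.phylo(got)
    expect_equal(cg[rownames(d), colnames(d)], d, tolerance = 1e-9)
    # and agreement with an independent NJ implementation
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports count leaf bipartitions reproducibly", {
  set.seed(77)
  # A and B identical, far from everything else: their split cannot break
  blockA <- paste(sample(c("D", "E"), 40, TRUE), collapse = "")
  others <- vapply(1:3, function(i)
    paste(sample(c("K", "R", "S", "T"), 40, TRUE), collapse = ""), "")
  msa <- c(A = blockA, B = blockA, C = others[1], D = others[2],
           E = others[3])
  tr <- bootstrapSupport(msa, nReps = 100, seed = 5)
  key <- "A|B"
  labs <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(labs >= 0 & labs <= 1))
  # locate the (A,B) clade support via the tree structure
  part <- ape::prop.part(tr)
  ntip <- length(tr$tip.label)
  abNode <- NULL
  for (n in seq_along(part))
    if (setequal(tr$tip.label[part[[n]]], c("A", "B"))) abNode <- n
  expect_false(is.null(abNode))
  expect_equal(as.numeric(tr$node.label[abNode]), 1.0)

  # determinism under a fixed seed
  tr2 <- bootstrapSupport(msa, nReps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrapSupport(msa, nReps = 0), ">= 1")
})

test_that("supports equal an independent bipartition-counting oracle", {
  set.seed(31)
  alpha <- LETTERS[1:20]
  msa <- vapply(1:6, function(i)
    paste(sample(alpha, 60, TRUE), collapse = ""), "")
  names(msa) <- paste0("t", 1:6)
  nReps <- 40
  seed <- 99
  tr <- bootstrapSupport(msa, nReps = nReps, seed = seed)

  # independently regenerate the replicates and count splits from scratch
  L <- nchar(msa[1])
  rows <- strsplit(msa, "")
  counts <- integer(0)
  set.seed(seed)
  for (r in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- vapply(rows, function(ch) paste(ch[cols], collapse = ""), "")
    names(boot) <- names(msa)
    bt <- neighborJoining(pDistanceMatrix(boot))
    for (k in oracleSplits(bt))
      counts[k] <- (if (k %in% names(counts)) counts[k] else 0L) + 1L
  }
  part <- ape::prop.part(tr)
  ntip <- length(tr$tip.label)
  for (n in seq_along(part)) {
    lab <- tr$node.label[n]
    if (lab == "") next
    side <- tr$tip.label[part[[n]]]
    if (sort(tr$tip.label)[1] %in% side)
      side <- setdiff(tr$tip.label, side)
    k <- paste(sort(side), collapse = "|")
    hits <- if (k %in% names(counts)) counts[[k]] else 0L
    expect_equal(as.numeric(lab), hits / nReps)
  }
})

test_that("newick output round-trips topology and branch lengths", {
  set.seed(17)
  for (i in 1:20) {
    tr <- randomAdditiveTree(sample(4:10, 1))
    nwk <- writeNewickTree(tr)
    back <- readNewickTree(text = nwk)
    expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-8)
  }
  expect_error(writeNewickTree(NULL), "not a writable tree")
  # metacharacter labels are quoted and survive a round trip
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A x", "B(1)", "C"), c("A x", "B(1)", "C")))
  nwk <- writeNewickTree(neighborJoining(d))
  expect_match(nwk, "'A x'", fixed = TRUE)
})

test_that("aligned FASTA input is validated", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ARKD", ">b", "AR-D", ">c", "ARKE"), fa)
  msa <- readMsa(fa)
  expect_equal(length(msa), 3L)
  expect_equal(unname(nchar(msa)), rep(4L, 3))
  writeLines(c(">a", "ARKD", ">b", "AR"), fa)
  expect_error(readMsa(fa), "at least 3")
  writeLines(c(">a", "ARKD", ">b", "AR", ">c", "ARKE"), fa)
  expect_error(readMsa(fa), "equal length")
})
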