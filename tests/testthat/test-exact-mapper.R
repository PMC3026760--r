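test_that("index construction validates input and reports content", {
  refs <- referenceSet(virus = c(v1 = strrep("ACGT", 25)))
  idx <- buildReferenceIndex(refs, k = 4)
  expect_s4_class(idx, "KmerIndex")
  expect_equal(length(idx@refs@seqs), 1L)
  expect_error(referenceSet(virus = character(0)), "at least one")
  expect_error(referenceSet(virus = c(a = "ACGTACGTACGT",
                                      a = "ACGTACGTACGT")), "unique")
  expect_error(buildReferenceIndex(refs, k = 0), "between")
})

test_that("exact matching finds plus and minus strand occurrences", {
  idx <- buildReferenceIndex(referenceSet(virus = c(r = "ACGGTCAG")), k = 4)
  h <- findExactMatches("GGTC", idx)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 2L)
  expect_identical(h$strand, "+")

  # palindromic query: revcomp(ACGT) == ACGT, four hits in fixed order
  idx2 <- buildReferenceIndex(referenceSet(virus = c(r = "ACGTACGT")), k = 4)
  h2 <- findExactMatches("ACGT", idx2)
  expect_equal(h2$position, c(0L, 4L, 0L, 4L))
  expect_identical(h2$strand, c("+", "+", "-", "-"))

  expect_error(findExactMatches("ACGN", idx), "outside")
  expect_error(findExactMatches("ACG", idx), "shorter")
})

test_that("hit lists equal a naive all-position scan on random references", {
  set.seed(31)
  refs <- c(v1 = randNt(2000), v2 = randNt(500))
  idx <- buildReferenceIndex(referenceSet(
    virus = refs["v1"], host = refs["v2"]))
  for (i in 1:150) {
    n <- sample(18:30, 1)
    q <- if (i %% 3 == 0) randNt(n) else {
      # substrings (possibly revcomp) so that hits actually occur
      src <- refs[[sample(1:2, 1)]]
      p <- sample(nchar(src) - n, 1)
      w <- substr(src, p, p + n - 1)
      if (runif(1) < 0.5) revComp(w) else w
    }
    got <- findExactMatches(q, idx)
    exp <- oracleHits(q, refs)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("classification follows the perfect-and-unambiguous rule", {
  # virus with an embedded unique word, host sharing one word with virus
  virus <- paste0("GGGTTTCCCAAATTTGGGCCC", "ACGGACTTGACCTGCATCAGCAT",
                  "TTGGCACCGACTGGAC")
  host <- paste0("CATCATCATGGTGGTGGTAAC", "TGCAGGCCTAGGCTAACTGATC",
                 "ACGGACTTGACCTGCATCAGCAT")  # shares a 23-mer with virus
  idx <- buildReferenceIndex(referenceSet(virus = c(v = virus),
                                          host = c(h = host)))
  collapsed <- data.frame(
    sequence = c("ACGGACTTGACCTGCATCAGCA",      # virus+host -> ambiguous
                 "GGGTTTCCCAAATTTGGGCC",        # unique virus sense
                 revComp("TTGGCACCGACTGGAC"),   # unique virus antisense
                 "TGCAGGCCTAGGCTAACTGATC",      # unique host
                 "TTTTTTTTTTTTTTTTTT"),         # unmapped
    read_count = 1L, barcode = "ACGT", stringsAsFactors = FALSE)
  m <- classifySequences(collapsed, idx)
  expect_identical(m$category, c("ambiguous", "virus_sense",
                                 "virus_antisense", "host", "unmapped"))
  expect_true(all(is.na(m$position[m$category %in%
                                     c("ambiguous", "unmapped")])))
  expect_true(all(!is.na(m$position[m$category %in%
                                      c("virus_sense", "virus_antisense",
                                        "host")])))
  tal <- categoryTally(m)
  expect_equal(sum(tal), nrow(collapsed))
})

test_that("classification equals a brute-force full-scan classifier", {
  set.seed(55)
  refs <- c(v1 = randNt(1500), v2 = randNt(800), h1 = randNt(3000))
  refClass <- c(v1 = "virus", v2 = "virus", h1 = "host")
  idx <- buildReferenceIndex(referenceSet(virus = refs[1:2],
                                          host = refs[3]))
  qs <- character(200)
  for (i in seq_along(qs)) {
    n <- sample(18:30, 1)
    if (i %% 4 == 0) qs[i] <- randNt(n)
    else {
      src <- refs[[sample(1:3, 1)]]
      p <- sample(nchar(src) - n, 1)
      w <- substr(src, p, p + n - 1)
      qs[i] <- if (runif(1) < 0.5) revComp(w) else w
    }
  }
  collapsed <- data.frame(sequence = qs, read_count = 1L, barcode = "ACGT",
                          stringsAsFactors = FALSE)
  got <- classifySequences(collapsed, idx)$category
  exp <- vapply(qs, oracleClassify, "", refs = refs, refClass = refClass)
  expect_identical(unname(got), unname(exp))
})

test_that("reverse-complementing all references swaps orientations", {
  set.seed(60)
  virus <- c(v = randNt(1000))
  host <- c(h = randNt(1000))
  idx <- buildReferenceIndex(referenceSet(virus = virus, host = host))
  idxRc <- buildReferenceIndex(referenceSet(virus = revComp(virus),
                                            host = revComp(host)))
  qs <- vapply(1:60, function(i) {
    n <- sample(18:30, 1); p <- sample(1000 - n, 1)
    w <- substr(virus[[1]], p, p + n - 1)
    if (i %% 2 == 0) revComp(w) else w
  }, "")
  collapsed <- data.frame(sequence = qs, stringsAsFactors = FALSE)
  a <- classifySequences(collapsed, idx)$category
  b <- classifySequences(collapsed, idxRc)$category
  swap <- c(virus_sense = "virus_antisense",
            virus_antisense = "virus_sense", host = "host",
            ambiguous = "ambiguous", unmapped = "unmapped")
  expect_identical(unname(swap[a]), b)
})
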