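test_that("translation follows the standard code and validates input", {
  expect_identical(translateCodons("ATG"), "M")
  expect_identical(translateCodons("ATGTAA"), "M*")
  expect_identical(translateCodons("augaaa"), "MK")  # U/lowercase normalized
  expect_error(translateCodons("ATGA"), "multiple of 3")
  expect_error(translateCodons("ATGNAA"), "outside")
  set.seed(11)
  nt <- randNt(60)
  oracle <- paste(vapply(seq(1, 58, 3), function(i)
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(nt, i, i + 2)))), ""), collapse = "")
  expect_identical(translateCodons(nt), oracle)
})

test_that("scanOrfs returns maximal ATG-to-stop calls with consistent slots", {
  gr <- scanOrfs(ViralSegment("s", "ATGAAATAG"), minAa = 1)
  expect_equal(length(gr), 1L)
  expect_equal(GenomicRanges::start(gr), 1L)
  expect_equal(GenomicRanges::end(gr), 9L)
  expect_equal(S4Vectors::mcols(gr)$aaLength, 2L)
  expect_identical(S4Vectors::mcols(gr)$protein, "MK")
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")

  # nested ATG shares the stop: only the 5'-most is reported
  gr2 <- scanOrfs(ViralSegment("s", "ATGATGAAATAG"), minAa = 1)
  plus <- gr2[S4Vectors::mcols(gr2)$frame == 0L]
  expect_equal(GenomicRanges::start(plus), 1L)

  # partial 3' calls only with allowPartial
  seg <- ViralSegment("s", "ATGAAAAAA")
  expect_equal(length(scanOrfs(seg, minAa = 1, bothStrands = FALSE)), 0L)
  gp <- scanOrfs(seg, minAa = 1, allowPartial = TRUE, bothStrands = FALSE)
  expect_true(S4Vectors::mcols(gp)$partial3p)
  expect_equal(S4Vectors::mcols(gp)$aaLength, 3L)
})

test_that("ORF calls agree with a brute-force oracle on random sequences", {
  set.seed(42)
  for (i in 1:40) {
    L <- sample(100:1000, 1)
    seg <- ViralSegment("x", randNt(L))
    for (ap in c(FALSE, TRUE)) {
      got <- scanOrfs(seg, minAa = 10, allowPartial = ap)
      exp <- oracleOrfs(segmentSeq(seg), 10, allowPartial = ap)
      expect_equal(GenomicRanges::start(got) - 1L, exp$start)
      expect_equal(GenomicRanges::end(got), exp$end)
      expect_equal(as.character(GenomicRanges::strand(got)), exp$strand)
      expect_equal(S4Vectors::mcols(got)$aaLength, exp$aa)
      expect_equal(S4Vectors::mcols(got)$partial3p, exp$partial)
    }
  }
})

test_that("stored proteins reproduce by translating the ORF range", {
  set.seed(7)
  seg <- ViralSegment("x", randNt(800))
  gr <- scanOrfs(seg, minAa = 5, allowPartial = TRUE)
  L <- nchar(segmentSeq(seg))
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    nt <- substr(segmentSeq(seg), s, e)
    if (as.character(GenomicRanges::strand(gr))[i] == "-") nt <- revComp(nt)
    aa <- translateCodons(nt)
    m <- S4Vectors::mcols(gr)[i, ]
    if (m$partial3p) expect_identical(aa, m$protein)
    else expect_identical(aa, paste0(m$protein, "*"))
  }
})

test_that("reverse-complementing a segment mirrors ORF coordinates", {
  set.seed(13)
  seq <- randNt(600)
  L <- nchar(seq)
  a <- scanOrfs(ViralSegment("x", seq), minAa = 8)
  b <- scanOrfs(ViralSegment("x", revComp(seq)), minAa = 8)
  flip <- data.frame(start = L - GenomicRanges::end(b),
                     end = L + 1L - GenomicRanges::start(b),
                     strand = ifelse(as.character(
                       GenomicRanges::strand(b)) == "+", "-", "+"))
  flip <- flip[order(flip$start, flip$end, flip$strand), ]
  expect_equal(GenomicRanges::start(a) - 1L, flip$start)
  expect_equal(GenomicRanges::end(a), flip$end + 0L)
  expect_equal(as.character(GenomicRanges::strand(a)), flip$strand)
})

test_that("a planted +1-frame ORF overlapping the anchor C-terminus is found", {
  # main ORF 0..300 (0-based half-open), planted 20-aa ORF in frame 1 at
  # 250..313, constructed by hand on a GAA-repeat backbone
  chars <- strsplit(paste0("ATG", strrep("GAA", 98), "TAA",
                           "GAAGAAGAAG", "TAA", strrep("C", 87)), "")[[1]]
  chars[251:253] <- c("A", "T", "G")
  seq <- paste(chars, collapse = "")
  seg <- ViralSegment("s", seq)
  orfs <- scanOrfs(seg, minAa = 20)
  anchor <- orfs[S4Vectors::mcols(orfs)$frame == 0L &
                 GenomicRanges::start(orfs) == 1L]
  expect_equal(GenomicRanges::end(anchor), 300L)
  hit <- findOverlappingPlus1Orf(orfs, anchor, minAa = 20, ctermWindow = 100)
  expect_equal(length(hit), 1L)
  expect_equal(GenomicRanges::start(hit), 251L)
  expect_equal(GenomicRanges::end(hit), 313L)
  expect_equal(S4Vectors::mcols(hit)$frame, 1L)
  expect_equal(S4Vectors::mcols(hit)$aaLength, 20L)
  # the same search with a window that misses the overlap returns empty
  none <- findOverlappingPlus1Orf(orfs, anchor, minAa = 21, ctermWindow = 100)
  expect_equal(length(none), 0L)
})

test_that("organization classification recovers planted genome features", {
  # conventional 1.4-kb RNA2 with a single 5' ORF: no delta, not oversize
  cfg <- simConfig(seed = 3, rna2Length = 1400L, capsidAa = 380L,
                   plantDelta = FALSE)
  gen <- simulateViralGenome(cfg)
  rep <- classifyOrganization(gen$segments)
  expect_equal(length(rep@orfDeltaCandidate), 0L)
  expect_false(rep@rna2Oversize)
  expect_equal(unname(rep@roles), c("RNA1", "RNA2"))

  # planted B2 and delta flags recovered across seeds
  for (seed in 1:8) {
    pb <- seed %% 2L == 0L
    gen <- simulateViralGenome(simConfig(seed = seed, plantB2 = pb,
                                         plantDelta = !pb))
    rep <- classifyOrganization(gen$segments)
    expect_equal(length(rep@b2Like) == 1L, pb)
    expect_equal(length(rep@orfDeltaCandidate) == 1L, !pb)
    expect_true(rep@rna2Oversize)
    if (pb) {
      expect_equal(GenomicRanges::start(rep@b2Like), gen$truth$b2$start)
      expect_equal(GenomicRanges::end(rep@b2Like), gen$truth$b2$end)
    } else {
      expect_equal(S4Vectors::mcols(rep@orfDeltaCandidate)$aaLength,
                   gen$truth$delta$aaLength)
    }
  }
  expect_error(classifyOrganization(rep(gen$segments, 2)), "1 or 2")
})

test_that("FASTA and GenBank readers normalize sequences", {
  segs <- list(ViralSegment("a", "ATGAAATAG"), ViralSegment("b", "ACGTACGT"))
  fa <- tempfile(fileext = ".fa")
  writeFastaSegments(segs, fa)
  back <- readFastaSegments(fa)
  expect_identical(vapply(back, segmentSeq, ""),
                   vapply(segs, segmentSeq, ""))
  expect_identical(vapply(back, segmentId, ""), c("a", "b"))

  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREC    24 bp  RNA  linear  VRL 01-JAN-2010",
    "DEFINITION  synthetic test record.",
    "ORIGIN",
    "        1 augaaauccg gcaaauagac gaua",
    "//"), gb)
  seg <- readGenbankSeq(gb)
  expect_identical(segmentId(seg), "TESTREC")
  expect_identical(segmentSeq(seg), "ATGAAATCCGGCAAATAGACGATA")
  expect_error(ViralSegment("x", "ACGRT"), "outside")
})
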