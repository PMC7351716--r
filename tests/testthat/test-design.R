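params38 <- designParams()

test_that("tiling splits a region into contiguous binding-length tiles and
           drops the remainder", {
  set.seed(1)
  target <- randomSeq(150)

  # 76 nt -> exactly two tiles, alternating strands
  r76 <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, 76))
  tiles <- tileRegion(target, r76, params38)
  expect_equal(length(tiles), 2L)
  expect_equal(GenomicRanges::start(tiles), c(1L, 39L))
  expect_equal(GenomicRanges::end(tiles), c(38L, 76L))
  expect_equal(S4Vectors::mcols(tiles)$boundStrand,
               c("sense", "antisense"))

  # exactly one binding length -> one tile on the start strand
  r38 <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, 38))
  one <- tileRegion(target, r38, params38)
  expect_equal(length(one), 1L)
  expect_equal(S4Vectors::mcols(one)$boundStrand, "sense")

  # 100 nt -> floor(100/38) = 2 tiles, 24-nt remainder dropped
  r100 <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, 100))
  t100 <- tileRegion(target, r100, params38)
  expect_equal(length(t100), 2L)
  expect_equal(max(GenomicRanges::end(t100)), 76L)

  # too-short region is a design error
  rShort <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, 37))
  expect_error(tileRegion(target, rShort, params38), "shorter")
})

test_that("tiles never overlap, stay inside the region, and alternate
           strands (or not) as configured", {
  set.seed(2)
  target <- randomSeq(1000)
  for (alt in c(TRUE, FALSE)) {
    p <- designParams(alternate = alt, startStrand = "antisense")
    region <- GenomicRanges::GRanges("t1", IRanges::IRanges(21, 950))
    tiles <- tileRegion(target, region, p)
    expect_true(all(GenomicRanges::start(tiles) >= 21,
                    GenomicRanges::end(tiles) <= 950))
    expect_false(any(IRanges::countOverlaps(tiles, tiles) > 1L))
    strands <- S4Vectors::mcols(tiles)$boundStrand
    expect_equal(strands[1], "antisense")
    if (alt) {
      expect_true(all(strands[-1] != strands[-length(strands)]))
    } else {
      expect_true(all(strands == "antisense"))
    }
  }
})

test_that("catcher domains follow the bound-strand rule and concatenate
           5'->3'", {
  p0 <- designParams(releaseLen = 0L)
  polyA <- strrep("A", 38)
  tile <- tileRegion(polyA, params = p0, targetId = "t1")
  cs <- buildCatcher(polyA, tile, p0)
  expect_equal(as.character(cs@bindingSite), strrep("T", 38))
  # no toehold: full sequence is binding + adapter = 38 + 22 = 60 nt
  expect_equal(length(fullSequence(cs)), 60L)
  expect_equal(as.character(fullSequence(cs)),
               paste0(strrep("T", 38), as.character(defaultAdapter())))

  # antisense-bound catcher carries the sense segment verbatim
  set.seed(3)
  target <- randomSeq(76)
  p <- designParams(startStrand = "antisense")
  tiles <- tileRegion(target, params = p, targetId = "t1")
  csA <- buildCatcher(target, tiles[1], p,
                      releaseSite = Biostrings::DNAString("ACGTACGTAC"))
  expect_equal(as.character(csA@bindingSite), substr(target, 1, 38))
  expect_equal(length(fullSequence(csA)), 10L + 38L + 22L)
})

test_that("release strands are the reverse complement of toehold plus
           binding site", {
  p <- designParams()
  target <- strrep("C", 38)  # sense-bound binding site = G x 38
  tile <- tileRegion(target, params = p, targetId = "t1")
  cs <- buildCatcher(target, tile, p,
                     releaseSite = Biostrings::DNAString("AAAAAAAAAA"))
  rs <- designReleaseStrand(cs)
  expect_equal(length(rs), 48L)  # 10 + 38 at defaults
  expect_equal(as.character(rs), paste0(strrep("C", 38), strrep("T", 10)))
  # complementary base-by-base to the catcher's first releaseLen+bindingLen
  expect_equal(as.character(Biostrings::reverseComplement(rs)),
               substr(as.character(fullSequence(cs)), 1, 48))

  # denaturation-only catchers have no addressable release strand
  p0 <- designParams(releaseLen = 0L)
  cs0 <- buildCatcher(target, tileRegion(target, params = p0,
                                         targetId = "t1"), p0)
  expect_error(designReleaseStrand(cs0), "denaturation")
})

test_that("library design tiles a 760-nt target into 20 alternating
           catchers with unique binding sites and one shared adapter", {
  set.seed(7)
  tg <- Biostrings::DNAStringSet(setNames(randomSeq(760), "g1"))
  csl <- designCSL(tg, seed = 11)
  expect_equal(length(csl), 20L)  # floor(760 / 38)
  strands <- S4Vectors::mcols(targetIntervals(csl))$boundStrand
  expect_true(all(strands == rep_len(c("sense", "antisense"), 20L)))
  sites <- as.character(bindingSites(csl))
  expect_equal(anyDuplicated(sites), 0L)
  expect_equal(length(unique(vapply(catchers(csl), function(x)
    as.character(x@adapter), character(1)))), 1L)
  # every toehold respects the complementarity cap against the target
  for (rs in as.character(releaseSites(csl))) {
    expect_lte(longestSharedSubstring(rs, tg[[1]],
                                      bothStrands = TRUE)$length,
               designParamsOf(csl)@releaseMaxComplement)
  }
})

test_that("library design is deterministic and duplicate targets collide", {
  set.seed(8)
  tg <- Biostrings::DNAStringSet(setNames(randomSeq(200), "g1"))
  a <- designCSL(tg, seed = 4)
  b <- designCSL(tg, seed = 4)
  expect_equal(as.character(fullSequences(a)),
               as.character(fullSequences(b)))

  # two identical target sequences force a binding-site collision
  dup <- Biostrings::DNAStringSet(c(g1 = as.character(tg[[1]]),
                                    g2 = as.character(tg[[1]])))
  expect_error(designCSL(dup, seed = 4), "duplicate binding sites")

  # empty region set -> empty library
  empty <- designCSL(tg, regions = GenomicRanges::GRanges(), seed = 4)
  expect_equal(length(empty), 0L)
})

test_that("off-target screen flags an embedded targeted segment but not a
           short share", {
  set.seed(9)
  tg <- Biostrings::DNAStringSet(setNames(randomSeq(380), "g1"))
  csl <- designCSL(tg, seed = 2)
  # readthrough-style transcript embedding a targeted 38-nt segment
  seg <- substr(as.character(tg[[1]]), 39, 76)
  readthrough <- paste0(randomSeq(60), seg, randomSeq(60))
  # and a transcript sharing only a 10-mer with a binding site
  tenmer <- substr(rcChar(as.character(bindingSites(csl)[[1]])), 5, 14)
  shorty <- paste0(randomSeq(40), tenmer, randomSeq(40))
  txome <- Biostrings::DNAStringSet(c(rt1 = readthrough, s1 = shorty))
  hits <- screenOfftargets(csl, txome, k = 16L)
  expect_true(any(hits$transcript == "rt1" & hits$sharedLen >= 38L))
  expect_false(any(hits$transcript == "s1"))
  # hits come sorted by decreasing shared length
  expect_true(!is.unsorted(rev(hits$sharedLen)))

  # empty library -> empty hit list
  emptyCsl <- designCSL(tg, regions = GenomicRanges::GRanges(), seed = 2)
  expect_equal(nrow(screenOfftargets(emptyCsl, txome, k = 16L)), 0L)
})

test_that("each binding site maps back to exactly its own design locus", {
  set.seed(10)
  tg <- Biostrings::DNAStringSet(setNames(randomSeq(500), "g1"))
  csl <- designCSL(tg, seed = 3)
  hits <- screenOfftargets(csl, tg, k = designParamsOf(csl)@bindingLen,
                           excludeDesigned = FALSE)
  expect_equal(nrow(hits), length(csl))
  iv <- targetIntervals(csl)
  for (i in seq_len(nrow(hits))) {
    locus <- iv[hits$catcher[i]]
    expect_equal(hits$startTranscript[i], GenomicRanges::start(locus))
    expect_equal(hits$sharedLen[i], GenomicRanges::width(locus))
  }
})

test_that("order sheets round-trip every sequence and are byte-identical
           for identical libraries", {
  set.seed(12)
  tg <- Biostrings::DNAStringSet(setNames(randomSeq(120), "g1"))
  csl <- designCSL(tg, seed = 6)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  exportOrderSheet(csl, f1)
  exportOrderSheet(designCSL(tg, seed = 6), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)), length(csl) + 1L)  # header + rows

  back <- readOrderSheet(f1)
  expect_equal(as.character(fullSequences(back)),
               as.character(fullSequences(csl)))
  expect_equal(as.character(bindingSites(back)),
               as.character(bindingSites(csl)))
  expect_equal(catcherNames(back), catcherNames(csl))

  # release sheet for a toehold-less library is empty, with a warning
  p0 <- designParams(releaseLen = 0L)
  csl0 <- designCSL(tg, params = p0, seed = 6)
  fr <- withr::local_tempfile(fileext = ".tsv")
  fo <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(exportOrderSheet(csl0, fo, releaseFile = fr),
                 "empty release sheet")
  expect_equal(nrow(read.table(fr, header = TRUE, sep = "\t")), 0L)
})
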