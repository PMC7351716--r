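#' Construct a synthetic-data configuration
#'
#' Defaults emulate the study conditions at desk scale: cDNA-style
#' fragments of 150-700 nt, 1e5 fragments per simulated library, and an
#' optionally "dominated" abundance model in which a few genes consume a
#' large fraction of reads, as the high-abundance targets do in the
#' motivating pancreatic libraries.
#'
#' @param seed Integer RNG seed (default 1).
#' @param nGenes Number of synthetic transcripts (default 20).
#' @param lengthRange Transcript length bounds in nt (default 500-2000).
#' @param abundance `"uniform"` or `"dominated"`.
#' @param dominantFraction Read mass fraction of the dominant gene under
#'   `"dominated"` (default 0.5).
#' @param fragmentRange Fragment length bounds in nt (default 150-700).
#' @param reads Total fragment count (default 1e5).
#' @return A [FixtureConfig-class].
#' @examples
#' fixtureConfig(seed = 42)
#' @export
fixtureConfig <- function(seed = 1L, nGenes = 20L,
                          lengthRange = c(500L, 2000L),
                          abundance = c("uniform", "dominated"),
                          dominantFraction = 0.5,
                          fragmentRange = c(150L, 700L),
                          reads = 100000L) {
  abundance <- match.arg(abundance)
  new("FixtureConfig", seed = as.integer(seed), nGenes = as.integer(nGenes),
      lengthRange = as.integer(lengthRange), abundance = abundance,
      dominantFraction = dominantFraction,
      fragmentRange = as.integer(fragmentRange), reads = as.integer(reads))
}

.randomSeq <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# uniform integer draw over an inclusive range (safe for lo == hi)
.sampleRange <- function(range, n)
  range[1L] + sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) - 1L

#' Generate a seeded toy transcriptome
#'
#' Uniform-composition random transcripts. Optionally embeds a shared
#' segment of the first gene into the second, emulating a readthrough
#' transcript that carries a targeted sequence and is therefore co-captured
#' by an off-target-unaware probe library. The copied segment is aligned to
#' the default tiling frame (tiles of `sharedLen` from base 1), so a
#' full-length binding site of a library designed on gene 1 recurs verbatim
#' in gene 2.
#'
#' @param config A [FixtureConfig-class].
#' @param embedShared Embed a shared segment of gene 1 into gene 2.
#' @param sharedLen Length of the shared segment (default 38 nt).
#' @return Named `DNAStringSet` (`gene01`, `gene02`, ...); byte-identical
#'   for identical configs.
#' @examples
#' makeTranscriptome(fixtureConfig(seed = 1, nGenes = 3))
#' @export
makeTranscriptome <- function(config = fixtureConfig(),
                              embedShared = FALSE, sharedLen = 38L) {
  stopifnot(is(config, "FixtureConfig"))
  if (config@nGenes == 0L) return(DNAStringSet())
  .withSeed(config@seed, {
    lens <- .sampleRange(config@lengthRange, config@nGenes)
    seqs <- vapply(lens, .randomSeq, character(1))
    names(seqs) <- sprintf("gene%02d", seq_len(config@nGenes))
    if (embedShared && config@nGenes >= 2L) {
      if (lens[1L] < sharedLen || lens[2L] < sharedLen)
        stop("transcripts too short to embed a ", sharedLen, "-nt segment")
      # align the copied segment to the default probe tiling frame
      # (tiles of sharedLen starting at base 1) so a full binding site of
      # a library designed on gene 1 is embedded verbatim in gene 2
      from <- (sample.int((lens[1L] - sharedLen) %/% sharedLen + 1L, 1L) -
                 1L) * sharedLen + 1L
      at <- sample.int(lens[2L] - sharedLen + 1L, 1L)
      seg <- substr(seqs[1L], from, from + sharedLen - 1L)
      substr(seqs[2L], at, at + sharedLen - 1L) <- seg
    }
    DNAStringSet(seqs)
  })
}

#' Generate a 10-member ssDNA mixture
#'
#' Ten members named A-J with lengths drawn from 20-190 nt and equal
#' molecule counts, emulating the multiplexed catch-and-release test
#' library. Members are rejection-sampled so that no pair (on either
#' strand) shares a complementary stretch of `maxCross` nt or more -
#' a catcher addressing one member then cannot capture another.
#'
#' @param config A [FixtureConfig-class] (only `seed` is used).
#' @param moleculesPerMember Molecule count per member (default 1e5).
#' @param maxCross Maximum tolerated inter-member complementarity minus
#'   one; pairs sharing >= `maxCross` nt are rejected (default 16).
#' @return A [MixtureSet-class] of 10 single-stranded members.
#' @examples
#' makeSsdnaLibrary(fixtureConfig(seed = 3))
#' @export
makeSsdnaLibrary <- function(config = fixtureConfig(),
                             moleculesPerMember = 100000L,
                             maxCross = 16L) {
  stopifnot(is(config, "FixtureConfig"))
  .withSeed(config@seed, {
    lens <- sort(sample(20:190, 10L, replace = TRUE), decreasing = TRUE)
    seqs <- character(0)
    for (len in lens) {
      repeat {
        cand <- .randomSeq(len)
        ok <- all(vapply(seqs, function(s)
          longestSharedSubstring(cand, s, bothStrands = TRUE)$length <
            maxCross, logical(1)))
        if (ok) break
      }
      seqs <- c(seqs, cand)
    }
    names(seqs) <- LETTERS[1:10]
    mixtureSet(seqs, molecules = moleculesPerMember, duplex = FALSE)
  })
}

#' Sample a cDNA-style fragment pool from a transcriptome
#'
#' Fragments are assigned to transcripts by the abundance model (uniform,
#' or dominated with the first gene taking `dominantFraction` of the
#' mass), start uniformly within the transcript, and have lengths uniform
#' in `fragmentRange`, truncated at the transcript end.
#'
#' @param transcriptome Named `DNAStringSet`.
#' @param config A [FixtureConfig-class].
#' @return `GRanges` of fragment origin intervals (seqlengths set to the
#'   transcript lengths).
#' @export
makeFragmentLibrary <- function(transcriptome, config = fixtureConfig()) {
  stopifnot(is(config, "FixtureConfig"), length(transcriptome) > 0L)
  lens <- setNames(width(transcriptome), names(transcriptome))
  if (config@fragmentRange[1L] > max(lens))
    stop("minimum fragment length exceeds the longest transcript")
  .withSeed(config@seed, {
    w <- if (config@abundance == "dominated" && length(lens) > 1L) {
      c(config@dominantFraction,
        rep((1 - config@dominantFraction) / (length(lens) - 1L),
            length(lens) - 1L))
    } else rep(1 / length(lens), length(lens))
    gene <- sample(names(lens), config@reads, replace = TRUE, prob = w)
    fragLen <- .sampleRange(config@fragmentRange, config@reads)
    starts <- floor(runif(config@reads) * lens[gene]) + 1L
    ends <- pmin(starts + fragLen - 1L, lens[gene])
    gr <- GRanges(gene, IRanges(starts, ends),
                  seqlengths = lens[sort(names(lens))])
    gr
  })
}

#' Simulate a depletion experiment at coverage level
#'
#' The control track is the per-base pileup of all fragments. For the
#' treated track, every fragment overlapping a binding-site interval of
#' the library by at least `minMatch` bases is removed independently with
#' probability `e` (the per-molecule capture probability); the pileup of
#' the survivors is the treated coverage. Bases inside targeted regions
#' are depleted by about `e`; depletion decays over roughly one fragment
#' length beyond a region boundary, because progressively fewer of the
#' fragments covering those bases also reach into the targeted region -
#' the distance-decay seen in per-base depletion profiles.
#'
#' @param fragments `GRanges` from [makeFragmentLibrary()] (seqlengths
#'   required).
#' @param csl A [CatcherLibrary-class]; its catchers' target intervals
#'   define the capturable regions.
#' @param e Per-fragment capture probability in `[0, 1]`.
#' @param minMatch Minimum overlap (bases) with a binding-site interval
#'   for a fragment to be capturable (default 20).
#' @param seed Integer seed.
#' @return List with `control` and `treated` (integer `RleList` per-base
#'   coverage, one element per transcript), and `removed` (logical
#'   per-fragment removal manifest).
#' @export
simulateDepletedCoverage <- function(fragments, csl, e, minMatch = 20L,
                                     seed = 1L) {
  stopifnot(is(fragments, "GRanges"), is(csl, "CatcherLibrary"),
            e >= 0, e <= 1)
  sl <- GenomeInfoDb::seqlengths(fragments)
  if (any(is.na(sl))) stop("fragments must carry seqlengths")
  sites <- targetIntervals(csl)
  capturable <- if (length(sites))
    overlapsAny(fragments, sites, minoverlap = minMatch) else
      rep(FALSE, length(fragments))
  removed <- .withSeed(seed,
                       capturable & runif(length(fragments)) < e)
  control <- coverage(fragments)
  treated <- coverage(fragments[!removed])
  list(control = control, treated = treated, removed = removed)
}

#' Transcripts of a library with no targeted interval
#'
#' Convenience for library-size normalization: the transcript ids among
#' `transcripts` that no catcher of `csl` targets.
#'
#' @param transcripts Character vector of transcript ids.
#' @param csl A [CatcherLibrary-class].
#' @return Character vector.
#' @export
untargetedTranscripts <- function(transcripts, csl) {
  setdiff(transcripts,
          unique(as.character(seqnames(targetIntervals(csl)))))
}
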