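#' Default 22-nt adapter domain
#'
#' A fixed synthetic 22-nt adapter used when no adapter is supplied. In a
#' real library the adapter is dictated by the anchor strand grafted to the
#' polymer; this constant is a placeholder with balanced composition so that
#' designs are reproducible out of the box. Replace it with the complement
#' of your anchor strand for wet-lab use.
#'
#' @return A 22-nt `DNAString`.
#' @export
defaultAdapter <- function() DNAString("GTAACGATCCAGCTGTCACTTG")

#' Construct design parameters
#'
#' @param bindingLen Binding-site length in nt (default 38).
#' @param adapterSeq Adapter domain (default [defaultAdapter()], 22 nt).
#' @param releaseLen Toehold length in nt, 0 to omit (default 10; typical
#'   TMSD toeholds are 6-10 nt).
#' @param alternate Alternate sense/antisense binding along a region.
#' @param startStrand Strand bound by the first tile.
#' @param tileStep Step between tile starts (default `bindingLen`:
#'   contiguous, non-overlapping).
#' @param minOfftargetK Default off-target screen threshold (nt).
#' @param releaseMaxComplement Max tolerated toehold/target complementarity.
#' @return A [DesignParams-class] object.
#' @examples
#' designParams()
#' @export
designParams <- function(bindingLen = 38L, adapterSeq = defaultAdapter(),
                         releaseLen = 10L, alternate = TRUE,
                         startStrand = c("sense", "antisense"),
                         tileStep = bindingLen, minOfftargetK = 16L,
                         releaseMaxComplement = 6L) {
  startStrand <- match.arg(startStrand)
  new("DesignParams",
      bindingLen = as.integer(bindingLen),
      adapterSeq = asDNA(adapterSeq, "adapterSeq"),
      releaseLen = as.integer(releaseLen),
      alternate = isTRUE(alternate),
      startStrand = startStrand,
      tileStep = as.integer(tileStep),
      minOfftargetK = as.integer(minOfftargetK),
      releaseMaxComplement = as.integer(releaseMaxComplement))
}

.otherStrand <- function(s) ifelse(s == "sense", "antisense", "sense")

#' Tile a target region with binding-site intervals
#'
#' Splits a region into contiguous tiles of exactly `bindingLen` nt starting
#' at the region start, assigning the strand each catcher will bind.
#' When `alternate` is on, consecutive tiles bind opposite target strands
#' (starting with `startStrand`) so that re-hybridization of the sense and
#' antisense strands of a denatured duplex target is blocked from both
#' sides and fragmented targets are still caught. A trailing remainder
#' shorter than `bindingLen` is dropped, so the tile count is
#' `floor(regionLength / bindingLen)` at the default step.
#'
#' @param target Target sequence (`DNAString` or character).
#' @param region Length-1 `GRanges` on the target (1-based closed, as
#'   returned by [readRegions()]); `NULL` tiles the full length.
#' @param params [DesignParams-class].
#' @param targetId Transcript id used when `region` is `NULL`.
#' @return `GRanges` of tiles with metadata column `boundStrand`.
#' @examples
#' p <- designParams()
#' tileRegion(paste(rep("ACGT", 19), collapse = ""), params = p,
#'            targetId = "t1")
#' @export
tileRegion <- function(target, region = NULL, params = designParams(),
                       targetId = "target") {
  target <- asDNA(target, "target")
  if (is.null(region))
    region <- GRanges(targetId, IRanges(1L, length(target)))
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (end(region) > length(target))
    stop("region extends beyond the target sequence")
  len <- width(region)
  if (len < params@bindingLen)
    stop("region (", len, " nt) shorter than bindingLen (",
         params@bindingLen, " nt)")
  starts <- seq.int(start(region), end(region) - params@bindingLen + 1L,
                    by = params@tileStep)
  tiles <- GRanges(as.character(seqnames(region)),
                   IRanges(starts, width = params@bindingLen))
  strands <- if (params@alternate) {
    rep_len(c(params@startStrand, .otherStrand(params@startStrand)),
            length(tiles))
  } else rep_len(params@startStrand, length(tiles))
  mcols(tiles)$boundStrand <- strands
  tiles
}

# Seeded toehold generation: rejection-sample a releaseLen-mer whose longest
# exact complementarity with any target (either strand) stays below the cap,
# so the toehold remains single-stranded in the presence of the targets.
# Falls back to the least-complementary candidate seen, with a warning.
.makeToehold <- function(releaseLen, targets, cap, tries = 200L) {
  if (releaseLen == 0L) return(DNAString(""))
  best <- NULL
  bestLen <- Inf
  for (i in seq_len(tries)) {
    cand <- DNAString(paste(sample(c("A", "C", "G", "T"), releaseLen,
                                   replace = TRUE), collapse = ""))
    worst <- 0L
    for (t in seq_along(targets)) {
      worst <- max(worst, longestSharedSubstring(cand, targets[[t]],
                                                 bothStrands = TRUE)$length)
      if (worst > cap && worst >= bestLen) break
    }
    if (worst <= cap) return(cand)
    if (worst < bestLen) { best <- cand; bestLen <- worst }
  }
  warning("could not sample a toehold with <= ", cap,
          "-nt target complementarity; using best candidate (", bestLen,
          " nt shared)")
  best
}

# Evaluate expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Assemble a three-domain catcher strand for one tile
#'
#' Computes the binding site from the bound strand (sense-bound: reverse
#' complement of the sense segment; antisense-bound: the sense segment
#' verbatim) and concatenates release site, binding site and adapter
#' 5'->3'. The toehold sits at the free 5' end, away from the
#' anchor-hybridized adapter, where a release strand can nucleate.
#'
#' @param target Target sequence.
#' @param tile Length-1 `GRanges` with a `boundStrand` metadata column, as
#'   produced by [tileRegion()].
#' @param params [DesignParams-class].
#' @param releaseSite Toehold `DNAString`; `NULL` generates one (seeded by
#'   the caller's RNG state) or omits it when `releaseLen` is 0.
#' @param name Catcher name; default derived from the locus.
#' @return A [CatcherStrand-class] object.
#' @examples
#' p <- designParams(releaseLen = 0L)
#' tl <- tileRegion(strrep("A", 38), params = p, targetId = "t1")
#' buildCatcher(strrep("A", 38), tl, p)
#' @export
buildCatcher <- function(target, tile, params = designParams(),
                         releaseSite = NULL, name = NULL) {
  target <- asDNA(target, "target")
  stopifnot(is(tile, "GRanges"), length(tile) == 1L,
            !is.null(mcols(tile)$boundStrand))
  if (length(params@adapterSeq) == 0L)
    stop("adapter sequence is missing")
  boundStrand <- mcols(tile)$boundStrand
  senseSeg <- subseq(target, start(tile), end(tile))
  bindingSite <- if (boundStrand == "sense") reverseComplement(senseSeg)
                 else senseSeg
  if (is.null(releaseSite)) {
    releaseSite <- .makeToehold(params@releaseLen, DNAStringSet(target),
                                params@releaseMaxComplement)
  } else if (length(releaseSite) == 0L || params@releaseLen == 0L) {
    releaseSite <- DNAString("")
  }
  if (is.null(name))
    name <- sprintf("%s_%d_%d_%s", as.character(seqnames(tile)),
                    start(tile) - 1L, end(tile),
                    ifelse(boundStrand == "sense", "s", "as"))
  new("CatcherStrand", name = name, targetInterval = granges(tile),
      boundStrand = boundStrand, bindingSite = bindingSite,
      adapter = params@adapterSeq, releaseSite = asDNA0(releaseSite))
}

# allow empty DNAString through validation
asDNA0 <- function(x) {
  s <- if (is(x, "DNAString")) x else DNAString(toupper(as.character(x)))
  if (length(s) == 0L) return(s)
  asDNA(s, "release site")
}

#' Full 5'->3' sequence of a catcher strand
#'
#' @param catcher A [CatcherStrand-class].
#' @return `DNAString`: release site, binding site, adapter concatenated.
#' @export
fullSequence <- function(catcher) {
  stopifnot(is(catcher, "CatcherStrand"))
  DNAString(xscat(catcher@releaseSite, catcher@bindingSite,
                  catcher@adapter))
}

#' Design a catcher strand library over one or more target regions
#'
#' Tiles every region, assembles a catcher per tile, generates toeholds from
#' a seeded generator, and validates the library invariants: one shared
#' adapter, pairwise-distinct binding sites (so each catcher addresses a
#' unique locus), and non-overlapping intervals per target. Output order is
#' deterministic (by target, then coordinate), so identical inputs yield
#' byte-identical order sheets.
#'
#' @param targets Named `DNAStringSet` (or FASTA path) of target sequences.
#' @param regions `GRanges` of regions to tile (seqnames must name targets);
#'   `NULL` tiles every target full-length. An empty `GRanges` yields an
#'   empty library.
#' @param params [DesignParams-class].
#' @param seed Integer seed for toehold generation (default 1).
#' @return A [CatcherLibrary-class].
#' @examples
#' set.seed(7)
#' tg <- DNAStringSet(c(g1 = paste(sample(c("A","C","G","T"), 760,
#'                                        TRUE), collapse = "")))
#' csl <- designCSL(tg)
#' length(csl)
#' @export
designCSL <- function(targets, regions = NULL, params = designParams(),
                      seed = 1L) {
  if (is.character(targets) && length(targets) == 1L &&
      file.exists(targets))
    targets <- readTargets(targets)
  targets <- .asDNASet(targets, "targets")
  if (is.null(names(targets)) || anyDuplicated(names(targets)))
    stop("targets must have unique names")
  if (is.null(regions)) {
    regions <- GRanges(names(targets), IRanges(1L, width(targets)))
  }
  stopifnot(is(regions, "GRanges"))
  bad <- setdiff(as.character(seqnames(regions)), names(targets))
  if (length(bad))
    stop("regions reference unknown targets: ", paste(bad, collapse = ", "))
  regions <- regions[order(as.character(seqnames(regions)), start(regions))]
  for (tid in unique(as.character(seqnames(regions)))) {
    rr <- regions[seqnames(regions) == tid]
    if (length(rr) > 1L && any(IRanges::countOverlaps(rr, rr) > 1L))
      stop("regions on target '", tid, "' overlap")
  }
  catchers <- .withSeed(seed, {
    out <- list()
    for (i in seq_along(regions)) {
      tid <- as.character(seqnames(regions)[i])
      tiles <- tileRegion(targets[[tid]], regions[i], params,
                          targetId = tid)
      for (j in seq_along(tiles)) {
        toehold <- .makeToehold(params@releaseLen, targets,
                                params@releaseMaxComplement)
        out[[length(out) + 1L]] <-
          buildCatcher(targets[[tid]], tiles[j], params,
                       releaseSite = toehold)
      }
    }
    out
  })
  sites <- vapply(catchers, function(x) as.character(x@bindingSite),
                  character(1))
  if (anyDuplicated(sites)) {
    dup <- unique(sites[duplicated(sites)])
    who <- vapply(catchers, function(x) x@name, character(1))
    stop("duplicate binding sites across regions (each catcher must have ",
         "a unique binding site): ",
         paste(vapply(dup, function(s)
           paste(who[sites == s], collapse = " == "), character(1)),
           collapse = "; "))
  }
  new("CatcherLibrary", catchers = catchers, params = params,
      targets = regions)
}

#' @describeIn CatcherLibrary-class Number of catchers in the library.
#' @param x A `CatcherLibrary`.
#' @export
setMethod("length", "CatcherLibrary", function(x) length(x@catchers))

#' Accessors for catcher strand libraries
#'
#' `catchers()` returns the list of [CatcherStrand-class] members,
#' `catcherNames()` their names, `bindingSites()` / `releaseSites()` /
#' `fullSequences()` the respective domains as named `DNAStringSet`s,
#' `targetIntervals()` the per-catcher target loci as a `GRanges` (with
#' `boundStrand` metadata), and `designParamsOf()` the [DesignParams-class]
#' used.
#'
#' @param csl A [CatcherLibrary-class].
#' @return See the individual descriptions.
#' @name csl-accessors
NULL

#' @rdname csl-accessors
#' @export
catchers <- function(csl) csl@catchers

#' @rdname csl-accessors
#' @export
catcherNames <- function(csl)
  vapply(csl@catchers, function(x) x@name, character(1))

#' @rdname csl-accessors
#' @export
bindingSites <- function(csl) {
  out <- DNAStringSet(lapply(csl@catchers, function(x) x@bindingSite))
  names(out) <- catcherNames(csl)
  out
}

#' @rdname csl-accessors
#' @export
releaseSites <- function(csl) {
  out <- DNAStringSet(lapply(csl@catchers, function(x) x@releaseSite))
  names(out) <- catcherNames(csl)
  out
}

#' @rdname csl-accessors
#' @export
fullSequences <- function(csl) {
  out <- DNAStringSet(lapply(csl@catchers, fullSequence))
  names(out) <- catcherNames(csl)
  out
}

#' @rdname csl-accessors
#' @export
targetIntervals <- function(csl) {
  if (!length(csl@catchers)) return(GRanges())
  gr <- GRanges(
    vapply(csl@catchers, function(x)
      as.character(seqnames(x@targetInterval)), character(1)),
    IRanges(vapply(csl@catchers, function(x) start(x@targetInterval),
                   integer(1)),
            vapply(csl@catchers, function(x) end(x@targetInterval),
                   integer(1))))
  names(gr) <- catcherNames(csl)
  mcols(gr)$boundStrand <- vapply(csl@catchers, function(x) x@boundStrand,
                                  character(1))
  gr
}

#' @rdname csl-accessors
#' @export
designParamsOf <- function(csl) csl@params

#' Design the TMSD release strand for a catcher
#'
#' The release strand is the reverse complement of the catcher's release
#' site plus binding site. It nucleates at the single-stranded toehold and
#' branch-migrates through the binding site, evicting the bound target
#' while itself remaining hybridized to the catcher - so the released
#' target carries no probe sequence. Catchers designed without a toehold
#' (`releaseLen = 0`) cannot be addressed this way and can only be released
#' non-selectively by thermal or basic denaturation; asking for their
#' release strand is an error.
#'
#' @param catcher A [CatcherStrand-class] with a non-empty release site.
#' @return A `DNAString` of length `releaseLen + bindingLen`.
#' @export
designReleaseStrand <- function(catcher) {
  stopifnot(is(catcher, "CatcherStrand"))
  if (length(catcher@releaseSite) == 0L)
    stop("catcher '", catcher@name, "' has no release site (toehold); ",
         "it can only be released non-selectively by denaturation")
  reverseComplement(DNAString(xscat(catcher@releaseSite,
                                    catcher@bindingSite)))
}

#' Release strands for all (or a subset of) catchers in a library
#'
#' @param csl A [CatcherLibrary-class].
#' @param which Catcher names to design release strands for (default all).
#' @return Named `DNAStringSet`, one release strand per selected catcher.
#' @export
designReleaseStrands <- function(csl, which = catcherNames(csl)) {
  stopifnot(is(csl, "CatcherLibrary"))
  sel <- csl@catchers[match(which, catcherNames(csl))]
  if (anyNA(match(which, catcherNames(csl))))
    stop("unknown catcher name(s): ",
         paste(setdiff(which, catcherNames(csl)), collapse = ", "))
  out <- DNAStringSet(lapply(sel, designReleaseStrand))
  names(out) <- which
  out
}

#' Screen a catcher library for off-target capture
#'
#' For every (catcher, transcript) pair, finds the longest exact substring
#' the binding site shares with the transcript on either strand and reports
#' pairs at or above `k`. Transcripts a catcher was designed against are
#' excluded by default; the motivating failure mode is a readthrough
#' transcript that embeds a targeted segment and is therefore co-captured.
#'
#' @param csl A [CatcherLibrary-class].
#' @param transcriptome Named `DNAStringSet` (or FASTA path).
#' @param k Minimum shared length to report (nt, >= 8); defaults to the
#'   library's `minOfftargetK`.
#' @param excludeDesigned Drop hits on each catcher's own target transcript.
#' @return A `DataFrame` sorted by decreasing `sharedLen` with columns
#'   `catcher`, `transcript`, `sharedLen`, `startCatcher`,
#'   `startTranscript` (1-based), `strand`.
#' @export
screenOfftargets <- function(csl, transcriptome,
                             k = designParamsOf(csl)@minOfftargetK,
                             excludeDesigned = TRUE) {
  stopifnot(is(csl, "CatcherLibrary"))
  if (is.character(transcriptome) && length(transcriptome) == 1L &&
      file.exists(transcriptome))
    transcriptome <- readTargets(transcriptome)
  transcriptome <- .asDNASet(transcriptome, "transcriptome")
  if (k < 8L) stop("k must be >= 8")
  rows <- list()
  for (cs in csl@catchers) {
    own <- as.character(seqnames(cs@targetInterval))
    for (tid in names(transcriptome)) {
      if (excludeDesigned && tid == own) next
      hit <- longestSharedSubstring(cs@bindingSite, transcriptome[[tid]],
                                    bothStrands = TRUE)
      if (hit$length >= k) {
        # report forward transcript coordinates even for matches found on
        # the reverse complement
        startTx <- if (hit$strand == "-")
          length(transcriptome[[tid]]) - (hit$startB + hit$length - 1L) + 1L
        else hit$startB
        rows[[length(rows) + 1L]] <-
          DataFrame(catcher = cs@name, transcript = tid,
                    sharedLen = hit$length, startCatcher = hit$startA,
                    startTranscript = startTx, strand = hit$strand)
      }
    }
  }
  if (!length(rows))
    return(DataFrame(catcher = character(), transcript = character(),
                     sharedLen = integer(), startCatcher = integer(),
                     startTranscript = integer(), strand = character()))
  out <- do.call(rbind, rows)
  out[order(-out$sharedLen, out$catcher, out$transcript), , drop = FALSE]
}
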