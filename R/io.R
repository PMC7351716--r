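#' Export a catcher library as a synthesis order sheet
#'
#' Writes a TSV with one row per catcher (name, target, 0-based half-open
#' interval, bound strand, the three domain sequences and the full 5'->3'
#' sequence), plus optional FASTA exports of the full catcher sequences and
#' of the companion release strands. Output is deterministic: the same
#' library always produces byte-identical files.
#'
#' @param csl A [CatcherLibrary-class].
#' @param file Path of the order-sheet TSV.
#' @param fastaFile Optional path for a FASTA of full catcher sequences.
#' @param releaseFile Optional path for a companion release-strand TSV;
#'   if the library has no toeholds an empty sheet is written with a
#'   warning (denaturation-only library).
#' @return `file`, invisibly.
#' @export
exportOrderSheet <- function(csl, file, fastaFile = NULL,
                             releaseFile = NULL) {
  stopifnot(is(csl, "CatcherLibrary"))
  iv <- targetIntervals(csl)
  tab <- data.frame(
    name = catcherNames(csl),
    target = if (length(csl)) as.character(seqnames(iv)) else character(),
    start = if (length(csl)) start(iv) - 1L else integer(),
    end = if (length(csl)) end(iv) else integer(),
    bound_strand = if (length(csl)) mcols(iv)$boundStrand else character(),
    release_site = as.character(releaseSites(csl)),
    binding_site = as.character(bindingSites(csl)),
    adapter = vapply(catchers(csl), function(x) as.character(x@adapter),
                     character(1)),
    full_sequence = as.character(fullSequences(csl)),
    stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fastaFile))
    writeFasta(fullSequences(csl), fastaFile)
  if (!is.null(releaseFile)) {
    if (csl@params@releaseLen == 0L || length(csl) == 0L) {
      if (csl@params@releaseLen == 0L)
        warning("library has no release sites; writing empty release sheet")
      rel <- data.frame(catcher = character(), sequence = character())
    } else {
      rs <- designReleaseStrands(csl)
      rel <- data.frame(catcher = names(rs), sequence = as.character(rs),
                        stringsAsFactors = FALSE)
    }
    write.table(rel, releaseFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(file)
}

#' Re-read an order sheet into a catcher library
#'
#' Reconstructs a [CatcherLibrary-class] from a TSV written by
#' [exportOrderSheet()]; the round trip preserves every sequence.
#'
#' @param file Order-sheet TSV path.
#' @return A [CatcherLibrary-class].
#' @export
readOrderSheet <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(release_site = "character"))
  if (nrow(tab) == 0L)
    return(new("CatcherLibrary", catchers = list(), params = designParams(),
               targets = GRanges()))
  tab$release_site[is.na(tab$release_site)] <- ""
  adapter <- asDNA(tab$adapter[1L], "adapter")
  relLen <- nchar(tab$release_site[1L])
  bindLen <- nchar(tab$binding_site[1L])
  params <- designParams(bindingLen = bindLen, adapterSeq = adapter,
                         releaseLen = relLen)
  catchers <- lapply(seq_len(nrow(tab)), function(i) {
    new("CatcherStrand",
        name = tab$name[i],
        targetInterval = .interval(tab$target[i], tab$start[i], tab$end[i]),
        boundStrand = tab$bound_strand[i],
        bindingSite = asDNA(tab$binding_site[i]),
        adapter = asDNA(tab$adapter[i]),
        releaseSite = asDNA0(tab$release_site[i]))
  })
  targets <- GRanges(tab$target, IRanges(tab$start + 1L, tab$end))
  new("CatcherLibrary", catchers = catchers, params = params,
      targets = targets)
}

#' Coverage track I/O (bedGraph)
#'
#' `writeCoverageBedGraph()` writes per-base coverage tracks (a named list
#' of integer vectors, or an `RleList` as returned by the coverage
#' simulators) as bedGraph with 0-based half-open intervals.
#' `readCoverageBedGraph()` reads one back and expands it to dense per-base
#' integer vectors; transcript lengths are taken from the track extents or
#' supplied explicitly.
#'
#' @param tracks Named list of per-base numeric vectors, or an `RleList`.
#' @param file Path.
#' @param lengths Optional named transcript lengths for re-expansion.
#' @return `readCoverageBedGraph`: named list of integer vectors.
#' @name coverage-io
NULL

#' @rdname coverage-io
#' @export
writeCoverageBedGraph <- function(tracks, file) {
  if (is(tracks, "RleList")) tracks <- lapply(tracks, as.integer)
  runs <- lapply(names(tracks), function(tid) {
    r <- Rle(as.numeric(tracks[[tid]]))
    ends <- cumsum(S4Vectors::runLength(r))
    data.frame(tid = tid, start = ends - S4Vectors::runLength(r) + 1L,
               end = ends, score = S4Vectors::runValue(r))
  })
  runs <- do.call(rbind, runs)
  gr <- GRanges(runs$tid, IRanges(runs$start, runs$end))
  mcols(gr)$score <- runs$score
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname coverage-io
#' @export
readCoverageBedGraph <- function(file, lengths = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  tids <- unique(as.character(seqnames(gr)))
  out <- lapply(tids, function(tid) {
    sub <- gr[seqnames(gr) == tid]
    len <- if (!is.null(lengths)) lengths[[tid]] else max(end(sub))
    depth <- numeric(len)
    for (i in seq_along(sub))
      depth[start(sub)[i]:end(sub)[i]] <- mcols(sub)$score[i]
    as.integer(depth)
  })
  names(out) <- tids
  out
}

#' Mixture I/O
#'
#' `writeMixture()` writes a [MixtureSet-class] as a FASTA plus a TSV of
#' `member`, `molecules`, `duplex`; `readMixture()` reads the pair back.
#'
#' @param mixture A [MixtureSet-class].
#' @param fastaFile,tsvFile Paths.
#' @return `readMixture`: a [MixtureSet-class].
#' @name mixture-io
NULL

#' @rdname mixture-io
#' @export
writeMixture <- function(mixture, fastaFile, tsvFile) {
  stopifnot(is(mixture, "MixtureSet"))
  writeFasta(mixture@seqs, fastaFile)
  write.table(data.frame(member = names(mixture@seqs),
                         molecules = mixture@molecules,
                         duplex = mixture@duplex),
              tsvFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsvFile)
}

#' @rdname mixture-io
#' @export
readMixture <- function(fastaFile, tsvFile) {
  seqs <- readTargets(fastaFile)
  tab <- read.table(tsvFile, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  ord <- match(names(seqs), tab$member)
  if (anyNA(ord)) stop("FASTA members missing from the TSV")
  mixtureSet(seqs, molecules = tab$molecules[ord],
             duplex = tab$duplex[ord])
}
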