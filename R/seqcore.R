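#' Coerce to a strict A/C/G/T DNA sequence
#'
#' Converts character input to a [Biostrings::DNAString] and rejects any
#' sequence that is empty or contains characters outside `A`, `C`, `G`, `T`.
#' Degenerate IUPAC codes (`N`, `R`, ...) and gaps are refused rather than
#' silently expanded: probe synthesis sheets must be unambiguous.
#'
#' @param x A character scalar, `DNAString`, or anything coercible to one.
#' @param what Label used in error messages.
#' @return A `DNAString`.
#' @examples
#' asDNA("ACGT")
#' @export
asDNA <- function(x, what = "sequence") {
  s <- if (is(x, "DNAString")) x else DNAString(toupper(as.character(x)))
  if (length(s) == 0L)
    stop(what, " must be non-empty")
  freq <- letterFrequency(s, letters = c("A", "C", "G", "T"))
  if (sum(freq) != length(s))
    stop(what, " contains characters outside A/C/G/T ",
         "(degenerate IUPAC codes are not allowed)")
  s
}

.asDNASet <- function(x, what = "sequences") {
  set <- if (is(x, "DNAStringSet")) x else DNAStringSet(x)
  ok <- rowSums(letterFrequency(set, letters = c("A", "C", "G", "T"))) ==
    width(set)
  if (any(width(set) == 0L) || !all(ok))
    stop(what, " must be non-empty and restricted to A/C/G/T")
  set
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed. A thin validating wrapper around
#' [Biostrings::reverseComplement()] that enforces the strict A/C/G/T
#' alphabet used throughout the package.
#'
#' @param seq Sequence (character or `DNAString`).
#' @return A `DNAString` of the same length.
#' @examples
#' revComp("AAACCC")  # GGGTTT
#' @export
revComp <- function(seq) reverseComplement(asDNA(seq))

#' GC fraction of a sequence
#'
#' @param seq Sequence (character or `DNAString`).
#' @return Fraction of G+C bases, in `[0, 1]`.
#' @examples
#' gcFraction("ACGT")  # 0.5
#' @export
gcFraction <- function(seq) {
  s <- asDNA(seq)
  unname(sum(letterFrequency(s, letters = c("G", "C")))) / length(s)
}

#' Longest exact shared substring of two sequences
#'
#' Finds the longest contiguous run of bases present in both `a` and `b`,
#' optionally also scanning the reverse complement of `b`. This is the engine
#' behind the off-target screen: a probe whose binding site shares a long
#' exact stretch with an unintended transcript will capture it, as in the
#' readthrough-transcript case where a gene sharing a targeted sequence was
#' co-captured.
#'
#' Ties are broken by the smallest start position in `a`, then in `b`; when
#' both strands are searched, the forward orientation wins remaining ties.
#'
#' @param a,b Sequences (character or `DNAString`).
#' @param bothStrands Also search `reverseComplement(b)` and report the
#'   better of the two orientations.
#' @return A list with `length`, `startA`, `startB` (1-based starts within
#'   `a` and within the searched orientation of `b`; 0 when `length` is 0)
#'   and `strand` (`"+"` for `b` as given, `"-"` for its reverse complement).
#' @examples
#' longestSharedSubstring("AAAA", "TTTT")                     # length 0
#' longestSharedSubstring("AAAA", "TTTT", bothStrands = TRUE) # length 4
#' @export
longestSharedSubstring <- function(a, b, bothStrands = FALSE) {
  a <- asDNA(a, "a")
  b <- asDNA(b, "b")
  fwd <- .lcs_dp(as.character(a), as.character(b))
  hit <- list(length = fwd[1L], startA = fwd[2L], startB = fwd[3L],
              strand = "+")
  if (isTRUE(bothStrands)) {
    rev <- .lcs_dp(as.character(a), as.character(reverseComplement(b)))
    better <- rev[1L] > hit$length ||
      (rev[1L] == hit$length && rev[1L] > 0L &&
         (rev[2L] < hit$startA ||
            (rev[2L] == hit$startA && rev[3L] < hit$startB)))
    if (better)
      hit <- list(length = rev[1L], startA = rev[2L], startB = rev[3L],
                  strand = "-")
  }
  hit
}

#' Read and write FASTA / BED interfaces
#'
#' `readTargets()` reads a multi-record FASTA into a validated
#' `DNAStringSet`; `writeFasta()` writes one. `readRegions()` reads BED3/BED6
#' target regions (0-based half-open, as in the BED convention) into a
#' [GenomicRanges::GRanges] whose seqnames are transcript identifiers.
#'
#' @param file Path to the file.
#' @param x A `DNAStringSet` (for `writeFasta`).
#' @return `readTargets`: a named `DNAStringSet`. `readRegions`: a `GRanges`.
#' @name sequence-io
NULL

#' @rdname sequence-io
#' @export
readTargets <- function(file) {
  set <- readDNAStringSet(file)
  names(set) <- sub("\\s.*$", "", names(set))
  .asDNASet(set, "FASTA records")
}

#' @rdname sequence-io
#' @export
writeFasta <- function(x, file) {
  writeXStringSet(DNAStringSet(x), file)
  invisible(file)
}

#' @rdname sequence-io
#' @export
readRegions <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  granges(gr)
}

# 0-based half-open [start0, end0) on transcript `id` -> GRanges (1-based
# internal representation, the Bioconductor convention)
.interval <- function(id, start0, end0) {
  stopifnot(start0 >= 0, end0 > start0)
  GRanges(id, IRanges(start = start0 + 1L, end = end0))
}
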